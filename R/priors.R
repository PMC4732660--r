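#' Yule (pure-birth) log prior on internal node ages
#'
#' Log density of the internal node ages of a fixed, fully bifurcating labeled
#' topology under the same pure-birth construction as
#' [simulate_pure_birth()]. With gaps between age-ranked splits distributed
#' `Exp(j * birth_rate)` and a uniform ranked history, the joint density of
#' (topology, ages) collapses to
#' `birth_rate^(n-1) * exp(-birth_rate * sum(internal ages))`;
#' conditioning on the fixed topology leaves the same expression restricted to
#' age configurations compatible with it. Returns `-Inf` for any state
#' violating parent-older-than-child ordering.
#'
#' @param tree A [time_tree()].
#' @param birth_rate Speciation rate (> 0).
#' @return Log density (no constants dropped beyond the topology factor).
#' @export
yule_log_prior <- function(tree, birth_rate) {
  stopifnot(inherits(tree, "time_tree"))
  check_number(birth_rate, "`birth_rate`", positive = TRUE)
  phy <- tree$phylo
  yule_log_prior_ages(tree$ages, phy$edge, ape::Ntip(phy), birth_rate)
}

# Fast path used inside the MCMC: ages indexed by ape node number.
yule_log_prior_ages <- function(ages, edge, ntip, birth_rate) {
  internal <- ages[(ntip + 1):length(ages)]
  if (any(internal <= 0)) return(-Inf)
  if (any(ages[edge[, 1]] <= ages[edge[, 2]])) return(-Inf)
  (length(internal)) * log(birth_rate) - birth_rate * sum(internal)
}

#' Log density of branch rates under the uncorrelated-lognormal clock
#'
#' Sum of independent lognormal log densities, `meanlog = mean_log`,
#' `sdlog = sd_log` (both log-space parameters).
#'
#' @param rates Positive branch rates.
#' @param mean_log Log-space mean of the branch-rate lognormal.
#' @param sd_log Log-space standard deviation (> 0).
#' @return Log density.
#' @export
ucln_rate_log_density <- function(rates, mean_log, sd_log) {
  if (sd_log < 0) stop_input("`sd_log` must be >= 0")
  if (any(rates <= 0)) return(-Inf)
  if (sd_log == 0)
    return(if (all(abs(log(rates) - mean_log) < 1e-12)) Inf else -Inf)
  sum(dlnorm(rates, meanlog = mean_log, sdlog = sd_log, log = TRUE))
}

# Hyperpriors for the relaxed-clock parameters: mean log rate flat within
# broad bounds, sd_log ~ Exponential(mean 1).
clock_hyper_log_prior <- function(mean_log, sd_log,
                                  mu_log_bounds = c(log(1e-6), log(1))) {
  if (sd_log < 0) return(-Inf)
  if (mean_log < mu_log_bounds[1] || mean_log > mu_log_bounds[2]) return(-Inf)
  -log(diff(mu_log_bounds)) + dexp(sd_log, rate = 1, log = TRUE)
}

#' Log prior of the full relaxed-clock state
#'
#' Branch-rate lognormal terms plus the hyperpriors on the log-space mean
#' (flat within `mu_log_bounds`) and standard deviation (exponential, mean 1).
#'
#' @param state A list with elements `rates`, `ucln_mean` (log-space mean) and
#'   `ucln_sd` (log-space sd).
#' @param mu_log_bounds Support of the flat prior on the log-space mean rate.
#' @return Log density.
#' @export
ucln_log_prior <- function(state, mu_log_bounds = c(log(1e-6), log(1))) {
  if (is.null(state$rates) || is.null(state$ucln_mean) || is.null(state$ucln_sd))
    stop_input("`state` must have elements rates, ucln_mean, ucln_sd")
  if (state$ucln_sd < 0) stop_input("`ucln_sd` must be >= 0")
  h <- clock_hyper_log_prior(state$ucln_mean, state$ucln_sd, mu_log_bounds)
  if (!is.finite(h)) return(-Inf)
  h + ucln_rate_log_density(state$rates, state$ucln_mean, state$ucln_sd)
}

#' Log density of a calibration prior at a node age
#'
#' Lognormal, uniform, or zero-truncated normal, evaluated at `age`; `-Inf`
#' outside the support. Normal calibrations are truncated at 0 and
#' renormalised, since negative ages are meaningless.
#'
#' @param prior A [calibration_prior()].
#' @param age Node age (>= 0).
#' @return Log density.
#' @export
calibration_log_prior <- function(prior, age) {
  stopifnot(inherits(prior, "calibration_prior"))
  check_number(age, "`age`", nonneg = TRUE)
  switch(prior$kind,
    lognormal = dlnorm(age, meanlog = prior$meanlog, sdlog = prior$sdlog,
                       log = TRUE),
    uniform = dunif(age, min = prior$lo, max = prior$hi, log = TRUE),
    normal = {
      if (age < 0) return(-Inf)
      dnorm(age, prior$mean, prior$sd, log = TRUE) -
        pnorm(0, prior$mean, prior$sd, lower.tail = FALSE, log.p = TRUE)
    },
    stop_input("unknown calibration kind: ", prior$kind)
  )
}

# Hyperprior on kappa used when kappa is estimated: lognormal(ln 2, 1).
kappa_log_prior <- function(kappa) {
  dlnorm(kappa, meanlog = log(2), sdlog = 1, log = TRUE)
}
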