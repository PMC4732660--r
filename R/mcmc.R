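#' MCMC configuration for the dating sampler
#'
#' @param chain_length Number of generations (proposals).
#' @param sample_every Thinning interval; the trace records generation 0 and
#'   every `sample_every` generations thereafter.
#' @param burnin_fraction Default burn-in used by [summarize_trace()].
#' @param seed Optional integer seed; identical inputs and seed reproduce the
#'   trace exactly.
#' @param clock_model `"ucln"` (uncorrelated lognormal branch rates, the
#'   default) or `"strict"` (one global rate).
#' @param estimate_kappa,estimate_freqs Sample the HKY parameters? When
#'   `FALSE` they stay fixed at their initial values.
#' @param estimate_clock_rate Strict clock only: sample the global rate
#'   (flat-in-log prior within `mu_log_bounds`) or keep it fixed.
#' @param use_likelihood Set `FALSE` for prior-only (data-free) runs.
#' @param birth_rate Yule tree-prior speciation rate.
#' @param init_clock_rate Initial (or fixed) clock rate / lognormal mean rate.
#' @param mu_log_bounds Support of the flat prior on the log mean rate.
#' @param move_weights Optional named numeric vector overriding the default
#'   proposal weights (see Details in [run_mcmc()]).
#' @param move_scales Optional named list overriding default proposal scales.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 2e5, sample_every = 100,
                        burnin_fraction = 0.5, seed = NULL,
                        clock_model = c("ucln", "strict"),
                        estimate_kappa = TRUE, estimate_freqs = TRUE,
                        estimate_clock_rate = TRUE, use_likelihood = TRUE,
                        birth_rate = 0.7, init_clock_rate = 0.01,
                        mu_log_bounds = c(log(1e-6), log(1)),
                        move_weights = NULL, move_scales = NULL) {
  clock_model <- match.arg(clock_model)
  if (chain_length < sample_every || sample_every < 1)
    stop_input("need chain_length >= sample_every >= 1")
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop_input("`burnin_fraction` must be in [0, 1)")
  check_number(birth_rate, "`birth_rate`", positive = TRUE)
  structure(list(chain_length = as.integer(chain_length),
                 sample_every = as.integer(sample_every),
                 burnin_fraction = burnin_fraction, seed = seed,
                 clock_model = clock_model,
                 estimate_kappa = estimate_kappa,
                 estimate_freqs = estimate_freqs,
                 estimate_clock_rate = estimate_clock_rate,
                 use_likelihood = use_likelihood,
                 birth_rate = birth_rate,
                 init_clock_rate = init_clock_rate,
                 mu_log_bounds = mu_log_bounds,
                 move_weights = move_weights, move_scales = move_scales),
            class = "mcmc_config")
}

default_move_scales <- function() {
  list(age_window = 0.05,     # fraction of current root age
       root_scale = 0.15, tree_scale = 0.10, time_rate_scale = 0.15,
       rate_mult = 0.8, clock_rate_mult = 0.3, kappa_mult = 0.15,
       freq_shift = 0.02, mu_slide = 0.1, sigma_mult = 0.3)
}

default_move_weights <- function() {
  c(age_slide = 15, age_window = 15, root_scale = 4, tree_scale = 2,
    time_rate_scale = 4, rate_mult = 20, clock_rate_mult = 5,
    kappa_mult = 2, freq_shift = 2, mu_slide = 3, sigma_mult = 3)
}

#' Felsenstein-pruning log likelihood under HKY
#'
#' `log P(alignment | topology, node ages, branch rates, HKY params)` with
#' per-branch substitution length = branch duration x branch rate, sites
#' independent, computed by the pruning algorithm over compressed site
#' patterns (compiled kernel).
#'
#' @param topology A [time_tree()] (provides topology and node ages).
#' @param branch_rates Per-branch rates in `topology$phylo$edge` row order, or
#'   a single global rate.
#' @param params An [hky_params()].
#' @param alignment A taxa-by-sites character matrix over A/C/G/T whose
#'   rownames exactly match the tree's tip labels.
#' @return Log likelihood (numeric scalar).
#' @export
pruning_log_likelihood <- function(topology, branch_rates, params, alignment) {
  stopifnot(inherits(topology, "time_tree"), inherits(params, "hky_params"))
  phy <- topology$phylo
  n <- ape::Ntip(phy)
  if (!setequal(rownames(alignment), phy$tip.label))
    stop_input("alignment taxa do not match tree tips")
  nedge <- nrow(phy$edge)
  if (length(branch_rates) == 1) branch_rates <- rep(branch_rates, nedge)
  if (length(branch_rates) != nedge)
    stop_input("`branch_rates` must have one rate per branch")
  if (any(branch_rates < 0)) stop_input("branch rates must be >= 0")
  po <- ape::reorder.phylo(phy, "postorder")
  # map postorder edges back to input edge order to carry rates over
  key_in <- paste(phy$edge[, 1], phy$edge[, 2])
  key_po <- paste(po$edge[, 1], po$edge[, 2])
  rates_po <- branch_rates[match(key_po, key_in)]
  dur_po <- topology$ages[po$edge[, 1]] - topology$ages[po$edge[, 2]]
  cp <- compress_patterns(alignment, phy$tip.label)
  pruning_loglik_cpp(po$edge, unname(dur_po) * rates_po, n,
                     cp$patterns, cp$weights, params$kappa, params$base_freqs)
}

# Repair candidate internal ages so that every parent is strictly older than
# its children (postorder sweep); used only to build a feasible initial state.
repair_ordering <- function(ages, edge_po, eps) {
  for (e in seq_len(nrow(edge_po))) {
    p <- edge_po[e, 1]; ch <- edge_po[e, 2]
    if (ages[p] <= ages[ch]) ages[p] <- ages[ch] + eps
  }
  ages
}

#' Fixed-topology Bayesian node-dating MCMC
#'
#' Metropolis-Hastings sampling of internal node ages, branch rates (UCLN or
#' strict clock), HKY parameters and the relaxed-clock hyperparameters,
#' targeting likelihood x Yule prior x clock prior x calibration priors on a
#' fixed topology. Proposal kernels: uniform and windowed node-age slides
#' within (oldest child, parent) bounds, multiplicative root and whole-tree
#' scalings, a joint time/rate rescale (which leaves the likelihood
#' invariant), multiplicative (log-scale) moves on branch rates, kappa and the
#' clock hyperparameters, and a two-frequency exchange move.
#'
#' @param alignment Character matrix (taxa x sites) over A/C/G/T; may be
#'   `NULL` when `config$use_likelihood` is `FALSE`.
#' @param topology A [time_tree()]; its topology is fixed throughout and its
#'   ages seed the initial state.
#' @param calibrations List of [calibration_prior()] objects; required for an
#'   identifiable timescale whenever rates are estimated with data.
#' @param params0 Initial [hky_params()].
#' @param config An [mcmc_config()].
#' @param init_ages Optional named vector (node key -> age) of initial
#'   internal node ages, e.g. primary posterior medians; ordering violations
#'   are repaired and infeasible states rescaled onto calibration support.
#' @return A tibble trace of class `mcmc_trace` with one row per recorded
#'   sample: `generation`, `log_likelihood`, `log_prior`, `kappa`,
#'   `freq_A` ... `freq_T`, clock columns (`ucln_mean`, `ucln_sd` or
#'   `clock_rate`), `age_*` per internal node and `rate_*` per branch
#'   (postorder edge index). Attributes: `node_keys` (age column -> frozen tip
#'   set), `acceptance` (per-move rates), `config`.
#' @export
run_mcmc <- function(alignment, topology, calibrations = list(),
                     params0 = hky_params(), config = mcmc_config(),
                     init_ages = NULL) {
  stopifnot(inherits(topology, "time_tree"), inherits(config, "mcmc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  phy <- topology$phylo
  n <- ape::Ntip(phy)
  nnode <- phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  edge_po <- po$edge
  nedge <- nrow(edge_po)
  root <- n + 1L
  internal <- (n + 1L):(n + nnode)
  nonroot_internal <- setdiff(internal, root)
  parent <- integer(n + nnode)
  parent[edge_po[, 2]] <- edge_po[, 1]
  kids <- matrix(0L, n + nnode, 2)
  for (e in seq_len(nedge)) {
    p <- edge_po[e, 1]
    kids[p, if (kids[p, 1] == 0L) 1L else 2L] <- edge_po[e, 2]
  }

  ucln <- config$clock_model == "ucln"
  est_rate <- ucln || config$estimate_clock_rate
  if (config$use_likelihood) {
    if (is.null(alignment)) stop_input("alignment required when likelihood is on")
    if (!setequal(rownames(alignment), phy$tip.label))
      stop_input("alignment taxa do not match tree tips")
    if (est_rate && length(calibrations) == 0)
      stop_input("no time-scale information: provide a calibration or fix the clock rate")
    cp <- compress_patterns(alignment, phy$tip.label)
  }

  keys <- node_keys(topology)
  cal_nodes <- vapply(calibrations, function(cp_) {
    hit <- names(keys)[match(cp_$node_key, keys)]
    if (is.na(hit)) stop_input("calibration key not found in topology: ",
                               substr(cp_$node_key, 1, 60))
    as.integer(hit)
  }, integer(1))

  # --- initial state -------------------------------------------------------
  ages <- unname(topology$ages)
  if (!is.null(init_ages)) {
    hit <- match(keys, names(init_ages))
    ok <- !is.na(hit)
    ages[as.integer(names(keys))[ok]] <- unname(init_ages[hit[ok]])
    ages <- repair_ordering(ages, edge_po, eps = 1e-6 * max(ages))
  }
  rates <- if (ucln) rep(config$init_clock_rate, nedge) else config$init_clock_rate
  kappa <- params0$kappa
  freqs <- params0$base_freqs
  mu <- log(config$init_clock_rate)
  sigma <- 0.5

  scales <- utils::modifyList(default_move_scales(),
                              config$move_scales %||% list())

  cal_log_prior <- function(a) {
    if (!length(cal_nodes)) return(0)
    s <- 0
    for (i in seq_along(cal_nodes)) {
      s <- s + calibration_log_prior(calibrations[[i]], a[cal_nodes[i]])
      if (!is.finite(s)) return(-Inf)
    }
    s
  }
  clock_log_prior <- function(r, m, s2) {
    if (ucln) {
      h <- clock_hyper_log_prior(m, s2, config$mu_log_bounds)
      if (!is.finite(h)) return(-Inf)
      h + ucln_rate_log_density(r, m, s2)
    } else if (config$estimate_clock_rate) {
      lr <- log(r)
      if (lr < config$mu_log_bounds[1] || lr > config$mu_log_bounds[2]) -Inf
      else -lr
    } else 0
  }
  log_prior <- function(a, r, m, s2, k) {
    y <- yule_log_prior_ages(a, edge_po, n, config$birth_rate)
    if (!is.finite(y)) return(-Inf)
    cl <- clock_log_prior(r, m, s2)
    if (!is.finite(cl)) return(-Inf)
    ca <- cal_log_prior(a)
    if (!is.finite(ca)) return(-Inf)
    y + cl + ca + if (config$estimate_kappa) kappa_log_prior(k) else 0
  }
  log_lik <- function(a, r, k, f) {
    if (!config$use_likelihood) return(0)
    blen <- (a[edge_po[, 1]] - a[edge_po[, 2]]) * r
    pruning_loglik_cpp(edge_po, blen, n, cp$patterns, cp$weights, k, f)
  }

  lp <- log_prior(ages, rates, mu, sigma, kappa)
  if (!is.finite(lp)) {
    # rescale onto the root calibration's support, if there is one
    root_cal <- which(cal_nodes == root)
    if (length(root_cal)) {
      cal <- calibrations[[root_cal[1]]]
      target <- switch(cal$kind, uniform = (cal$lo + cal$hi) / 2,
                       lognormal = exp(cal$meanlog), normal = cal$mean)
      ages[internal] <- ages[internal] * (target / ages[root])
      lp <- log_prior(ages, rates, mu, sigma, kappa)
    }
  }
  if (!is.finite(lp)) stop_input("could not construct a feasible initial state")
  ll <- log_lik(ages, rates, kappa, freqs)

  # --- move schedule -------------------------------------------------------
  w <- default_move_weights()
  if (!is.null(config$move_weights))
    w[names(config$move_weights)] <- config$move_weights
  if (!length(nonroot_internal)) w[c("age_slide", "age_window")] <- 0
  if (!ucln) w[c("rate_mult", "mu_slide", "sigma_mult")] <- 0
  if (ucln) w["clock_rate_mult"] <- 0
  if (!ucln && !config$estimate_clock_rate)
    w[c("clock_rate_mult", "time_rate_scale")] <- 0
  if (!config$estimate_kappa) w["kappa_mult"] <- 0
  if (!config$estimate_freqs || !config$use_likelihood) w["freq_shift"] <- 0
  if (!config$use_likelihood && !est_rate)
    w[c("rate_mult", "clock_rate_mult", "mu_slide", "sigma_mult",
        "kappa_mult", "time_rate_scale")] <- 0
  w <- w[w > 0]
  move_names <- names(w)
  cw <- cumsum(w / sum(w))

  n_int <- length(internal)
  n_rate_pars <- if (ucln) nedge else 1L
  prop_attempt <- setNames(numeric(length(move_names)), move_names)
  prop_accept <- prop_attempt

  nsamp <- config$chain_length %/% config$sample_every + 1L
  age_cols <- paste0("age_", internal)
  rate_cols <- paste0("rate_", seq_len(if (ucln) nedge else 1L))
  clock_cols <- if (ucln) c("ucln_mean", "ucln_sd") else "clock_rate"
  cols <- c("generation", "log_likelihood", "log_prior", "kappa",
            paste0("freq_", c("A", "C", "G", "T")), clock_cols,
            age_cols, rate_cols)
  out <- matrix(NA_real_, nsamp, length(cols), dimnames = list(NULL, cols))
  out[1L, ] <- c(0, ll, lp, kappa, freqs,
                 if (ucln) c(mu, sigma) else rates[1],
                 ages[internal], if (ucln) rates else rates[1])
  row <- 1L

  for (gen in seq_len(config$chain_length)) {
    mv <- move_names[findInterval(runif(1), cw) + 1L]
    prop_attempt[mv] <- prop_attempt[mv] + 1
    a2 <- ages; r2 <- rates; k2 <- kappa; f2 <- freqs; m2 <- mu; s2 <- sigma
    lh <- 0       # log Hastings ratio
    lik_changed <- TRUE
    switch(mv,
      age_slide = {
        v <- nonroot_internal[sample.int(length(nonroot_internal), 1L)]
        lo <- max(a2[kids[v, ]]); hi <- a2[parent[v]]
        a2[v] <- runif(1, lo, hi)
      },
      age_window = {
        v <- nonroot_internal[sample.int(length(nonroot_internal), 1L)]
        a2[v] <- a2[v] + runif(1, -1, 1) * scales$age_window * a2[root]
      },
      root_scale = {
        u <- runif(1, -scales$root_scale, scales$root_scale)
        a2[root] <- a2[root] * exp(u); lh <- u
      },
      tree_scale = {
        u <- runif(1, -scales$tree_scale, scales$tree_scale)
        a2[internal] <- a2[internal] * exp(u); lh <- n_int * u
      },
      time_rate_scale = {
        u <- runif(1, -scales$time_rate_scale, scales$time_rate_scale)
        a2[internal] <- a2[internal] * exp(u)
        r2 <- r2 * exp(-u)
        if (ucln) m2 <- m2 - u
        lh <- (n_int - n_rate_pars) * u
      },
      rate_mult = {
        e <- sample.int(nedge, 1L)
        u <- runif(1, -scales$rate_mult, scales$rate_mult)
        r2[e] <- r2[e] * exp(u); lh <- u
      },
      clock_rate_mult = {
        u <- runif(1, -scales$clock_rate_mult, scales$clock_rate_mult)
        r2 <- r2 * exp(u); lh <- u
      },
      kappa_mult = {
        u <- runif(1, -scales$kappa_mult, scales$kappa_mult)
        k2 <- k2 * exp(u); lh <- u
      },
      freq_shift = {
        ij <- sample.int(4L, 2L)
        d <- runif(1, -scales$freq_shift, scales$freq_shift)
        f2[ij[1]] <- f2[ij[1]] + d; f2[ij[2]] <- f2[ij[2]] - d
        if (any(f2 < 1e-4)) f2 <- freqs  # reject via no-op
      },
      mu_slide = {
        m2 <- m2 + runif(1, -scales$mu_slide, scales$mu_slide)
        lik_changed <- FALSE
      },
      sigma_mult = {
        u <- runif(1, -scales$sigma_mult, scales$sigma_mult)
        s2 <- s2 * exp(u); lh <- u
        lik_changed <- FALSE
      }
    )
    lp2 <- log_prior(a2, r2, m2, s2, k2)
    if (is.finite(lp2)) {
      ll2 <- if (lik_changed) log_lik(a2, r2, k2, f2) else ll
      if (log(runif(1)) < (ll2 + lp2) - (ll + lp) + lh) {
        ages <- a2; rates <- r2; kappa <- k2; freqs <- f2; mu <- m2
        sigma <- s2; ll <- ll2; lp <- lp2
        prop_accept[mv] <- prop_accept[mv] + 1
      }
    }
    if (gen %% config$sample_every == 0L) {
      row <- row + 1L
      out[row, ] <- c(gen, ll, lp, kappa, freqs,
                      if (ucln) c(mu, sigma) else rates[1],
                      ages[internal], if (ucln) rates else rates[1])
    }
  }

  trace <- tibble::as_tibble(out)
  attr(trace, "node_keys") <- setNames(as.list(unname(keys[as.character(internal)])),
                                       age_cols)
  attr(trace, "acceptance") <- ifelse(prop_attempt > 0,
                                      prop_accept / pmax(prop_attempt, 1), NA)
  attr(trace, "config") <- config
  class(trace) <- c("mcmc_trace", class(trace))
  trace
}
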