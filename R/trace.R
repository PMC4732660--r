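#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted samples containing
#' `ceiling(prob * n)` of them.
#'
#' @param samples Numeric vector (length >= 2).
#' @param prob Coverage fraction in (0, 1); default 0.95.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' hpd_interval(0:99, 0.95)
hpd_interval <- function(samples, prob = 0.95) {
  if (length(samples) < 2) stop_input("need at least 2 samples")
  if (!is.numeric(prob) || prob <= 0 || prob >= 1)
    stop_input("`prob` must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + m - 1])
}

#' Effective sample size of an MCMC series
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive consecutive pair (Geyer's initial positive sequence).
#' A constant series is degenerate: ESS is reported as `n` with attribute
#' `degenerate = TRUE`.
#'
#' @param series Numeric vector (length >= 10).
#' @return ESS (numeric scalar, possibly with a `degenerate` attribute).
#' @export
effective_sample_size <- function(series) {
  n <- length(series)
  if (n < 10) stop_input("need at least 10 samples")
  if (sd(series) == 0 || !is.finite(sd(series)))
    return(structure(as.numeric(n), degenerate = TRUE))
  max_lag <- min(n - 1, max(20, floor(10 * log10(n))) * 5)
  rho <- acf(series, lag.max = max_lag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(rho) - 1) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- n / (1 + 2 * s)
  min(ess, n)
}

#' Summarise an MCMC trace into per-node age summaries
#'
#' Discards the first `burnin_fraction` of samples and reports, per internal
#' node, the posterior median and 95% HPD of its age.
#'
#' @param trace A trace tibble from [run_mcmc()] (carries a `node_keys`
#'   attribute mapping `age_*` columns to frozen tip-set keys).
#' @param burnin_fraction Fraction of samples to discard (default 0.5).
#' @param prob HPD coverage (default 0.95).
#' @return A tibble with columns `node_key`, `n_tips`, `median`, `hpd_lo`,
#'   `hpd_hi`, `ci_width`, of class `node_summary`.
#' @export
summarize_trace <- function(trace, burnin_fraction = 0.5, prob = 0.95) {
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop_input("`burnin_fraction` must be in [0, 1)")
  keys <- attr(trace, "node_keys")
  if (is.null(keys)) stop_input("trace has no node_keys attribute")
  keep <- seq_len(nrow(trace)) > floor(burnin_fraction * nrow(trace))
  if (sum(keep) < 2)
    stop_input("no samples remain after burn-in")
  post <- trace[keep, , drop = FALSE]
  out <- purrr::map_dfr(names(keys), function(col) {
    x <- post[[col]]
    h <- hpd_interval(x, prob)
    tibble::tibble(node_key = keys[[col]], median = median(x),
                   hpd_lo = h[["lo"]], hpd_hi = h[["hi"]])
  })
  out <- dplyr::mutate(out,
    n_tips = vapply(strsplit(.data$node_key, ";", fixed = TRUE), length, 1L),
    ci_width = .data$hpd_hi - .data$hpd_lo)
  out <- dplyr::relocate(out, "node_key", "n_tips")
  class(out) <- c("node_summary", class(out))
  out
}
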