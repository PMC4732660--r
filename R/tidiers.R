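#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a secondary-calibration experiment
#'
#' One row per matched node per secondary analysis: the signed
#' primary-minus-secondary differences in HPD median, minimum, maximum and CI
#' width, with the replicate id, arm and standardised node age.
#'
#' @param x A `seccal_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.seccal_experiment <- function(x, ...) {
  x$node_diffs
}

#' One-row overview of a secondary-calibration experiment
#'
#' @param x A `seccal_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A one-row tibble: replicate counts, the uniform-arm proportion of
#'   significant paired t tests (raw and Bonferroni-corrected), and the
#'   pooled CI-width paired t test.
#' @export
glance.seccal_experiment <- function(x, ...) {
  uni <- dplyr::filter(x$replicate_comparisons, .data$arm == "uniform")
  tibble::tibble(
    n_secondary = nrow(x$replicate_comparisons),
    n_uniform = nrow(uni),
    prop_significant = mean(uni$significant[uni$t_defined]),
    prop_significant_bonferroni =
      mean(uni$significant_bonferroni[uni$t_defined]),
    pooled_width_t = x$pooled_width_test$t,
    pooled_width_df = x$pooled_width_test$df,
    pooled_width_p = x$pooled_width_test$p)
}

#' Tidy an MCMC trace
#'
#' @param x An `mcmc_trace` from [run_mcmc()].
#' @param ... Unused.
#' @return The trace as a plain tibble.
#' @export
tidy.mcmc_trace <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Convergence overview of an MCMC trace
#'
#' Post-burn-in effective sample sizes of the likelihood, prior and root age.
#'
#' @param x An `mcmc_trace` from [run_mcmc()].
#' @param burnin_fraction Burn-in fraction (default from the run's config).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mcmc_trace <- function(x, burnin_fraction = NULL, ...) {
  cfg <- attr(x, "config")
  b <- burnin_fraction %||% (if (!is.null(cfg)) cfg$burnin_fraction else 0.5)
  keep <- seq_len(nrow(x)) > floor(b * nrow(x))
  post <- x[keep, , drop = FALSE]
  age_cols <- grep("^age_", names(post), value = TRUE)
  root_col <- age_cols[1]
  tibble::tibble(
    n_samples = nrow(post),
    ess_likelihood = effective_sample_size(post$log_likelihood),
    ess_prior = effective_sample_size(post$log_prior),
    ess_root_age = effective_sample_size(post[[root_col]]))
}
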