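#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-node differences against standardised node age
#'
#' The uniform-arm analogue of the standardised-node-age panels: signed
#' primary-minus-secondary differences (median, HPD minimum, HPD maximum, CI
#' width) against node age standardised so the clade root is 1 and the tips
#' are 0. Positive values mean younger (or, for width, narrower) secondary
#' estimates.
#'
#' @param node_diffs A [node_differences()]-shaped tibble (e.g.
#'   `experiment$node_diffs`).
#' @param arm_filter Arm to display (default `"uniform"`).
#' @return A ggplot.
#' @export
plot_node_differences <- function(node_diffs, arm_filter = "uniform") {
  df <- node_diffs
  if ("arm" %in% names(df))
    df <- dplyr::filter(df, .data$arm == arm_filter)
  long <- tidyr::pivot_longer(df, c("d_median", "d_min", "d_max", "d_width"),
                              names_to = "measure", values_to = "difference")
  ggplot2::ggplot(long, ggplot2::aes(.data$std_age, .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "standardised node age (root = 1, tips = 0)",
                  y = "primary - secondary (time units)")
}

#' Plot primary vs secondary median node ages
#'
#' Points below the identity line are nodes estimated younger in the
#' secondary analysis.
#'
#' @param matched_all A row-bound [match_nodes()] tibble (e.g.
#'   `experiment$matched_all`).
#' @return A ggplot.
#' @export
plot_median_comparison <- function(matched_all) {
  ggplot2::ggplot(matched_all,
                  ggplot2::aes(.data$primary_median, .data$secondary_median)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "primary median age", y = "secondary median age")
}

#' Plot per-replicate summed differences against clade size or age
#'
#' @param replicate_comparisons The `replicate_comparisons` tibble of a
#'   [run_experiment()] result.
#' @param predictor `"n_tips"` or `"root_age"`.
#' @return A ggplot.
#' @export
plot_replicate_sums <- function(replicate_comparisons,
                                predictor = c("n_tips", "root_age")) {
  predictor <- match.arg(predictor)
  long <- tidyr::pivot_longer(
    replicate_comparisons,
    c("sum_abs_min", "sum_abs_max", "sum_abs_median", "sum_abs_width"),
    names_to = "measure", values_to = "summed_abs_difference")
  ggplot2::ggplot(long, ggplot2::aes(.data[[predictor]],
                                     .data$summed_abs_difference,
                                     colour = .data$arm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = predictor, y = "summed |primary - secondary|")
}

#' Autoplot a secondary-calibration experiment
#'
#' @param object A `seccal_experiment`.
#' @param type `"differences"` (standardised node-age panels),
#'   `"medians"` (primary vs secondary medians) or `"sums"` (per-replicate
#'   summed differences vs tip count).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seccal_experiment <- function(object,
                                       type = c("differences", "medians",
                                                "sums"), ...) {
  type <- match.arg(type)
  switch(type,
    differences = plot_node_differences(object$node_diffs),
    medians = plot_median_comparison(object$matched_all),
    sums = plot_replicate_sums(object$replicate_comparisons))
}

#' Autoplot an MCMC trace
#'
#' Trace panels for the likelihood, prior and root age.
#'
#' @param object An `mcmc_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcmc_trace <- function(object, ...) {
  root_col <- grep("^age_", names(object), value = TRUE)[1]
  df <- tibble::tibble(generation = object$generation,
                       log_likelihood = object$log_likelihood,
                       log_prior = object$log_prior,
                       root_age = object[[root_col]])
  long <- tidyr::pivot_longer(df, -"generation")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL)
}
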