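#' Per-node differences between primary and secondary summaries
#'
#' Signed differences, always primary minus secondary, so positive
#' `d_median` means the secondary estimate is younger and positive `d_width`
#' means the secondary credible interval is narrower. `std_age` is the
#' primary median age standardised by the primary median of the clade root
#' (root = 1, tips -> 0).
#'
#' @param matched Output of [match_nodes()] (>= 1 row).
#' @return A tibble with columns `node_key`, `n_tips`, `std_age`, `d_median`,
#'   `d_min`, `d_max`, `d_width`.
#' @export
node_differences <- function(matched) {
  if (!is.data.frame(matched) || nrow(matched) < 1)
    stop_input("`matched` must have at least one matched pair")
  root_median <- matched$primary_median[which.max(matched$n_tips)]
  dplyr::transmute(matched,
    node_key = .data$node_key,
    n_tips = .data$n_tips,
    std_age = standardized_node_ages(.data$primary_median, root_median),
    d_median = .data$primary_median - .data$secondary_median,
    d_min = .data$primary_hpd_lo - .data$secondary_hpd_lo,
    d_max = .data$primary_hpd_hi - .data$secondary_hpd_hi,
    d_width = .data$primary_ci_width - .data$secondary_ci_width)
}

#' Summed absolute differences of a replicate
#'
#' @param diffs Output of [node_differences()].
#' @return A one-row tibble with `sum_abs_min`, `sum_abs_max`,
#'   `sum_abs_median`, `sum_abs_width`.
#' @export
summed_absolute_differences <- function(diffs) {
  if (!is.data.frame(diffs) || nrow(diffs) < 1)
    stop_input("`diffs` must have at least one row")
  tibble::tibble(
    sum_abs_min = sum(abs(diffs$d_min)),
    sum_abs_max = sum(abs(diffs$d_max)),
    sum_abs_median = sum(abs(diffs$d_median)),
    sum_abs_width = sum(abs(diffs$d_width)))
}

#' Paired Student's t test
#'
#' Two-sided paired t test of `x` against `y` (via [stats::t.test()]). A
#' zero-variance difference vector yields an explicit undefined result
#' (`defined = FALSE`, `p = NA`) rather than an infinite statistic.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_diff`, `defined`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_input("`x` and `y` must have equal length >= 2")
  d <- x - y
  if (sd(d) == 0) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1, p = NA_real_,
                          mean_diff = mean(d), defined = FALSE))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate),
                 defined = TRUE)
}

#' Bonferroni significance flags
#'
#' Flag i is `TRUE` iff `p[i] < alpha / length(p)`. `NA` p-values give `NA`
#' flags.
#'
#' @param p_values Numeric vector of p values.
#' @param alpha Family-wise significance level in (0, 1).
#' @return Logical vector.
#' @export
bonferroni_flags <- function(p_values, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1)")
  p_values < alpha / length(p_values)
}

#' Pooled credible-interval-width test
#'
#' Paired t test of primary vs secondary 95% CI widths pooled over every
#' matched node of every replicate. A positive statistic means secondary
#' intervals are narrower on average.
#'
#' @param matched_all Row-bound [match_nodes()] output across replicates.
#' @return A one-row tibble as in [paired_t_test()].
#' @export
pooled_ci_width_test <- function(matched_all) {
  if (nrow(matched_all) < 2) stop_input("need >= 2 pooled pairs")
  paired_t_test(matched_all$primary_ci_width, matched_all$secondary_ci_width)
}

#' Standardise node ages by the root age
#'
#' @param node_ages Ages (all `<= root_age`).
#' @param root_age Root age (> 0).
#' @return `node_ages / root_age` (root -> 1, tips -> 0).
#' @export
standardized_node_ages <- function(node_ages, root_age) {
  check_number(root_age, "`root_age`", positive = TRUE)
  if (any(node_ages > root_age * (1 + 1e-9)))
    stop_input("node ages exceed the root age")
  node_ages / root_age
}

#' Regress per-replicate summed differences on clade age and size
#'
#' Ordinary least squares of each summed-absolute-difference response on each
#' predictor, with a Bonferroni correction over the family of fitted models
#' (responses x predictors; 4 x 2 = 8 by default).
#'
#' @param replicate_comparisons Tibble with the `sum_abs_*` columns plus the
#'   predictor columns (see [run_experiment()]).
#' @param predictors Predictor column names (default clade root age and tip
#'   count).
#' @param alpha Family-wise level for the Bonferroni flags.
#' @return A tibble: `response`, `predictor`, `slope`, `intercept`, `p`,
#'   `p_bonferroni`, `significant`; rows with an undefined fit (constant
#'   predictor) carry `NA` and `defined = FALSE`.
#' @export
regress_summaries <- function(replicate_comparisons,
                              predictors = c("root_age", "n_tips"),
                              alpha = 0.05) {
  if (nrow(replicate_comparisons) < 3) stop_input("need >= 3 replicates")
  responses <- c("sum_abs_min", "sum_abs_max", "sum_abs_median",
                 "sum_abs_width")
  grid <- tidyr::expand_grid(response = responses, predictor = predictors)
  out <- purrr::pmap_dfr(grid, function(response, predictor) {
    x <- replicate_comparisons[[predictor]]
    y <- replicate_comparisons[[response]]
    if (sd(x) == 0) {
      return(tibble::tibble(response, predictor, slope = NA_real_,
                            intercept = NA_real_, p = NA_real_,
                            defined = FALSE))
    }
    fit <- lm(y ~ x)
    ct <- summary(fit)$coefficients
    p <- if (nrow(ct) == 2 && !is.nan(ct[2, 4])) ct[2, 4] else NA_real_
    tibble::tibble(response, predictor, slope = coef(fit)[[2]],
                   intercept = coef(fit)[[1]], p = p, defined = TRUE)
  })
  m <- nrow(out)
  dplyr::mutate(out, p_bonferroni = pmin(1, .data$p * m),
                significant = bonferroni_flags(.data$p, alpha))
}
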