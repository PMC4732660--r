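make_matched_row <- function(pm, plo, phi, sm, slo, shi) {
  tibble::tibble(node_key = "k1", n_tips = 3,
                 primary_median = pm, primary_hpd_lo = plo,
                 primary_hpd_hi = phi, primary_ci_width = phi - plo,
                 secondary_median = sm, secondary_hpd_lo = slo,
                 secondary_hpd_hi = shi, secondary_ci_width = shi - slo)
}

test_that("node differences follow the primary-minus-secondary convention", {
  m <- make_matched_row(10, 8, 14, 9, 8.5, 12)
  d <- node_differences(m)
  expect_equal(d$d_median, 1)    # secondary younger -> positive
  expect_equal(d$d_min, -0.5)
  expect_equal(d$d_max, 2)
  expect_equal(d$d_width, 2.5)   # secondary narrower -> positive
  ident <- node_differences(make_matched_row(10, 8, 14, 10, 8, 14))
  expect_equal(unlist(ident[, c("d_median", "d_min", "d_max", "d_width")]),
               c(d_median = 0, d_min = 0, d_max = 0, d_width = 0))
  older <- node_differences(make_matched_row(10, 8, 14, 12, 9, 15))
  expect_lt(older$d_median, 0)
})

test_that("summed absolute differences use magnitudes, not net values", {
  d0 <- tibble::tibble(d_min = c(0, 0), d_max = c(0, 0),
                       d_median = c(0, 0), d_width = c(0, 0))
  expect_equal(unlist(summed_absolute_differences(d0)),
               c(sum_abs_min = 0, sum_abs_max = 0, sum_abs_median = 0,
                 sum_abs_width = 0))
  d <- tibble::tibble(d_min = c(1, -1), d_max = c(2, -3),
                      d_median = c(1, -1), d_width = c(-0.5, 0.25))
  s <- summed_absolute_differences(d)
  expect_equal(s$sum_abs_median, 2)
  expect_equal(s$sum_abs_max, 5)
  expect_equal(s$sum_abs_width, 0.75)
  # spreadsheet-style recomputation on a random 5-node fixture
  set.seed(91)
  d5 <- tibble::tibble(d_min = rnorm(5), d_max = rnorm(5),
                       d_median = rnorm(5), d_width = rnorm(5))
  s5 <- summed_absolute_differences(d5)
  expect_equal(s5$sum_abs_min, sum(abs(d5$d_min)))
  expect_equal(s5$sum_abs_width, sum(abs(d5$d_width)))
})

test_that("paired t test matches the closed form and flags degeneracy", {
  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$defined)
  expect_true(is.na(same$p))
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("paired t p-values are uniform under the null", {
  set.seed(92)
  ps <- replicate(400, paired_t_test(rnorm(20), rnorm(20))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("Bonferroni flags compare against alpha over the family size", {
  expect_identical(bonferroni_flags(c(0.03), 0.05), TRUE)
  p <- c(4e-4, 6e-4, rep(0.5, 98))
  flags <- bonferroni_flags(p, 0.05)  # threshold 5e-4 at m = 100
  expect_identical(flags[1:2], c(TRUE, FALSE))
  expect_false(any(flags[-(1:2)]))
  expect_error(bonferroni_flags(0.5, 1.2), "alpha")
})

test_that("pooled width test has pooled degrees of freedom and direction", {
  set.seed(93)
  n <- 200
  pooled <- dplyr::bind_rows(lapply(1:4, function(i) {
    w <- runif(n / 4, 2, 6)
    make_matched_row(10, 8, 14, 9, 8.5, 12)[rep(1, n / 4), ] |>
      dplyr::mutate(primary_ci_width = w,
                    secondary_ci_width = w - abs(rnorm(n / 4, 1, 0.3)))
  }))
  r <- pooled_ci_width_test(pooled)
  expect_equal(r$df, n - 1)
  expect_gt(r$t, 0)  # secondary systematically narrower -> positive t
  expect_lt(r$p, 0.01)
  same <- pooled_ci_width_test(
    dplyr::mutate(pooled, secondary_ci_width = primary_ci_width))
  expect_false(same$defined)
})

test_that("standardised node ages map root to 1 and preserve order", {
  expect_equal(standardized_node_ages(c(70, 35, 0), 70), c(1, 0.5, 0))
  x <- sort(runif(20, 0, 50))
  expect_true(all(diff(standardized_node_ages(x, 50)) >= 0))
  expect_error(standardized_node_ages(c(80), 70), "exceed")
})

test_that("regressions recover exact and noisy coefficients", {
  rc <- tibble::tibble(
    root_age = seq(10, 60, length.out = 40),
    n_tips = rep(20, 40),
    sum_abs_min = 2 * seq(10, 60, length.out = 40) + 5,
    sum_abs_max = 3 * seq(10, 60, length.out = 40) - 1,
    sum_abs_median = seq(10, 60, length.out = 40),
    sum_abs_width = 0.5 * seq(10, 60, length.out = 40))
  out <- suppressWarnings(regress_summaries(rc, predictors = "root_age"))
  expect_equal(out$slope, c(2, 3, 1, 0.5), tolerance = 1e-10)
  expect_equal(out$intercept, c(5, -1, 0, 0), tolerance = 1e-8)
  expect_true(all(out$p < 1e-10))
  # constant predictor -> undefined fit
  out2 <- regress_summaries(rc, predictors = "n_tips")
  expect_true(all(!out2$defined))
  # known slope under noise, n = 200
  set.seed(94)
  x <- runif(200, 0, 100)
  rc3 <- tibble::tibble(root_age = x, n_tips = rpois(200, 30) + 2,
                        sum_abs_min = x + rnorm(200),
                        sum_abs_max = x + rnorm(200),
                        sum_abs_median = x + rnorm(200),
                        sum_abs_width = x + rnorm(200))
  out3 <- regress_summaries(rc3, predictors = "root_age")
  fit_se <- summary(lm(rc3$sum_abs_median ~ x))$coefficients[2, 2]
  expect_true(all(abs(out3$slope - 1) < 3 * fit_se + 1e-6))
})

test_that("regression p-values are uniform under the null", {
  set.seed(95)
  ps <- replicate(300, {
    y <- rnorm(30)
    x <- rnorm(30)
    summary(lm(y ~ x))$coefficients[2, 4]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("differences are antisymmetric and scale-equivariant", {
  for (seed in c(96, 97, 98)) {
    m <- random_matched(12, seed)
    d <- node_differences(m)
    dsw <- node_differences(swap_matched(m))
    for (col in c("d_median", "d_min", "d_max", "d_width"))
      expect_equal(dsw[[col]], -d[[col]])
    expect_equal(as.data.frame(summed_absolute_differences(dsw)),
                 as.data.frame(summed_absolute_differences(d)))
    # scaling all ages by c scales sums, keeps t, p and standardised ages
    c_ <- 3.7
    msc <- m
    for (col in grep("primary_|secondary_", names(m), value = TRUE))
      msc[[col]] <- m[[col]] * c_
    dsc <- node_differences(msc)
    expect_equal(dsc$d_median, c_ * d$d_median)
    expect_equal(dsc$std_age, d$std_age)
    expect_equal(as.numeric(summed_absolute_differences(dsc)[1, 1:4]),
                 c_ * as.numeric(summed_absolute_differences(d)[1, 1:4]))
    t1 <- paired_t_test(m$primary_median, m$secondary_median)
    t2 <- paired_t_test(msc$primary_median, msc$secondary_median)
    expect_equal(t1$t, t2$t, tolerance = 1e-10)
    expect_equal(t1$p, t2$p, tolerance = 1e-10)
  }
})

test_that("per-replicate paired t matches an independent TSV recomputation", {
  m <- random_matched(15, 99)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(m, path, progress = FALSE)
  raw <- utils::read.delim(path)
  d <- raw$primary_median - raw$secondary_median
  t_indep <- mean(d) / (sd(d) / sqrt(length(d)))
  p_indep <- 2 * pt(-abs(t_indep), length(d) - 1)
  r <- paired_t_test(m$primary_median, m$secondary_median)
  expect_equal(r$t, t_indep, tolerance = 1e-9)
  expect_equal(r$p, p_indep, tolerance = 1e-9)
})
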