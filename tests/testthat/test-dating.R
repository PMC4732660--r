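test_that("pruning likelihood equals exhaustive state enumeration", {
  p <- default_hky()
  tt3 <- time_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  tt4 <- time_tree(ape::read.tree(text = "((a:1,b:1):1.5,(c:2,d:2):0.5);"))
  set.seed(21)
  for (tt in list(tt3, tt4)) {
    st <- strict_clock_subst_tree(tt, 0.3)
    aln <- simulate_alignment(st, p, 4, seed = 22)
    expect_equal(pruning_log_likelihood(tt, 0.3, p, aln),
                 enumeration_loglik(tt, 0.3, p, aln), tolerance = 1e-10)
  }
})

test_that("zero branch lengths give log stationary frequency", {
  p <- default_hky()
  tt <- time_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  aln <- matrix("C", 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(pruning_log_likelihood(tt, 0, p, aln),
               log(p$base_freqs[2]), tolerance = 1e-12)
})

test_that("likelihood is invariant to a joint rate-time rescale", {
  p <- default_hky()
  tr <- rescale_to_age(simulate_pure_birth(8, 0.7, seed = 23), 70)
  aln <- simulate_alignment(strict_clock_subst_tree(tr, 0.01), p, 60,
                            seed = 24)
  base <- pruning_log_likelihood(tr, 0.01, p, aln)
  scaled <- pruning_log_likelihood(rescale_to_age(tr, 70 / 3), 0.03, p, aln)
  expect_equal(base, scaled, tolerance = 1e-9)
})

test_that("likelihood rejects a taxon mismatch", {
  p <- default_hky()
  tt <- time_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  aln <- matrix("A", 3, 2, dimnames = list(c("a", "b", "x"), NULL))
  expect_error(pruning_log_likelihood(tt, 0.1, p, aln), "match")
})

test_that("Yule prior matches the generating construction's density", {
  # 2-tip tree: root age is the gap below the only split, Exp(birth_rate)
  lam <- 0.7
  for (t in c(0.3, 1, 4)) {
    tt <- time_tree(ape::read.tree(text = sprintf("(a:%g,b:%g);", t, t)))
    expect_equal(yule_log_prior(tt, lam), dexp(t, lam, log = TRUE),
                 tolerance = 1e-12)
  }
  # general n: density of gaps Exp(j * lambda) times the uniform
  # ranked-history factor 1/(n-1)!
  set.seed(25)
  for (i in 1:5) {
    tr <- simulate_pure_birth(9, lam)
    a <- sort(tr$ages[tr$ages > 0], decreasing = TRUE)
    gaps <- c(-diff(a), a[length(a)])
    expect_equal(yule_log_prior(tr, lam),
                 sum(dexp(gaps, seq_along(gaps) * lam, log = TRUE)) -
                   lfactorial(length(gaps)),
                 tolerance = 1e-10)
  }
})

test_that("Yule prior is -Inf outside the age-ordering support", {
  tr <- simulate_pure_birth(6, 0.7, seed = 26)
  expect_true(is.finite(yule_log_prior(tr, 0.7)))
  bad <- tr
  root <- ape::Ntip(tr$phylo) + 1L
  bad$ages[root] <- min(bad$ages[bad$ages > 0]) / 2
  expect_identical(yule_log_prior(bad, 0.7), -Inf)
})

test_that("UCLN rate density: closed form, independence, normalisation", {
  mu <- log(0.02)
  expect_equal(ucln_rate_log_density(exp(mu), mu, 1),
               -mu - 0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(27)
  r <- rlnorm(6, mu, 0.8)
  expect_equal(ucln_rate_log_density(r, mu, 0.8),
               sum(vapply(r, ucln_rate_log_density, 1, mean_log = mu,
                          sd_log = 0.8)), tolerance = 1e-12)
  z <- integrate(function(x) exp(vapply(x, ucln_rate_log_density, 1,
                                        mean_log = mu, sd_log = 0.8)),
                 0, Inf, rel.tol = 1e-9)
  expect_equal(z$value, 1, tolerance = 1e-6)
  full <- ucln_log_prior(list(rates = r, ucln_mean = mu, ucln_sd = 0.8))
  expect_true(is.finite(full))
  expect_error(ucln_log_prior(list(rates = r, ucln_mean = mu, ucln_sd = -1)),
               "ucln_sd")
})

test_that("calibration densities follow their stated forms", {
  u <- calibration_prior("k", "uniform", lo = 2, hi = 10)
  expect_equal(calibration_log_prior(u, 5), -log(8))
  expect_identical(calibration_log_prior(u, 11), -Inf)
  ln <- calibration_prior("k", "lognormal", meanlog = log(12), sdlog = 1)
  expect_equal(plnorm(12, log(12), 1), 0.5)
  expect_equal(calibration_log_prior(ln, 12),
               dlnorm(12, log(12), 1, log = TRUE))
  nm <- calibration_prior("k", "normal", mean = 10, sd = 1)
  expect_equal(calibration_log_prior(nm, 10), -log(sqrt(2 * pi)),
               tolerance = 1e-10)
  expect_error(calibration_log_prior(u, -1), "age")
})

test_that("HPD intervals are the shortest windows", {
  expect_equal(unname(hpd_interval(rep(3, 10), 0.95)), c(3, 3))
  h <- hpd_interval(0:99, 0.95)
  expect_equal(unname(h[2] - h[1]), 94)
  expect_equal(unname(h), brute_force_hpd(0:99, 0.95))
  set.seed(28)
  for (i in 1:50) {
    x <- switch(1 + i %% 3, rnorm(60), rexp(35), rlnorm(120))
    expect_equal(unname(hpd_interval(x, 0.9)), brute_force_hpd(x, 0.9))
  }
  expect_error(hpd_interval(1), "2 samples")
})

test_that("HPD width of a large uniform sample is about the coverage", {
  set.seed(29)
  h <- hpd_interval(runif(2e5), 0.95)
  expect_lt(abs((h[2] - h[1]) - 0.95), 0.01)
})

test_that("effective sample size recovers i.i.d. and AR(1) benchmarks", {
  set.seed(30)
  x <- rnorm(10000)
  expect_lt(abs(effective_sample_size(x) - 10000) / 10000, 0.10)
  rho <- 0.8
  ar <- as.numeric(arima.sim(list(ar = rho), 20000))
  expected <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - expected) / expected, 0.15)
  const <- effective_sample_size(rep(2, 100))
  expect_equal(as.numeric(const), 100)
  expect_true(attr(const, "degenerate"))
})

test_that("trace summaries survive a TSV round trip", {
  tr <- simulate_pure_birth(5, 0.7, seed = 31)
  cfg <- mcmc_config(chain_length = 2000, sample_every = 10, seed = 32,
                     clock_model = "strict", estimate_clock_rate = FALSE,
                     estimate_kappa = FALSE, estimate_freqs = FALSE,
                     use_likelihood = FALSE, birth_rate = 0.7)
  trace <- run_mcmc(NULL, tr, list(), default_hky(), cfg)
  s1 <- summarize_trace(trace, 0.5)
  expect_true(all(s1$hpd_lo <= s1$median & s1$median <= s1$hpd_hi))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(trace, path)
  s2 <- summarize_trace(read_trace_tsv(path), 0.5)
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-9)
  # independent recomputation from the raw columns
  post <- as.data.frame(trace)[-(1:floor(nrow(trace) / 2)), ]
  keys <- attr(trace, "node_keys")
  for (col in names(keys)) {
    row <- s1[s1$node_key == keys[[col]], ]
    expect_equal(row$median, median(post[[col]]))
    expect_equal(unname(hpd_interval(post[[col]], 0.95)),
                 c(row$hpd_lo, row$hpd_hi))
  }
})

test_that("a constant trace collapses to a point summary", {
  tr <- simulate_pure_birth(4, 0.7, seed = 33)
  cfg <- mcmc_config(chain_length = 100, sample_every = 10, seed = 34,
                     clock_model = "strict", estimate_clock_rate = FALSE,
                     estimate_kappa = FALSE, estimate_freqs = FALSE,
                     use_likelihood = FALSE, birth_rate = 0.7,
                     move_weights = c(age_slide = 0, age_window = 0,
                                      root_scale = 0, tree_scale = 1e-9))
  trace <- run_mcmc(NULL, tr, list(), default_hky(), cfg)
  trace_const <- trace
  for (col in grep("^age_", names(trace), value = TRUE))
    trace_const[[col]] <- trace[[col]][1]
  s <- summarize_trace(trace_const, 0.5)
  expect_equal(s$hpd_lo, s$median)
  expect_equal(s$hpd_hi, s$median)
  expect_equal(s$ci_width, rep(0, nrow(s)))
})
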