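test_that("minimal pure-birth tree is a single cherry", {
  tr <- simulate_pure_birth(2, 0.7, seed = 1)
  expect_equal(tr$phylo$Nnode, 1L)
  expect_equal(ape::Ntip(tr$phylo), 2L)
  expect_equal(unname(tr$ages[1:2]), c(0, 0))
  expect_gt(tr$root_age, 0)
})

test_that("a 1500-tip phylogeny has 1499 internal nodes", {
  tr <- simulate_pure_birth(1500, 0.7, seed = 3)
  expect_equal(tr$phylo$Nnode, 1499L)
  expect_s3_class(tr, "time_tree")
})

test_that("pure-birth trees are ultrametric and reject bad parameters", {
  for (seed in 1:5) {
    tr <- simulate_pure_birth(25, 0.7, seed = seed)
    d <- ape::node.depth.edgelength(tr$phylo)[1:25]
    expect_lt(max(abs(d - tr$root_age)) / tr$root_age, 1e-9)
  }
  expect_error(simulate_pure_birth(1, 0.7), "n_tips")
  expect_error(simulate_pure_birth(10, -1), "birth_rate")
})

test_that("mean root age follows the Yule depth law", {
  # E[root age] = sum_{k=1}^{n-1} 1/(k * lambda) under the generating
  # construction; checked by Monte Carlo within 3 standard errors.
  n <- 10; lam <- 0.7; reps <- 2000
  set.seed(41)
  roots <- replicate(reps, simulate_pure_birth(n, lam)$root_age)
  expected <- sum(1 / (lam * (1:(n - 1))))
  se <- sqrt(sum(1 / (lam * (1:(n - 1)))^2)) / sqrt(reps)
  expect_lt(abs(mean(roots) - expected), 3 * se)
})

test_that("rescaling is the identity at the current root age and linear", {
  tr <- simulate_pure_birth(12, 0.7, seed = 2)
  same <- rescale_to_age(tr, tr$root_age)
  expect_equal(same$ages, tr$ages)
  tr35 <- rescale_to_age(tr, 35)
  tr70 <- rescale_to_age(tr35, 70)
  expect_equal(unname(tr70$ages), unname(tr35$ages) * 2)
  expect_equal(tr70$root_age, 70)
  expect_error(rescale_to_age(tr, -1), "root_age")
})

test_that("strict clock branch lengths are duration times rate", {
  tr <- rescale_to_age(simulate_pure_birth(20, 0.7, seed = 4), 70)
  st <- strict_clock_subst_tree(tr, 0.01)
  # root-to-tip path length = 70 * 0.01 = 0.7 expected substitutions/site
  d <- ape::node.depth.edgelength(st$phylo)[1:20]
  expect_equal(d, rep(0.7, 20), tolerance = 1e-9)
  ident <- strict_clock_subst_tree(tr, 1)
  expect_equal(ident$phylo$edge.length, ident$durations)
  st2 <- strict_clock_subst_tree(tr, 0.02)
  expect_equal(st2$phylo$edge.length, 2 * st$phylo$edge.length)
  expect_error(strict_clock_subst_tree(tr, 0), "clock_rate")
})

test_that("rate-length consistency holds for every substitution tree", {
  tr <- rescale_to_age(simulate_pure_birth(30, 0.7, seed = 5), 70)
  for (st in list(strict_clock_subst_tree(tr, 0.013),
                  ucln_subst_tree(tr, 0.02, 2.017, seed = 6))) {
    expect_equal(st$phylo$edge.length / st$durations, st$rates,
                 tolerance = 1e-12)
    expect_true(all(st$phylo$edge.length >= 0))
    expect_identical(st$phylo$edge, tr$phylo$edge)
  }
})

test_that("UCLN branch rates have the requested real-space mean", {
  tr <- simulate_pure_birth(251, 0.7, seed = 7)  # 500 branches per draw
  rates <- unlist(lapply(1:20, function(i)
    ucln_subst_tree(tr, 0.02, 2.017, seed = 100 + i)$rates))
  expect_gte(length(rates), 10000)
  sd_real <- 0.02 * sqrt(exp(2.017^2) - 1)
  se <- sd_real / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.02), 3 * se)
  # degenerate sd: identical to the strict clock
  expect_equal(ucln_subst_tree(tr, 0.02, 0)$phylo$edge.length,
               strict_clock_subst_tree(tr, 0.02)$phylo$edge.length)
})
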