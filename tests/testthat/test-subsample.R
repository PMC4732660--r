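test_that("clade extraction respects size limits and distinctness", {
  tr <- rescale_to_age(simulate_pure_birth(120, 0.7, seed = 71), 70)
  reps <- extract_random_clades(tr, 10, 10, seed = 72)
  expect_equal(nrow(reps), 10L)
  expect_equal(anyDuplicated(reps$node_key), 0L)
  expect_true(all(reps$n_tips >= 10))
  for (i in seq_len(nrow(reps))) {
    st <- reps$subtree[[i]]
    expect_s3_class(st, "time_tree")
    expect_equal(ape::Ntip(st$phylo), reps$n_tips[i])
    expect_equal(tip_key(st$phylo$tip.label), reps$node_key[i])
    expect_equal(st$root_age, reps$root_age[i], tolerance = 1e-9)
  }
})

test_that("eligibility counting is exhaustive on a known topology", {
  # balanced 31-tip tree: the root's children subtend 16 and 15 tips, so at
  # min_tips = 20 only the root qualifies
  bal <- balanced_time_tree(31)
  expect_error(extract_random_clades(bal, 2, 20, seed = 73), "only 1")
  one <- extract_random_clades(bal, 1, 20, seed = 73)
  expect_equal(one$n_tips, 31L)
  # at min_tips = 16 exactly the root and its 16-tip child qualify
  two <- extract_random_clades(bal, 2, 16, seed = 74)
  expect_setequal(two$n_tips, c(31L, 16L))
})

test_that("clade sampling is reproducible for a fixed seed", {
  tr <- rescale_to_age(simulate_pure_birth(80, 0.7, seed = 75), 70)
  r1 <- extract_random_clades(tr, 5, 8, seed = 76)
  r2 <- extract_random_clades(tr, 5, 8, seed = 76)
  expect_identical(r1$node_key, r2$node_key)
})

test_that("alignment restriction keeps all sites and exactly the tip set", {
  tr <- rescale_to_age(simulate_pure_birth(25, 0.7, seed = 77), 70)
  aln <- simulate_alignment(strict_clock_subst_tree(tr, 0.01),
                            default_hky(), 150, seed = 78)
  all_taxa <- restrict_alignment(aln, rownames(aln))
  expect_equal(dim(all_taxa), dim(aln))
  expect_equal(all_taxa[sort(rownames(aln)), ], aln[sort(rownames(aln)), ])
  sub <- restrict_alignment(aln, c("t3", "t1", "t8"))
  expect_equal(rownames(sub), c("t1", "t3", "t8"))
  expect_equal(ncol(sub), 150L)
  expect_error(restrict_alignment(aln, "nope"), "unknown")
})

test_that("node matching is a bijection keyed by tip sets", {
  tr <- rescale_to_age(simulate_pure_birth(60, 0.7, seed = 79), 70)
  truth <- true_node_ages(tr)
  fake_summary <- function(tt, jitter) {
    ages <- true_node_ages(tt)
    tibble::tibble(node_key = ages$node_key, n_tips = ages$n_tips,
                   median = ages$age + jitter, hpd_lo = ages$age - 1,
                   hpd_hi = ages$age + 1, ci_width = 2)
  }
  prim <- fake_summary(tr, 0)
  clade <- extract_random_clades(tr, 1, 20, seed = 80)
  sec <- fake_summary(clade$subtree[[1]], 0.5)
  matched <- match_nodes(prim, sec)
  expect_equal(nrow(matched), clade$n_tips[1] - 1L)
  expect_equal(matched$primary_median + 0.5, matched$secondary_median)
  # symmetric and idempotent under swapping roles
  swapped <- match_nodes(sec, prim[prim$node_key %in% sec$node_key, ])
  expect_setequal(swapped$node_key, matched$node_key)
  # unmatched keys are a consistency error
  sec_bad <- sec
  sec_bad$node_key[1] <- "not;a;real;clade"
  expect_error(match_nodes(prim, sec_bad), "no primary")
})

test_that("hand-built 4-tip matching agrees with brute-force comparison", {
  tt <- time_tree(ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);"))
  s <- true_node_ages(tt)
  summ <- tibble::tibble(node_key = s$node_key, n_tips = s$n_tips,
                         median = s$age, hpd_lo = s$age, hpd_hi = s$age,
                         ci_width = 0)
  matched <- match_nodes(summ, summ)
  expect_equal(nrow(matched), 3L)
  for (i in seq_len(nrow(matched))) {
    target <- strsplit(matched$node_key[i], ";", fixed = TRUE)[[1]]
    brute <- which(vapply(strsplit(summ$node_key, ";", fixed = TRUE),
                          setequal, TRUE, y = target))
    expect_length(brute, 1L)
    expect_equal(summ$median[brute], matched$primary_median[i])
  }
})
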