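# Fixture builders shared across test files. Everything is generated in code;
# no data files.

default_hky <- function() hky_params(2, c(0.30, 0.26, 0.23, 0.21))

# Independent HKY generator matrix (unnormalised entries kappa*pi_j for
# transitions, pi_j for transversions), scaled to one expected substitution
# per unit time. Used only to drive the matrix-exponential oracle.
hky_generator <- function(kappa, freqs) {
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- all(sort(c(i, j)) == c(1, 3)) || all(sort(c(i, j)) == c(2, 4))
    Q[i, j] <- (if (transition) kappa else 1) * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * freqs)
}

# Balanced ultrametric tree on n tips built by successive pairing; with
# n = 31 the root's children subtend 16 and 15 tips.
balanced_time_tree <- function(n) {
  items <- lapply(seq_len(n), function(i) list(s = paste0("t", i), h = 0))
  while (length(items) > 1) {
    nxt <- list()
    i <- 1
    while (i < length(items)) {
      a <- items[[i]]; b <- items[[i + 1]]
      h <- max(a$h, b$h) + 1
      nxt[[length(nxt) + 1]] <- list(
        s = paste0("(", a$s, ":", h - a$h, ",", b$s, ":", h - b$h, ")"),
        h = h)
      i <- i + 2
    }
    if (i == length(items)) nxt[[length(nxt) + 1]] <- items[[i]]
    items <- nxt
  }
  time_tree(ape::read.tree(text = paste0(items[[1]]$s, ";")))
}

# Exhaustive-enumeration HKY likelihood for small trees: sums the joint
# probability over all internal-state assignments, site by site. Fully
# independent of the pruning kernel.
enumeration_loglik <- function(tree, rate, params, alignment) {
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  internal <- (n + 1):(n + phy$Nnode)
  states <- 1:4
  f <- params$base_freqs
  edge <- phy$edge
  elen <- (tree$ages[edge[, 1]] - tree$ages[edge[, 2]]) * rate
  P <- lapply(seq_len(nrow(edge)),
              function(e) hky_transition_matrix(elen[e], params))
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  total <- 0
  for (s in seq_len(ncol(alignment))) {
    obs <- match(alignment[, s], c("A", "C", "G", "T"))
    site_p <- 0
    for (g in seq_len(nrow(grid))) {
      assign_all <- integer(n + phy$Nnode)
      assign_all[seq_len(n)] <- obs
      assign_all[internal] <- grid[g, ]
      p <- f[assign_all[n + 1]]
      for (e in seq_len(nrow(edge)))
        p <- p * P[[e]][assign_all[edge[e, 1]], assign_all[edge[e, 2]]]
      site_p <- site_p + p
    }
    total <- total + log(site_p)
  }
  total
}

# Brute-force shortest HPD window.
brute_force_hpd <- function(samples, prob) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(prob * n)
  best <- c(x[1], x[n])
  if (m >= n) return(best)
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# Random node-summary pair tables for compare-module property tests.
random_matched <- function(n_nodes, seed) {
  set.seed(seed)
  mk <- function() {
    med <- sort(runif(n_nodes, 1, 50), decreasing = TRUE)
    lo <- med - runif(n_nodes, 0.1, 5)
    hi <- med + runif(n_nodes, 0.1, 5)
    tibble::tibble(median = med, hpd_lo = pmax(lo, 0), hpd_hi = hi)
  }
  p <- mk(); s <- mk()
  tibble::tibble(
    node_key = paste0("k", seq_len(n_nodes)),
    n_tips = c(n_nodes + 1, sample(2:max(3, n_nodes), n_nodes - 1, TRUE)),
    primary_median = p$median, primary_hpd_lo = p$hpd_lo,
    primary_hpd_hi = p$hpd_hi, primary_ci_width = p$hpd_hi - p$hpd_lo,
    secondary_median = s$median, secondary_hpd_lo = s$hpd_lo,
    secondary_hpd_hi = s$hpd_hi, secondary_ci_width = s$hpd_hi - s$hpd_lo)
}

# Swap the primary/secondary roles of a matched table.
swap_matched <- function(matched) {
  out <- matched
  for (col in c("median", "hpd_lo", "hpd_hi", "ci_width")) {
    p <- paste0("primary_", col); s <- paste0("secondary_", col)
    tmp <- out[[p]]; out[[p]] <- out[[s]]; out[[s]] <- tmp
  }
  out
}

# The scaled-down end-to-end experiment shared by the acceptance tests: the
# full four-arm design on a 70-tip tree. Built once per test session.
acceptance_env <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(acceptance_env$ex)) {
    cfg <- experiment_config(
      "desk", n_tips = 70, n_sites = 500, n_clades = 7, min_tips = 10,
      n_primary_calibrations = 9,
      primary_chain_length = 1.5e5, primary_sample_every = 100,
      secondary_chain_length = 6e4, secondary_chain_length_large = 6e4,
      secondary_sample_every = 60,
      normal_every = 2, two_node_every = 3, relaxed_every = 4,
      relaxed_n_sites = 750, seed = 7)
    acceptance_env$ex <- suppressMessages(run_experiment(cfg))
  }
  acceptance_env$ex
}
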