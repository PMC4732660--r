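#' Ultrametric time trees
#'
#' A `time_tree` wraps an [ape::phylo] tree whose branch lengths are in time
#' units (tips contemporaneous at age 0) together with the node ages implied by
#' them. Internal node ages strictly exceed the ages of their children and the
#' root age equals the tree depth.
#'
#' @param phylo A rooted, fully bifurcating ultrametric [ape::phylo] object
#'   with branch lengths in time units.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An object of class `time_tree`: a list with elements `phylo`,
#'   `ages` (named by ape node number; tips exactly 0) and `root_age`.
#' @export
time_tree <- function(phylo, tol = 1e-8) {
  if (!inherits(phylo, "phylo")) stop_input("`phylo` must be an ape phylo object")
  if (is.null(phylo$edge.length)) stop_input("tree has no branch lengths")
  if (!ape::is.binary(phylo)) stop_input("tree must be fully bifurcating")
  n <- ape::Ntip(phylo)
  depth <- ape::node.depth.edgelength(phylo)
  root_age <- max(depth[seq_len(n)])
  tipdev <- abs(depth[seq_len(n)] - root_age)
  if (any(tipdev > tol * max(root_age, 1)))
    stop_input("tree is not ultrametric (tip depth spread ",
               format(max(tipdev)), ")")
  ages <- root_age - depth
  ages[seq_len(n)] <- 0
  names(ages) <- as.character(seq_along(ages))
  structure(list(phylo = phylo, ages = ages, root_age = root_age),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("<time_tree> ", ape::Ntip(x$phylo), " tips, root age ",
      format(x$root_age, digits = 6), "\n", sep = "")
  invisible(x)
}

root_node <- function(tree) ape::Ntip(tree$phylo) + 1L

#' Frozen tip-set keys for every internal node
#'
#' @param tree A [time_tree()].
#' @return Named character vector: names are internal node numbers, values the
#'   [tip_key()] of the tips each node subtends.
#' @export
node_keys <- function(tree) {
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal <- (n + 1L):(n + phy$Nnode)
  setNames(vapply(sets[internal], tip_key, character(1)),
           as.character(internal))
}

#' True node ages keyed by tip set
#'
#' @param tree A [time_tree()].
#' @return A tibble with columns `node_key`, `n_tips`, `age`.
#' @export
true_node_ages <- function(tree) {
  keys <- node_keys(tree)
  tibble::tibble(
    node_key = unname(keys),
    n_tips = vapply(strsplit(unname(keys), ";", fixed = TRUE), length, 1L),
    age = unname(tree$ages[names(keys)])
  )
}

#' Simulate a pure-birth (Yule) time tree conditioned on a number of tips
#'
#' Speciation events are laid down from the root towards the present: with
#' `j` splits already placed the waiting time to the next one is exponential
#' with rate `j * birth_rate`, and the youngest gap (last split to present) is
#' exponential with rate `(n_tips - 1) * birth_rate`. At each event a uniformly
#' chosen extant lineage splits. The expected root age is therefore
#' `sum(1 / (birth_rate * (1:(n_tips - 1))))`. Tip labels `t1 ... tn` are
#' assigned in lineage-creation order, deterministically for a given seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Optional integer seed.
#' @return A [time_tree()].
#' @export
#' @examples
#' tr <- simulate_pure_birth(10, 0.7, seed = 1)
#' tr$root_age
simulate_pure_birth <- function(n_tips, birth_rate, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2 || n_tips != round(n_tips))
    stop_input("`n_tips` must be an integer >= 2")
  check_number(birth_rate, "`birth_rate`", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)

  gaps <- rexp(n - 1L, rate = (1:(n - 1L)) * birth_rate)
  split_ages <- rev(cumsum(rev(gaps)))  # split j age = sum of gaps j..n-1

  # node ids: tips 1..n, internal n+j for split j (root = n+1)
  max_edges <- 2L * n - 2L
  edge <- matrix(0L, max_edges, 2L)
  edge_len <- numeric(max_edges)
  ages <- numeric(2L * n - 1L)
  n_edges <- 0L

  pending_parent <- NA_integer_  # parent internal node of each open lineage
  for (j in seq_len(n - 1L)) {
    i <- if (length(pending_parent) == 1L) 1L else
      sample.int(length(pending_parent), 1L)
    node <- n + j
    ages[node] <- split_ages[j]
    par <- pending_parent[i]
    if (!is.na(par)) {
      n_edges <- n_edges + 1L
      edge[n_edges, ] <- c(par, node)
      edge_len[n_edges] <- ages[par] - ages[node]
    }
    pending_parent <- c(pending_parent[-i], node, node)
  }
  for (i in seq_along(pending_parent)) {
    n_edges <- n_edges + 1L
    edge[n_edges, ] <- c(pending_parent[i], i)
    edge_len[n_edges] <- ages[pending_parent[i]]
  }

  phy <- structure(list(edge = edge[seq_len(n_edges), , drop = FALSE],
                        edge.length = edge_len[seq_len(n_edges)],
                        tip.label = paste0("t", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  phy <- ape::reorder.phylo(phy, "cladewise")
  time_tree(phy)
}

#' Rescale a time tree to a target root age
#'
#' Multiplies every node age (and branch length) by
#' `root_age / current root age`; the topology is unchanged.
#'
#' @param tree A [time_tree()].
#' @param root_age Target root age (> 0).
#' @return A [time_tree()].
#' @export
rescale_to_age <- function(tree, root_age) {
  check_number(root_age, "`root_age`", positive = TRUE)
  f <- root_age / tree$root_age
  phy <- tree$phylo
  phy$edge.length <- phy$edge.length * f
  out <- tree
  out$phylo <- phy
  out$ages <- tree$ages * f
  out$root_age <- root_age
  out
}

new_subst_tree <- function(time_tree, rates) {
  phy <- time_tree$phylo
  durations <- time_tree$ages[phy$edge[, 1]] - time_tree$ages[phy$edge[, 2]]
  durations <- unname(durations)
  sphy <- phy
  sphy$edge.length <- durations * rates
  structure(list(phylo = sphy, rates = rates, durations = durations,
                 time_tree = time_tree),
            class = "subst_tree")
}

#' @export
print.subst_tree <- function(x, ...) {
  cat("<subst_tree> ", ape::Ntip(x$phylo), " tips, tree length ",
      format(sum(x$phylo$edge.length), digits = 6), " subst/site\n", sep = "")
  invisible(x)
}

#' Strict-clock substitution tree
#'
#' Converts a chronogram into a tree whose branch lengths are expected
#' substitutions/site under a single global clock rate.
#'
#' @param tree A [time_tree()].
#' @param clock_rate Substitutions per site per time unit (> 0).
#' @return A `subst_tree`: the same topology with per-branch `rates`,
#'   `durations` and substitution branch lengths.
#' @export
strict_clock_subst_tree <- function(tree, clock_rate) {
  check_number(clock_rate, "`clock_rate`", positive = TRUE)
  new_subst_tree(tree, rep(clock_rate, nrow(tree$phylo$edge)))
}

#' Uncorrelated-lognormal relaxed-clock substitution tree
#'
#' Each branch receives an independent lognormal rate whose *real-space* mean
#' is `mean_rate` and whose *log-space* standard deviation is `sd_log`
#' (i.e. `meanlog = log(mean_rate) - sd_log^2 / 2`). `sd_log = 0` degenerates
#' to [strict_clock_subst_tree()].
#'
#' @param tree A [time_tree()].
#' @param mean_rate Real-space mean branch rate (> 0).
#' @param sd_log Log-space standard deviation of the branch rates (>= 0).
#' @param seed Optional integer seed.
#' @return A `subst_tree`.
#' @export
ucln_subst_tree <- function(tree, mean_rate, sd_log, seed = NULL) {
  check_number(mean_rate, "`mean_rate`", positive = TRUE)
  check_number(sd_log, "`sd_log`", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  nedge <- nrow(tree$phylo$edge)
  if (sd_log == 0) return(strict_clock_subst_tree(tree, mean_rate))
  meanlog <- log(mean_rate) - sd_log^2 / 2
  new_subst_tree(tree, rlnorm(nedge, meanlog = meanlog, sdlog = sd_log))
}
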