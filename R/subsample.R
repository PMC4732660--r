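#' Extract random clades from a dated tree
#'
#' Samples `n_clades` distinct internal nodes (clade roots) uniformly at
#' random from the nodes subtending at least `min_tips` tips, without
#' replacement; nested/overlapping clades are permitted (distinctness is of
#' the clade-root nodes). The root itself is eligible. Each replicate carries
#' the full induced subtree.
#'
#' @param tree A [time_tree()].
#' @param n_clades Number of clades to extract.
#' @param min_tips Minimum clade size (tips).
#' @param seed Optional integer seed.
#' @return A tibble of class `clade_replicates` with columns `replicate`,
#'   `node_key`, `n_tips`, `root_age` (true subtree root age) and a
#'   list-column `subtree` of [time_tree()] objects.
#' @export
extract_random_clades <- function(tree, n_clades = 100, min_tips = 20,
                                  seed = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (!is.null(seed)) set.seed(seed)
  keys <- node_keys(tree)
  sizes <- vapply(strsplit(unname(keys), ";", fixed = TRUE), length, 1L)
  eligible <- names(keys)[sizes >= min_tips]
  if (length(eligible) < n_clades)
    stop_input("only ", length(eligible), " internal nodes subtend >= ",
               min_tips, " tips; cannot extract ", n_clades, " clades")
  chosen <- sample(eligible, n_clades)
  subtrees <- lapply(chosen, function(nd) extract_clade(tree, as.integer(nd)))
  tibble::tibble(
    replicate = seq_len(n_clades),
    node_key = unname(keys[chosen]),
    n_tips = sizes[match(chosen, names(keys))],
    root_age = unname(tree$ages[chosen]),
    subtree = subtrees
  ) |>
    structure(class = c("clade_replicates", class(tibble::tibble())))
}

# Induced subtree rooted at `node` as a time_tree (whole tree if node is the
# root).
extract_clade <- function(tree, node) {
  if (node == root_node(tree)) return(tree)
  time_tree(ape::extract.clade(tree$phylo, node))
}

#' Restrict an alignment to a set of taxa
#'
#' Keeps the rows for exactly `tip_set` (all columns retained), in sorted
#' taxon order so the result is deterministic.
#'
#' @param alignment Character matrix with taxon rownames.
#' @param tip_set Character vector of taxa (subset of the alignment's rows).
#' @return The restricted alignment.
#' @export
restrict_alignment <- function(alignment, tip_set) {
  miss <- setdiff(tip_set, rownames(alignment))
  if (length(miss))
    stop_input("unknown taxa: ", paste(head(miss, 5), collapse = ", "))
  out <- alignment[sort(unique(tip_set)), , drop = FALSE]
  class(out) <- c("dna_alignment", "matrix", "array")
  out
}

#' Match primary and secondary node summaries by frozen tip set
#'
#' Every internal node of the secondary (clade) analysis is paired with the
#' primary-analysis node subtending the same tip set; with a fixed topology
#' this pairing is a bijection onto the clade's nodes.
#'
#' @param primary_summaries,secondary_summaries [summarize_trace()] tibbles.
#' @return A tibble with one row per secondary node: `node_key`, `n_tips`,
#'   and `median`, `hpd_lo`, `hpd_hi`, `ci_width` suffixed `_primary` /
#'   `_secondary`.
#' @export
match_nodes <- function(primary_summaries, secondary_summaries) {
  unmatched <- setdiff(secondary_summaries$node_key, primary_summaries$node_key)
  if (length(unmatched))
    stop_input(length(unmatched), " secondary node(s) have no primary ",
               "counterpart; with a fixed topology this indicates corrupted keys")
  dplyr::inner_join(
    dplyr::select(secondary_summaries, "node_key", "n_tips",
                  secondary_median = "median", secondary_hpd_lo = "hpd_lo",
                  secondary_hpd_hi = "hpd_hi", secondary_ci_width = "ci_width"),
    dplyr::select(primary_summaries, "node_key",
                  primary_median = "median", primary_hpd_lo = "hpd_lo",
                  primary_hpd_hi = "hpd_hi", primary_ci_width = "ci_width"),
    by = "node_key"
  ) |>
    dplyr::relocate("node_key", "n_tips", dplyr::starts_with("primary"))
}
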