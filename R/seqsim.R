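DNA_STATES <- c("A", "C", "G", "T")

#' HKY substitution-model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Stationary base frequencies in order A, C, G, T; must sum
#'   to 1 (tolerance 1e-12 after normalisation check).
#' @return An object of class `hky_params`.
#' @export
#' @examples
#' hky_params(kappa = 2, base_freqs = c(0.30, 0.26, 0.23, 0.21))
hky_params <- function(kappa = 2, base_freqs = c(0.30, 0.26, 0.23, 0.21)) {
  check_number(kappa, "`kappa`", positive = TRUE)
  if (length(base_freqs) != 4 || any(base_freqs < 0))
    stop_input("`base_freqs` must be four non-negative frequencies (A, C, G, T)")
  if (abs(sum(base_freqs) - 1) > 1e-12)
    stop_input("`base_freqs` must sum to 1 (got ", format(sum(base_freqs)), ")")
  structure(list(kappa = kappa, base_freqs = as.numeric(base_freqs)),
            class = "hky_params")
}

#' @export
print.hky_params <- function(x, ...) {
  cat("<hky_params> kappa =", x$kappa, " freqs =",
      paste(format(x$base_freqs), collapse = " "), "\n")
  invisible(x)
}

#' HKY transition-probability matrix
#'
#' Closed-form `P(t)` for the HKY rate matrix normalised to one expected
#' substitution per unit branch length, so `branch_length` is in expected
#' substitutions/site. Rows index the parent state, columns the child state,
#' in order A, C, G, T; rows sum to 1.
#'
#' @param branch_length Expected substitutions/site (>= 0).
#' @param params An [hky_params()] object.
#' @return A 4x4 row-stochastic matrix.
#' @export
hky_transition_matrix <- function(branch_length, params) {
  check_number(branch_length, "`branch_length`", nonneg = TRUE)
  stopifnot(inherits(params, "hky_params"))
  P <- hky_pmat_cpp(branch_length, params$kappa, params$base_freqs)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Simulate a nucleotide alignment along a substitution tree
#'
#' Root states are drawn i.i.d. from the stationary frequencies; each child's
#' state is drawn from the HKY transition matrix of its branch, independently
#' across sites.
#'
#' @param tree A `subst_tree` (see [strict_clock_subst_tree()]).
#' @param params An [hky_params()] object.
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return A character matrix (taxa x sites) over A/C/G/T with taxon rownames,
#'   of class `dna_alignment`.
#' @export
simulate_alignment <- function(tree, params, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "subst_tree"), inherits(params, "hky_params"))
  if (!is.numeric(n_sites) || n_sites < 1 || n_sites != round(n_sites))
    stop_input("`n_sites` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  if (n < 2) stop_input("tree must have at least two tips")
  n_sites <- as.integer(n_sites)

  ord <- ape::reorder.phylo(phy, "cladewise")  # parents before children
  states <- matrix(NA_integer_, n + phy$Nnode, n_sites)
  root <- n + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = params$base_freqs)
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    P <- hky_pmat_cpp(ord$edge.length[e], params$kappa, params$base_freqs)
    ps <- states[par, ]
    cs <- integer(n_sites)
    for (x in 1:4) {
      idx <- which(ps == x)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[x, ])
    }
    states[child, ] <- cs
  }
  aln <- matrix(DNA_STATES[states[seq_len(n), , drop = FALSE]], nrow = n,
                dimnames = list(phy$tip.label, NULL))
  class(aln) <- c("dna_alignment", class(aln))
  aln
}

# Compress alignment columns to unique site patterns; returns integer matrix
# of states (taxa x patterns, 1..4) and pattern weights, rows ordered to match
# `taxa`.
compress_patterns <- function(alignment, taxa) {
  miss <- setdiff(taxa, rownames(alignment))
  if (length(miss))
    stop_input("alignment is missing taxa: ", paste(miss, collapse = ", "))
  m <- alignment[taxa, , drop = FALSE]
  codes <- matrix(match(m, DNA_STATES), nrow = nrow(m))
  if (anyNA(codes)) stop_input("alignment contains states outside A/C/G/T")
  key <- apply(codes, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(patterns = codes[, first, drop = FALSE], weights = w)
}
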