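#' Tree, alignment, trace and summary I/O
#'
#' Plain-text formats used by the pipeline: Newick/NEXUS trees (branch
#' lengths in time units for a [time_tree()], expected substitutions/site for
#' a `subst_tree`), FASTA alignments, tab-separated traces and node-summary
#' tables, and NEXUS summary trees annotated with
#' `[&median=..,hpd={lo,hi}]` node comments.
#'
#' @name seccal-io
NULL

#' @rdname seccal-io
#' @param tree A [time_tree()] (or, for [write_subst_tree()], a `subst_tree`).
#' @param path File path.
#' @export
write_time_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @rdname seccal-io
#' @export
read_time_tree <- function(path) {
  time_tree(ape::read.tree(path))
}

#' @rdname seccal-io
#' @export
write_subst_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @rdname seccal-io
#' @param alignment Character matrix (taxa x sites) over A/C/G/T.
#' @export
write_alignment_fasta <- function(alignment, path) {
  lines <- character(2L * nrow(alignment))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(alignment))
  lines[c(FALSE, TRUE)] <- apply(alignment, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname seccal-io
#' @export
read_alignment_fasta <- function(path) {
  d <- ape::read.FASTA(path)
  mm <- as.character(as.matrix(d))
  m <- matrix(toupper(mm), nrow = nrow(mm),
              dimnames = list(rownames(mm), NULL))
  if (!all(m %in% DNA_STATES))
    stop_input("alignment in ", path, " contains states outside A/C/G/T")
  class(m) <- c("dna_alignment", "matrix", "array")
  m
}

#' @rdname seccal-io
#' @param trace An `mcmc_trace` tibble from [run_mcmc()]. Written as a
#'   tab-separated log (one row per sample) together with a `<path>.keys`
#'   companion table mapping `age_*` columns to frozen tip-set keys.
#' @export
write_trace_tsv <- function(trace, path) {
  readr::write_tsv(tibble::as_tibble(trace), path, progress = FALSE)
  keys <- attr(trace, "node_keys")
  readr::write_tsv(tibble::tibble(column = names(keys),
                                  node_key = unlist(keys)),
                   paste0(path, ".keys"), progress = FALSE)
  invisible(path)
}

#' @rdname seccal-io
#' @export
read_trace_tsv <- function(path) {
  trace <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  km <- readr::read_tsv(paste0(path, ".keys"), show_col_types = FALSE,
                        progress = FALSE)
  attr(trace, "node_keys") <- setNames(as.list(km$node_key), km$column)
  class(trace) <- c("mcmc_trace", class(trace))
  trace
}

#' @rdname seccal-io
#' @param summaries A `node_summary` tibble from [summarize_trace()].
#' @export
write_node_summaries_tsv <- function(summaries, path) {
  readr::write_tsv(tibble::as_tibble(summaries), path, progress = FALSE)
  invisible(path)
}

#' @rdname seccal-io
#' @export
read_node_summaries_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("node_summary", class(out))
  out
}

#' @rdname seccal-io
#' @param summaries For [write_summary_nexus()], the [summarize_trace()]
#'   tibble whose rows annotate the matching internal nodes.
#' @export
write_summary_nexus <- function(tree, summaries, path) {
  phy <- tree$phylo
  keys <- node_keys(tree)
  idx <- match(unname(keys), summaries$node_key)
  ann <- rep("", ape::Ntip(phy) + phy$Nnode)
  ok <- !is.na(idx)
  ann[as.integer(names(keys))[ok]] <- sprintf(
    "[&median=%.10g,hpd={%.10g,%.10g}]",
    summaries$median[idx[ok]], summaries$hpd_lo[idx[ok]],
    summaries$hpd_hi[idx[ok]])
  nwk <- newick_with_comments(phy, ann)
  writeLines(c("#NEXUS", "begin trees;",
               paste0("tree SUMMARY = [&R] ", nwk), "end;"), path)
  invisible(path)
}

# Newick string with a per-node comment inserted after each node.
newick_with_comments <- function(phy, ann) {
  n <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  lens <- numeric(n + phy$Nnode)
  lens[phy$edge[, 2]] <- phy$edge.length
  rec <- function(node) {
    if (node <= n) {
      paste0(phy$tip.label[node], ann[node], ":", format(lens[node], digits = 12))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, character(1)),
                     collapse = ",")
      suff <- if (node == n + 1L) ";" else
        paste0(":", format(lens[node], digits = 12))
      paste0("(", inner, ")", ann[node], suff)
    }
  }
  rec(n + 1L)
}

#' @rdname seccal-io
#' @return `read_summary_nexus()` returns a list with `tree` (a [time_tree()])
#'   and `summaries` (a `node_summary` tibble rebuilt from the annotations).
#' @export
read_summary_nexus <- function(path) {
  lines <- readLines(path)
  tl <- grep("^tree ", lines, value = TRUE)[1]
  nwk <- sub("^tree [^=]+= *(\\[&R\\] *)?", "", tl)
  anns <- regmatches(nwk, gregexpr("\\[&[^]]*\\]", nwk))[[1]]
  clean <- gsub("\\[&[^]]*\\]", "", nwk)
  phy <- ape::read.tree(text = clean)
  tree <- time_tree(phy)
  # annotations appear in the Newick in the same node order as a fresh write;
  # recover node identity by re-walking the cleaned string with keys
  keys <- node_keys(tree)
  med <- as.numeric(sub(".*median=([-0-9.eE+]+).*", "\\1", anns))
  lo <- as.numeric(sub(".*hpd=\\{([-0-9.eE+]+),.*", "\\1", anns))
  hi <- as.numeric(sub(".*hpd=\\{[^,]+,([-0-9.eE+]+)\\}.*", "\\1", anns))
  ord <- nexus_annotation_nodes(nwk, phy)
  summaries <- tibble::tibble(
    node_key = unname(keys[as.character(ord)]),
    n_tips = vapply(strsplit(unname(keys[as.character(ord)]), ";",
                             fixed = TRUE), length, 1L),
    median = med, hpd_lo = lo, hpd_hi = hi,
    ci_width = hi - lo)
  class(summaries) <- c("node_summary", class(summaries))
  list(tree = tree, summaries = summaries)
}

# Internal-node numbers, in the order their "[&...]" annotations appear in
# the Newick string: an internal node's annotation follows its closing ")".
nexus_annotation_nodes <- function(nwk, phy) {
  n <- ape::Ntip(phy)
  # reproduce the writer's traversal to know which node each ")" closes
  order_written <- integer(0)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(node) {
    if (node > n) {
      for (k in kids[[as.character(node)]]) rec(k)
      order_written <<- c(order_written, node)
    }
  }
  rec(n + 1L)
  order_written
}
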