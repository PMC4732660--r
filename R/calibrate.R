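#' Node calibration priors
#'
#' A calibration prior attaches a distribution over age to the node identified
#' by `node_key` (a frozen tip set, see [tip_key()]). Supported kinds:
#' `"lognormal"` (`meanlog`, `sdlog`, both log-space), `"uniform"`
#' (`lo`, `hi`) and `"normal"` (`mean`, `sd`; truncated at age 0).
#'
#' @param node_key Node key (see [tip_key()]).
#' @param kind One of `"lognormal"`, `"uniform"`, `"normal"`.
#' @param ... Kind-specific parameters (see Details).
#' @return An object of class `calibration_prior`.
#' @export
#' @examples
#' calibration_prior(tip_key(c("t1", "t2")), "uniform", lo = 10, hi = 20)
calibration_prior <- function(node_key, kind, ...) {
  kind <- match.arg(kind, c("lognormal", "uniform", "normal"))
  pars <- list(...)
  if (kind == "lognormal") {
    check_number(pars$meanlog %||% NA, "`meanlog`")
    check_number(pars$sdlog %||% NA, "`sdlog`", positive = TRUE)
  } else if (kind == "uniform") {
    check_number(pars$lo %||% NA, "`lo`", nonneg = TRUE)
    check_number(pars$hi %||% NA, "`hi`", positive = TRUE)
    if (pars$lo >= pars$hi) stop_input("uniform calibration requires lo < hi")
  } else {
    check_number(pars$mean %||% NA, "`mean`")
    check_number(pars$sd %||% NA, "`sd`", positive = TRUE)
  }
  structure(c(list(node_key = as.character(node_key), kind = kind), pars),
            class = "calibration_prior")
}

#' @export
print.calibration_prior <- function(x, ...) {
  pars <- x[setdiff(names(x), c("node_key", "kind"))]
  cat("<calibration_prior> ", x$kind, "(",
      paste(names(pars), unlist(pars), sep = "=", collapse = ", "),
      ") on ", substr(x$node_key, 1, 40),
      if (nchar(x$node_key) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Sample primary calibrations from the true tree
#'
#' Samples `n_internal` distinct non-root internal nodes uniformly at random,
#' adds the root, and gives each a lognormal calibration whose log-space
#' standard deviation is `log_sd` and whose median equals the node's true age
#' (`meanlog = log(true age)`).
#'
#' @param true_tree A [time_tree()].
#' @param n_internal Number of non-root internal nodes to calibrate (default
#'   29, so 30 calibrations including the root).
#' @param log_sd Log-space standard deviation of each lognormal prior.
#' @param seed Optional integer seed.
#' @return A list of [calibration_prior()] objects (root last).
#' @export
sample_primary_calibrations <- function(true_tree, n_internal = 29,
                                        log_sd = 1, seed = NULL) {
  stopifnot(inherits(true_tree, "time_tree"))
  if (!is.null(seed)) set.seed(seed)
  keys <- node_keys(true_tree)
  root <- as.character(root_node(true_tree))
  nonroot <- setdiff(names(keys), root)
  if (n_internal >= length(nonroot) + 1)
    stop_input("`n_internal` (", n_internal, ") must be smaller than the ",
               length(nonroot), " non-root internal nodes available")
  chosen <- c(sample(nonroot, n_internal), root)
  lapply(chosen, function(nd) {
    calibration_prior(keys[[nd]], "lognormal",
                      meanlog = log(true_tree$ages[[nd]]), sdlog = log_sd)
  })
}

#' Uniform secondary calibration from a primary 95% HPD
#'
#' The published secondary-calibration practice this package studies: the
#' primary analysis's HPD bounds for a node become the support of a uniform
#' prior on that node in the secondary analysis.
#'
#' @param hpd_lo,hpd_hi Primary 95% HPD bounds (`0 <= hpd_lo < hpd_hi`).
#' @param node_key Node key the prior applies to.
#' @return A uniform [calibration_prior()].
#' @export
uniform_secondary_prior <- function(hpd_lo, hpd_hi, node_key) {
  check_number(hpd_lo, "`hpd_lo`", nonneg = TRUE)
  check_number(hpd_hi, "`hpd_hi`", nonneg = TRUE)
  if (hpd_lo >= hpd_hi)
    stop_input("degenerate HPD interval: hpd_lo (", hpd_lo,
               ") must be < hpd_hi (", hpd_hi, ")")
  calibration_prior(node_key, "uniform", lo = hpd_lo, hi = hpd_hi)
}

#' Normal secondary calibration from a primary 95% HPD
#'
#' A normal prior whose central 95% mass spans exactly the primary HPD:
#' `mean = (lo + hi) / 2`, `sd = (hi - lo) / (2 * qnorm(0.975))`. The density
#' is truncated at 0 when evaluated (see [calibration_log_prior()]).
#'
#' @inheritParams uniform_secondary_prior
#' @return A normal [calibration_prior()].
#' @export
normal_secondary_prior <- function(hpd_lo, hpd_hi, node_key) {
  check_number(hpd_lo, "`hpd_lo`", nonneg = TRUE)
  check_number(hpd_hi, "`hpd_hi`", nonneg = TRUE)
  if (hpd_lo >= hpd_hi)
    stop_input("degenerate HPD interval: hpd_lo (", hpd_lo,
               ") must be < hpd_hi (", hpd_hi, ")")
  calibration_prior(node_key, "normal",
                    mean = (hpd_lo + hpd_hi) / 2,
                    sd = (hpd_hi - hpd_lo) / (2 * qnorm(0.975)))
}

#' Second calibration node of a clade: two nodes tipward on the right
#'
#' Returns the key of `root -> child[2] -> child[2]` ("right side" = second
#' child in stored Newick child order; the left/right convention is
#' tool-dependent, so the stored order is the recorded choice). Errors with
#' class `seccal_ineligible` if that position is a tip, so callers can skip or
#' substitute the replicate.
#'
#' @param subtree A [time_tree()].
#' @return The node key (character).
#' @export
second_calibration_node <- function(subtree) {
  stopifnot(inherits(subtree, "time_tree"))
  phy <- subtree$phylo
  n <- ape::Ntip(phy)
  second_child <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(kids) != 2) stop_input("tree is not bifurcating at node ", node)
    kids[2]
  }
  a <- second_child(root_node(subtree))
  if (a <= n) stop_ineligible("right child of the root is a tip")
  b <- second_child(a)
  if (b <= n) stop_ineligible("node two steps tipward on the right is a tip")
  unname(node_keys(subtree)[[as.character(b)]])
}

stop_ineligible <- function(msg) {
  stop(structure(class = c("seccal_ineligible", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Serialise calibrations to a plain-text table
#'
#' @param calibrations A list of [calibration_prior()] objects.
#' @return A tibble with columns `node_key`, `kind`, `par1`, `par2` (parameter
#'   order: meanlog/sdlog, lo/hi, or mean/sd).
#' @export
calibrations_tbl <- function(calibrations) {
  purrr::map_dfr(calibrations, function(cp) {
    pars <- switch(cp$kind,
      lognormal = c(cp$meanlog, cp$sdlog),
      uniform = c(cp$lo, cp$hi),
      normal = c(cp$mean, cp$sd))
    tibble::tibble(node_key = cp$node_key, kind = cp$kind,
                   par1 = pars[1], par2 = pars[2])
  })
}
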