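#' Experiment configuration
#'
#' Bundles every constant of the secondary-calibration experiment: the
#' pure-birth tree (`n_tips`, `birth_rate`, `root_age`), the HKY sequence
#' simulation (`n_sites`, `kappa`, `base_freqs`, `clock_rate`), the primary
#' calibration scheme (`n_primary_calibrations` non-root nodes plus the root,
#' lognormal log-sd `calibration_log_sd`), clade subsampling (`n_clades`,
#' `min_tips`), the MCMC schedule, the arm cadence (`normal_every`,
#' `two_node_every`, `relaxed_every`; 0 disables an arm) and the
#' relaxed-clock data simulation (`relaxed_mean_rate`, `relaxed_sd_log`,
#' `relaxed_n_sites`).
#'
#' The `"full"` preset is the full-scale study design (1500 tips,
#' 2000 bp, 29+root calibrations, 100 clades of >= 20 tips, 100M-generation
#' primary chain sampled every 2000, 30M/60M-generation secondary chains
#' sampled every 3000 with the 200-tip threshold, arms on every 10th
#' replicate, 3000 bp relaxed-clock matrix with lognormal mean rate 0.020 and
#' log-sd 2.017). The `"desk"` preset keeps the same structure at a size a
#' single CPU finishes in an hour or two (120 tips, 800 bp, 9+root
#' calibrations, 12 clades of >= 10 tips, 2e5-generation chains sampled every
#' 100).
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides of any configuration field.
#' @param seed Master seed; every stage and replicate seed is derived from it.
#' @param outdir Output directory for persisted artifacts, or `NULL` to keep
#'   everything in memory.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "full"), ..., seed = 1,
                              outdir = NULL) {
  preset <- match.arg(preset)
  base <- list(
    n_tips = 120, birth_rate = 0.7, root_age = 70,
    n_sites = 800, kappa = 2, base_freqs = c(0.30, 0.26, 0.23, 0.21),
    clock_rate = 0.01,
    n_primary_calibrations = 9, calibration_log_sd = 1,
    n_clades = 12, min_tips = 10,
    primary_chain_length = 2e5, primary_sample_every = 100,
    secondary_chain_length = 2e5, secondary_chain_length_large = 4e5,
    large_tip_threshold = 200, secondary_sample_every = 100,
    burnin_fraction = 0.5,
    normal_every = 10, two_node_every = 10, relaxed_every = 10,
    relaxed_mean_rate = 0.020, relaxed_sd_log = 2.017, relaxed_n_sites = 1200,
    dating_birth_rate = NULL)
  if (preset == "full") {
    base <- utils::modifyList(base, list(
      n_tips = 1500, n_sites = 2000, n_primary_calibrations = 29,
      n_clades = 100, min_tips = 20,
      primary_chain_length = 1e8, primary_sample_every = 2000,
      secondary_chain_length = 3e7, secondary_chain_length_large = 6e7,
      secondary_sample_every = 3000, relaxed_n_sites = 3000))
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop_input("unknown config fields: ",
                              paste(bad, collapse = ", "))
  cfg <- utils::modifyList(base, over)
  cfg$preset <- preset
  cfg$seed <- seed
  cfg$outdir <- outdir
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config> preset=", x$preset, ": ", x$n_tips, " tips, ",
      x$n_sites, " bp, ", x$n_clades, " clades (>=", x$min_tips, " tips), ",
      "seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Chain length rule: longer chains for large secondary trees.
secondary_chain_length <- function(config, n_tips) {
  if (n_tips < config$large_tip_threshold) config$secondary_chain_length
  else config$secondary_chain_length_large
}

run_secondary <- function(alignment, subtree, cals, config, params,
                          init_ages, seed, birth_rate, init_rate) {
  n_tips <- ape::Ntip(subtree$phylo)
  mc <- mcmc_config(
    chain_length = secondary_chain_length(config, n_tips),
    sample_every = config$secondary_sample_every,
    burnin_fraction = config$burnin_fraction, seed = seed,
    clock_model = "ucln", birth_rate = birth_rate,
    init_clock_rate = init_rate)
  trace <- run_mcmc(alignment, subtree, cals, params, mc,
                    init_ages = init_ages)
  summarize_trace(trace, config$burnin_fraction)
}

# One comparison row from a secondary summary vs the primary summary.
compare_replicate <- function(arm, rep_id, primary_summary, secondary_summary,
                              n_tips) {
  matched <- match_nodes(primary_summary, secondary_summary)
  diffs <- node_differences(matched)
  tt <- paired_t_test(matched$primary_median, matched$secondary_median)
  root_row <- which.max(secondary_summary$n_tips)
  cmp <- dplyr::bind_cols(
    tibble::tibble(arm = arm, replicate = rep_id, n_tips = n_tips,
                   root_age = secondary_summary$median[root_row]),
    summed_absolute_differences(diffs),
    dplyr::rename_with(tt, ~ paste0("t_", .x)))
  list(comparison = cmp,
       diffs = dplyr::mutate(diffs, arm = arm, replicate = rep_id,
                             .before = 1),
       matched = dplyr::mutate(matched, arm = arm, replicate = rep_id,
                               .before = 1))
}

#' Run the full secondary-calibration experiment
#'
#' Executes the whole design: simulate the pure-birth tree and its HKY
#' alignment, date the full tree with lognormal primary calibrations
#' (the "primary" analysis), extract random clades, re-date every clade with
#' only a secondary calibration built from the primary posterior (uniform
#' prior on the clade root; plus, on a configurable cadence, a normal-prior
#' arm, a two-node uniform arm and a relaxed-clock-data arm), and compute the
#' comparison statistics. Fully reproducible from `(config, config$seed)`.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress messages?
#' @return A list of class `seccal_experiment`: `config`, `tree` (true,
#'   rescaled), `primary_summary`, `clades`, `node_diffs`,
#'   `replicate_comparisons`, `matched_all`, `pooled_width_test`, `table1`,
#'   `regressions`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  ms <- config$seed
  params <- hky_params(config$kappa, config$base_freqs)

  say("stage tree: ", config$n_tips, "-tip pure-birth tree")
  tree <- simulate_pure_birth(config$n_tips, config$birth_rate,
                              seed = derive_seed(ms, "tree"))
  tree <- rescale_to_age(tree, config$root_age)
  birth_rate_dating <- config$dating_birth_rate %||%
    ((config$n_tips - 1) / sum(tree$ages))

  say("stage seq: ", config$n_sites, " bp strict-clock HKY alignment")
  subst <- strict_clock_subst_tree(tree, config$clock_rate)
  aln <- simulate_alignment(subst, params, config$n_sites,
                            seed = derive_seed(ms, "seq"))

  cals <- sample_primary_calibrations(tree, config$n_primary_calibrations,
                                      config$calibration_log_sd,
                                      seed = derive_seed(ms, "cal"))

  say("stage primary: dating the full tree")
  primary_mc <- mcmc_config(chain_length = config$primary_chain_length,
                            sample_every = config$primary_sample_every,
                            burnin_fraction = config$burnin_fraction,
                            seed = derive_seed(ms, "primary"),
                            birth_rate = birth_rate_dating,
                            init_clock_rate = config$clock_rate)
  primary_trace <- run_mcmc(aln, tree, cals, params, primary_mc)
  primary_summary <- summarize_trace(primary_trace, config$burnin_fraction)
  primary_init <- setNames(primary_summary$median, primary_summary$node_key)

  say("stage clades: extracting ", config$n_clades, " clades")
  clades <- extract_random_clades(tree, config$n_clades, config$min_tips,
                                  seed = derive_seed(ms, "clades"))

  every <- function(k) if (k > 0) which(seq_len(config$n_clades) %% k == 0) else
    integer(0)
  normal_set <- every(config$normal_every)
  relaxed_set <- every(config$relaxed_every)

  # Two-node arm: a scheduled replicate whose two-nodes-tipward position is a
  # tip is ineligible; the next eligible replicate is substituted.
  twonode_key2 <- lapply(clades$subtree, function(st) {
    tryCatch(second_calibration_node(st),
             seccal_ineligible = function(e) NULL)
  })
  twonode_set <- integer(0)
  for (s in every(config$two_node_every)) {
    cand <- c(s:config$n_clades, seq_len(s - 1))
    cand <- setdiff(cand, twonode_set)
    ok <- cand[!vapply(twonode_key2[cand], is.null, TRUE)]
    if (!length(ok)) {
      warning("no eligible replicate found for a scheduled two-node run",
              call. = FALSE)
    } else {
      twonode_set <- c(twonode_set, ok[1])
      if (ok[1] != s)
        message("two-node arm: replicate ", s, " ineligible; substituted ",
                "replicate ", ok[1])
    }
  }

  comparisons <- list(); diffs <- list(); matched <- list()
  sec_root_prior <- function(summary_tbl, key, kind) {
    row <- summary_tbl[summary_tbl$node_key == key, ]
    builder <- if (kind == "uniform") uniform_secondary_prior else
      normal_secondary_prior
    builder(row$hpd_lo, row$hpd_hi, key)
  }

  for (i in seq_len(config$n_clades)) {
    subtree <- clades$subtree[[i]]
    key <- clades$node_key[i]
    aln_i <- restrict_alignment(aln, subtree$phylo$tip.label)
    say("replicate ", i, "/", config$n_clades, " (", clades$n_tips[i], " tips)")

    res <- compare_replicate(
      "uniform", i, primary_summary,
      run_secondary(aln_i, subtree,
                    list(sec_root_prior(primary_summary, key, "uniform")),
                    config, params, primary_init,
                    derive_seed(ms, "sec_uniform", i), birth_rate_dating,
                    config$clock_rate),
      clades$n_tips[i])
    comparisons <- c(comparisons, list(res$comparison))
    diffs <- c(diffs, list(res$diffs))
    matched <- c(matched, list(res$matched))

    if (i %in% normal_set) {
      res <- compare_replicate(
        "normal", i, primary_summary,
        run_secondary(aln_i, subtree,
                      list(sec_root_prior(primary_summary, key, "normal")),
                      config, params, primary_init,
                      derive_seed(ms, "sec_normal", i), birth_rate_dating,
                      config$clock_rate),
        clades$n_tips[i])
      comparisons <- c(comparisons, list(res$comparison))
      diffs <- c(diffs, list(res$diffs))
    }

    if (i %in% twonode_set) {
      key2 <- twonode_key2[[i]]
      res <- compare_replicate(
        "two_node", i, primary_summary,
        run_secondary(aln_i, subtree,
                      list(sec_root_prior(primary_summary, key, "uniform"),
                           sec_root_prior(primary_summary, key2, "uniform")),
                      config, params, primary_init,
                      derive_seed(ms, "sec_twonode", i), birth_rate_dating,
                      config$clock_rate),
        clades$n_tips[i])
      comparisons <- c(comparisons, list(res$comparison))
      diffs <- c(diffs, list(res$diffs))
    }
  }

  relaxed_out <- NULL
  if (length(relaxed_set)) {
    say("stage relaxed: re-simulating data under the UCLN clock")
    relaxed_subst <- ucln_subst_tree(tree, config$relaxed_mean_rate,
                                     config$relaxed_sd_log,
                                     seed = derive_seed(ms, "relaxed_tree"))
    relaxed_aln <- simulate_alignment(relaxed_subst, params,
                                      config$relaxed_n_sites,
                                      seed = derive_seed(ms, "relaxed_seq"))
    relaxed_mc <- mcmc_config(chain_length = config$primary_chain_length,
                              sample_every = config$primary_sample_every,
                              burnin_fraction = config$burnin_fraction,
                              seed = derive_seed(ms, "relaxed_primary"),
                              birth_rate = birth_rate_dating,
                              init_clock_rate = config$relaxed_mean_rate)
    relaxed_trace <- run_mcmc(relaxed_aln, tree, cals, params, relaxed_mc)
    relaxed_primary <- summarize_trace(relaxed_trace, config$burnin_fraction)
    relaxed_init <- setNames(relaxed_primary$median, relaxed_primary$node_key)
    for (i in relaxed_set) {
      subtree <- clades$subtree[[i]]
      key <- clades$node_key[i]
      res <- compare_replicate(
        "relaxed", i, relaxed_primary,
        run_secondary(restrict_alignment(relaxed_aln,
                                         subtree$phylo$tip.label),
                      subtree,
                      list(sec_root_prior(relaxed_primary, key, "uniform")),
                      config, params, relaxed_init,
                      derive_seed(ms, "sec_relaxed", i), birth_rate_dating,
                      config$relaxed_mean_rate),
        clades$n_tips[i])
      comparisons <- c(comparisons, list(res$comparison))
      diffs <- c(diffs, list(res$diffs))
    }
    relaxed_out <- relaxed_primary
  }

  replicate_comparisons <- dplyr::bind_rows(comparisons) |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(significant = .data$t_p < 0.05,
                  significant_bonferroni = bonferroni_flags(.data$t_p)) |>
    dplyr::ungroup()
  node_diffs <- dplyr::bind_rows(diffs)
  matched_all <- dplyr::bind_rows(matched)

  out <- structure(list(
    config = config, tree = tree, primary_summary = primary_summary,
    relaxed_primary_summary = relaxed_out, clades = clades,
    node_diffs = node_diffs, replicate_comparisons = replicate_comparisons,
    matched_all = matched_all,
    pooled_width_test = pooled_ci_width_test(matched_all),
    table1 = make_table1(replicate_comparisons),
    regressions = regress_summaries(
      dplyr::filter(replicate_comparisons, .data$arm == "uniform"))),
    class = "seccal_experiment")
  if (!is.null(config$outdir)) persist_experiment(out, aln, config$outdir)
  out
}

#' @export
print.seccal_experiment <- function(x, ...) {
  cat("<seccal_experiment> ", nrow(x$replicate_comparisons),
      " secondary analyses over ", x$config$n_clades, " clades\n", sep = "")
  print(x$table1)
  invisible(x)
}

#' Arm-level summary table of averaged summed differences
#'
#' Per experiment arm: mean of the per-replicate summed absolute differences
#' in HPD minimum, maximum, median and CI width (time units), plus the
#' proportion of replicates whose paired t test on median node ages is
#' significant at P < 0.05. Arms with no replicates are omitted with a
#' warning; an arm whose tests are all undefined carries `NA`.
#'
#' @param replicate_comparisons The `replicate_comparisons` tibble of a
#'   [run_experiment()] result.
#' @return A tibble with one row per arm.
#' @export
make_table1 <- function(replicate_comparisons) {
  arms <- c("uniform", "normal", "two_node", "relaxed")
  present <- intersect(arms, unique(replicate_comparisons$arm))
  absent <- setdiff(unique(replicate_comparisons$arm), arms)
  if (length(absent)) present <- c(present, absent)
  missing_arms <- setdiff(arms, present)
  if (length(missing_arms))
    warning("arm(s) with no replicates omitted: ",
            paste(missing_arms, collapse = ", "), call. = FALSE)
  replicate_comparisons |>
    dplyr::filter(.data$arm %in% present) |>
    dplyr::mutate(arm = factor(.data$arm, levels = present)) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      avg_min = mean(.data$sum_abs_min),
      avg_max = mean(.data$sum_abs_max),
      avg_median = mean(.data$sum_abs_median),
      avg_ci = mean(.data$sum_abs_width),
      t_test_median = mean(.data$significant[.data$t_defined]),
      .groups = "drop") |>
    dplyr::mutate(arm = as.character(.data$arm))
}

# Persist the experiment's artifacts as plain-text files.
persist_experiment <- function(x, alignment, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_time_tree(x$tree, file.path(outdir, "true_tree.nwk"))
  write_alignment_fasta(alignment, file.path(outdir, "alignment.fasta"))
  write_node_summaries_tsv(x$primary_summary,
                           file.path(outdir, "primary_summary.tsv"))
  write_summary_nexus(x$tree, x$primary_summary,
                      file.path(outdir, "primary_summary.nex"))
  readr::write_tsv(dplyr::select(x$clades, -"subtree"),
                   file.path(outdir, "clade_manifest.tsv"), progress = FALSE)
  readr::write_tsv(x$node_diffs, file.path(outdir, "node_differences.tsv"),
                   progress = FALSE)
  readr::write_tsv(x$replicate_comparisons,
                   file.path(outdir, "replicate_comparisons.tsv"),
                   progress = FALSE)
  readr::write_tsv(x$table1, file.path(outdir, "table1.tsv"), progress = FALSE)
  readr::write_tsv(x$regressions, file.path(outdir, "regressions.tsv"),
                   progress = FALSE)
  invisible(outdir)
}
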