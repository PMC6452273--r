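#' Configuration for an end-to-end run
#'
#' A run either ingests files (`paths`) or simulates its inputs
#' (`simulation`); exactly one of the two must be given, and a seed is
#' mandatory because control matching, model fitting and simulation are all
#' stochastic. Every stage derives its own substream from the master seed via
#' [derive_seed()], so reruns with the same config are byte-identical.
#'
#' @param paths list with `tree` (Newick file), optional `boot_trees`
#'   (multi-tree Newick file) and `trait_table` (TSV, see
#'   [read_trait_table()]).
#' @param simulation list with `n_tips`, `birth_rate`, `pair_models` (list of
#'   `pair_model`s; pair `i` yields traits `sys<i>`/`cas<i>`),
#'   `control_frequencies` (numeric vector), `n_boot_trees`, `length_cv`.
#' @param alpha Bonferroni family-wise level (default 0.05).
#' @param k_controls,margin control matching parameters (defaults 10, 0.01).
#' @param lo,hi frequency filter bounds (defaults 0.01, 0.99).
#' @param lrt_threshold median-LRT significance threshold (default 0.01).
#' @param n_starts optimizer starts per model fit (default 5).
#' @param seed master integer seed (mandatory).
#' @param outdir output directory (created if needed); `NULL` for no files.
#' @param reconcile_policy `"strict"` or `"intersect"` (see [reconcile()]).
#' @return a validated `run_config` list.
#' @export
run_config <- function(paths = NULL, simulation = NULL, alpha = 0.05,
                       k_controls = 10L, margin = 0.01, lo = 0.01, hi = 0.99,
                       lrt_threshold = 0.01, n_starts = 5L, seed,
                       outdir = NULL, reconcile_policy = "strict") {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(paths) == is.null(simulation)) {
    stop("exactly one of `paths` or `simulation` must be given")
  }
  if (!is.null(simulation)) {
    req <- c("n_tips", "pair_models")
    if (!all(req %in% names(simulation))) {
      stop("simulation block needs at least: ", paste(req, collapse = ", "))
    }
    simulation$birth_rate <- simulation$birth_rate %||% 1
    simulation$control_frequencies <- simulation$control_frequencies %||%
      rep(seq(0.1, 0.9, by = 0.2), length.out = 20L)
    simulation$n_boot_trees <- simulation$n_boot_trees %||% 0L
    simulation$length_cv <- simulation$length_cv %||% 0.2
  }
  structure(list(paths = paths, simulation = simulation, alpha = alpha,
                 k_controls = k_controls, margin = margin, lo = lo, hi = hi,
                 lrt_threshold = lrt_threshold, n_starts = n_starts,
                 seed = as.integer(seed), outdir = outdir,
                 reconcile_policy = reconcile_policy),
            class = "run_config")
}

#' Run the whole association pipeline
#'
#' Executes, in order: input simulation or ingestion; frequency filtering and
#' the phi/Fisher/Bonferroni screen (with the delta-phi control comparison);
#' the phylogenetically corrected correlated-evolution test on the
#' Bonferroni-significant pairs only (pairs passing the naive screen are the
#' only candidates for phylogenetic confirmation); the signed association
#' matrix; and single-linkage clustering. All stage outputs, a summary and a
#' parameter log are written to `cfg$outdir` when set.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_report` with elements `tree`, `boot_trees`,
#'   `traits`, `screen`, `phylo` (data.frame), `signed` (matrix),
#'   `clustering` (or `NULL`), and `summary` (named list of counts and
#'   headline statistics).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$seed

  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    tree <- simulate_tree(sim$n_tips, sim$birth_rate,
                          seed = derive_seed(seed, "tree"))
    pair_tms <- lapply(seq_along(sim$pair_models), function(i) {
      simulate_pair_traits(tree, sim$pair_models[[i]],
                           seed = derive_seed(seed, paste0("pair_", i)),
                           trait_ids = c(paste0("sys", i), paste0("cas", i)))
    })
    ctrl <- simulate_controls(tree$tip.label, sim$control_frequencies,
                              seed = derive_seed(seed, "controls"))
    tm <- do.call(cbind_traits, c(pair_tms, list(ctrl)))
    boot_trees <- if (sim$n_boot_trees > 0L) {
      jitter_trees(tree, sim$n_boot_trees, sim$length_cv,
                   seed = derive_seed(seed, "boot"))
    } else NULL
  } else {
    tree <- read_newick(cfg$paths$tree)
    tm <- read_trait_table(cfg$paths$trait_table)
    boot_trees <- if (!is.null(cfg$paths$boot_trees)) {
      read_newick_set(cfg$paths$boot_trees)
    } else NULL
  }

  rec <- reconcile(tree, tm, cfg$reconcile_policy)
  tree <- rec$tree
  tm <- rec$traits

  scr <- screen_associations(tm, k_controls = cfg$k_controls,
                             margin = cfg$margin, alpha = cfg$alpha,
                             lo = cfg$lo, hi = cfg$hi,
                             seed = derive_seed(seed, "screen"))

  sig <- which(scr$records$bonferroni_significant)
  phylo <- if (length(sig)) {
    do.call(rbind, lapply(sig, function(i) {
      s <- scr$records$system[i]
      ca <- scr$records$cas[i]
      ct <- correlation_test(tree,
                             subset_traits(tm, traits = c(s, ca)),
                             boot_trees = boot_trees,
                             n_starts = cfg$n_starts,
                             threshold = cfg$lrt_threshold,
                             seed = derive_seed(seed, paste0("phylo_", s, "_", ca)))
      data.frame(system = s, cas = ca,
                 lnl_indep = ct$lnl_indep, lnl_dep = ct$lnl_dep,
                 lrt_stat = ct$statistic, p_main = ct$p_main,
                 median_p = ct$median_p, n_trees = ct$n_trees,
                 significant = ct$significant, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(system = character(), cas = character(),
               lnl_indep = numeric(), lnl_dep = numeric(),
               lrt_stat = numeric(), p_main = numeric(),
               median_p = numeric(), n_trees = integer(),
               significant = logical(), stringsAsFactors = FALSE)
  }

  signed <- signed_matrix(scr, phylo)
  clustering <- if (nrow(signed) >= 1L && ncol(signed) >= 1L) {
    cluster_signed(signed)
  } else NULL

  summary <- list(
    n_genomes = nrow(tm$values),
    n_pairs_tested = scr$m_tests,
    n_bonferroni_significant = length(sig),
    n_significant_positive = sum(signed == 1L),
    n_significant_negative = sum(signed == -1L),
    delta_phi_mean = scr$delta_phi$mean,
    delta_phi_t = scr$delta_phi$t,
    delta_phi_p = scr$delta_phi$p,
    seed = seed)

  report <- structure(list(tree = tree, boot_trees = boot_trees, traits = tm,
                           screen = scr, phylo = phylo, signed = signed,
                           clustering = clustering, summary = summary,
                           config = cfg),
                      class = "run_report")
  if (!is.null(cfg$outdir)) write_run_outputs(report, cfg$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "pipeline run: %d genomes, %d pairs tested\n",
    "  Bonferroni-significant: %d; after phylogenetic correction: %d (+), %d (-)\n",
    "  delta-phi one-sided p = %.4g\n"),
    s$n_genomes, s$n_pairs_tested, s$n_bonferroni_significant,
    s$n_significant_positive, s$n_significant_negative, s$delta_phi_p))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_run_outputs <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_newick(report$tree, p("tree.nwk"))
  if (!is.null(report$boot_trees)) {
    write_newick(report$boot_trees, p("boot_trees.nwk"))
  }
  write_trait_table(report$traits, p("traits.tsv"))
  write_tsv(report$screen$records, p("screen.tsv"))
  dphi <- report$screen$delta_phi
  write_tsv(data.frame(mean_delta_phi = dphi$mean, t = dphi$t,
                       one_sided_p = dphi$p, n_pairs = dphi$n),
            p("delta_phi.tsv"))
  write_tsv(report$phylo, p("phylo_test.tsv"))
  signed_df <- as.data.frame(report$signed)
  signed_df <- cbind(cas = rownames(report$signed), signed_df)
  write_tsv(signed_df, p("signed_matrix.tsv"))
  if (!is.null(report$clustering)) {
    write_tsv(report$clustering$row_merge, p("row_merge.tsv"))
    write_tsv(report$clustering$col_merge, p("col_merge.tsv"))
    writeLines(c(paste(c("rows:", report$clustering$row_order), collapse = "\t"),
                 paste(c("cols:", report$clustering$col_order), collapse = "\t")),
               p("leaf_orders.tsv"))
  }
  jsonlite::write_json(report$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- report$config
  log_lines <- c(
    sprintf("cooccurphylo %s on R %s.%s",
            as.character(utils::packageVersion("cooccurphylo")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", cfg$seed),
    sprintf("alpha: %g  k_controls: %d  margin: %g", cfg$alpha,
            cfg$k_controls, cfg$margin),
    sprintf("frequency filter: (%g, %g)  lrt_threshold: %g  n_starts: %d",
            cfg$lo, cfg$hi, cfg$lrt_threshold, cfg$n_starts),
    sprintf("mode: %s", if (is.null(cfg$simulation)) "ingest" else "simulate"))
  writeLines(log_lines, p("run_log.txt"))
  invisible(outdir)
}
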