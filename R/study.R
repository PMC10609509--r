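#' Configuration of a slow-fast simulation study
#'
#' Defaults are the reference full-scale design (1000 leaves, 2596 sites,
#' 100 replicate alignments, 1000 bootstrap trees per partition, LG,
#' alpha = 0.803 with 12 categories, gamma branch-length priors with shapes
#' 0.7581720/1.509421 and internal median 0.05 substitutions/site); scale
#' down `n_leaves`, `n_replicates` and `n_bootstrap` for desk-size runs.
#'
#' @param n_leaves taxa per simulated tree.
#' @param n_sites alignment length (also the RSAP target length).
#' @param n_replicates number of simulated alignments.
#' @param n_bootstrap bootstrap trees per partition.
#' @param alpha gamma shape of site-rate heterogeneity.
#' @param k number of equiprobable rate categories.
#' @param model substitution model name (see [load_model()]).
#' @param frequencies optional empirical equilibrium frequencies overriding
#'   the model defaults.
#' @param prior [branch_length_prior()].
#' @param recovery_threshold bootstrap support needed to call a reference
#'   bipartition recovered (default 0.8).
#' @param slope_categories categories regressed over in the RF-vs-rate
#'   slope (default 9:12, the fast end).
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_leaves = 1000, n_sites = 2596,
                              n_replicates = 100, n_bootstrap = 1000,
                              alpha = 0.803, k = 12, model = "LG",
                              frequencies = NULL,
                              prior = branch_length_prior(),
                              recovery_threshold = 0.8,
                              slope_categories = 9:12,
                              seed = 1) {
  counts <- c(n_leaves = n_leaves, n_sites = n_sites,
              n_replicates = n_replicates, n_bootstrap = n_bootstrap, k = k)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_leaves < 4) stop("n_leaves must be >= 4")
  if (!(recovery_threshold > 0 && recovery_threshold <= 1))
    stop("recovery_threshold must be in (0, 1]")
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(inherits(prior, "branch_length_prior"))
  structure(list(n_leaves = as.integer(n_leaves),
                 n_sites = as.integer(n_sites),
                 n_replicates = as.integer(n_replicates),
                 n_bootstrap = as.integer(n_bootstrap),
                 alpha = alpha, k = as.integer(k), model = model,
                 frequencies = frequencies, prior = unclass(prior),
                 recovery_threshold = recovery_threshold,
                 slope_categories = as.integer(slope_categories),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Write / read an experiment configuration (lossless JSON round-trip)
#'
#' @param config `experiment_config`.
#' @param path JSON file.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prior <- do.call(branch_length_prior,
                   x$prior[c("internal_shape", "terminal_shape",
                             "internal_scale", "terminal_scale")])
  experiment_config(n_leaves = x$n_leaves, n_sites = x$n_sites,
                    n_replicates = x$n_replicates,
                    n_bootstrap = x$n_bootstrap, alpha = x$alpha, k = x$k,
                    model = x$model, frequencies = x$frequencies,
                    prior = prior,
                    recovery_threshold = x$recovery_threshold,
                    slope_categories = x$slope_categories, seed = x$seed)
}

# Bootstrap an RSAP without materialising the replicated alignment:
# resampling the tandem-replicated columns is a multinomial over the source
# columns whose cell probabilities are the tandem multiplicities, so each
# replicate passes resampled weights to the shared distance grid.
bootstrap_rsap <- function(codes_src, target_length, n_boot, grid, seed) {
  n_src <- ncol(codes_src)
  with_seed(seed, {
    lapply(seq_len(n_boot), function(r) {
      slots <- sample.int(target_length, target_length, replace = TRUE)
      w <- tabulate(((slots - 1L) %% n_src) + 1L, nbins = n_src)
      nj_tree(distance_matrix(codes_src, grid, weights = w))
    })
  })
}

# Mean RF distance of per-tree key sets to a reference key set.
mean_rf_keysets <- function(keysets, ref_keys) {
  mean(vapply(keysets, function(k)
    length(setdiff(k, ref_keys)) + length(setdiff(ref_keys, k)),
    numeric(1)))
}

mean_rf_to_keys <- function(trees, ref_keys, taxa) {
  mean_rf_keysets(lapply(trees, function(tr) tree_splits(tr, taxa)$key),
                  ref_keys)
}

#' Run the slow-fast simulation study end to end
#'
#' For each replicate: simulate an alignment on a fresh random tree, remove
#' invariant sites, assign the variable sites to rate categories against
#' the true tree, build the `k` tandem-replicated partitions, bootstrap
#' each, and score recovery of the true tree's bipartitions. Summaries
#' across replicates include per-category recovery fractions (below-median
#' and top-quartile branch lengths), Spearman correlations between category
#' rate and recovered branch lengths (with BH q-values across replicates),
#' mean RF distance to the true tree per category, and the OLS slope of RF
#' on rate over the fast categories.
#'
#' @param config `experiment_config`.
#' @param out_dir optional directory for TSV/JSON reports.
#' @param verbose log per-replicate progress to stderr.
#' @return object of class `slowfast_study`: list with `config`,
#'   `recovery` (stacked recovery tables), `per_category` (replicate x
#'   category summaries), `replicate_stats`, `summary`.
#' @export
run_simulation_study <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  model <- load_model(config$model, frequencies = config$frequencies)
  cats <- discretize_gamma(config$alpha, config$k)
  # Each RSAP is rate-homogeneous by construction, so its bootstrap
  # distances are estimated under a single rate (the analog of refitting
  # the rate model per partition); the 12-category mixture grid is only
  # appropriate for rate-heterogeneous alignments.
  rsap_grid <- distance_grid(model, discretize_gamma(1, 1))
  prior <- do.call(branch_length_prior, config$prior)
  k <- config$k
  say <- function(...) if (verbose) message(...)

  recovery_all <- list()
  per_cat_all <- list()
  rep_stats <- list()
  for (i in seq_len(config$n_replicates)) {
    res <- tryCatch({
      t0 <- Sys.time()
      topo <- random_topology(config$n_leaves,
                              seed = derive_seed(config$seed, 1, i))
      tree <- assign_branch_lengths(topo, prior,
                                    seed = derive_seed(config$seed, 2, i))
      sim <- evolve_alignment(tree, model, cats, config$n_sites,
                              seed = derive_seed(config$seed, 3, i))
      codes <- encode_alignment(sim$alignment)
      inv <- invariant_columns(codes)
      var_codes <- codes[, !inv, drop = FALSE]
      assignment <- assign_site_categories(var_codes, tree, model, cats)
      bins <- bin_sites(assignment)
      taxa <- sort(tree$tip.label)
      ref <- bipartitions(tree, taxa)

      tabs <- list()
      percat <- list()
      for (c in seq_len(k)) {
        if (!length(bins[[c]])) {
          say("  replicate ", i, ": category ", c, " empty; skipped")
          next
        }
        trees <- bootstrap_rsap(var_codes[, bins[[c]], drop = FALSE],
                                config$n_sites, config$n_bootstrap,
                                rsap_grid,
                                seed = derive_seed(config$seed, 4,
                                                   (i - 1L) * k + c))
        keysets <- lapply(trees, function(tr) tree_splits(tr, taxa)$key)
        tab <- recovery_from_support(ref, support_from_keysets(keysets),
                                     config$recovery_threshold,
                                     partition = c,
                                     mean_rate = cats$rates[c])
        tab$replicate <- i
        tabs[[c]] <- tab
        percat[[c]] <- data.frame(
          replicate = i, category = c, mean_rate = cats$rates[c],
          n_sites = length(bins[[c]]),
          mean_rf = mean_rf_keysets(keysets, ref$key))
      }
      tabs <- do.call(rbind, tabs)
      percat <- do.call(rbind, percat)
      stats <- recovery_statistics(tabs)
      slope <- rf_slope(percat$mean_rf, percat$mean_rate,
                        which(percat$category %in% config$slope_categories))
      say("replicate ", i, "/", config$n_replicates, " done (",
          sum(inv), " invariant sites; ",
          format(Sys.time() - t0, digits = 3), ")")
      list(tabs = tabs, percat = percat,
           stats = data.frame(
             replicate = i, n_invariant = sum(inv),
             rho_pooled = stats$rho_pooled, p_pooled = stats$p_pooled,
             rho_median = stats$rho_median, p_median = stats$p_median,
             rf_slope_fast = slope),
           per_partition = cbind(replicate = i, stats$per_partition))
    }, error = function(e) {
      warning("replicate ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    recovery_all[[i]] <- res$tabs
    per_cat_all[[i]] <- merge(res$percat, res$per_partition,
                              by.x = c("replicate", "category", "mean_rate"),
                              by.y = c("replicate", "partition", "mean_rate"))
    rep_stats[[i]] <- res$stats
  }
  if (!length(rep_stats)) stop("every replicate failed")
  recovery <- do.call(rbind, recovery_all)
  per_category <- do.call(rbind, per_cat_all)
  rep_stats <- do.call(rbind, rep_stats)
  rep_stats$q_pooled <- bh_qvalues(rep_stats$p_pooled)

  agg <- stats::aggregate(
    cbind(below_median_recovery, top_quartile_recovery, mean_rf) ~
      category + mean_rate, per_category, mean)
  agg <- agg[order(agg$category), ]
  rownames(agg) <- NULL
  summary <- list(
    n_replicates_done = nrow(rep_stats),
    mean_rho_pooled = mean(rep_stats$rho_pooled, na.rm = TRUE),
    mean_rho_median = mean(rep_stats$rho_median, na.rm = TRUE),
    prop_significant = mean(rep_stats$q_pooled < 0.05, na.rm = TRUE),
    mean_rf_slope_fast = mean(rep_stats$rf_slope_fast, na.rm = TRUE),
    category_summary = agg,
    below_median_recovery_slowest =
      agg$below_median_recovery[match(min(agg$category), agg$category)],
    below_median_recovery_fastest =
      agg$below_median_recovery[match(max(agg$category), agg$category)],
    min_top_quartile_recovery = min(agg$top_quartile_recovery),
    rf_argmax_category = agg$category[which.max(agg$mean_rf)],
    rf_argmin_category = agg$category[which.min(agg$mean_rf)])

  study <- structure(list(config = config, recovery = recovery,
                          per_category = per_category,
                          replicate_stats = rep_stats, summary = summary),
                     class = "slowfast_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.slowfast_study <- function(x, ...) {
  s <- x$summary
  cat("Slow-fast simulation study:", s$n_replicates_done, "replicates,",
      x$config$n_leaves, "leaves,", x$config$n_sites, "sites\n")
  cat(sprintf("  mean pooled Spearman rho (rate vs recovered branch length): %.3f\n",
              s$mean_rho_pooled))
  cat(sprintf("  below-median-branch recovery: slowest %.1f%%, fastest %.1f%%\n",
              100 * s$below_median_recovery_slowest,
              100 * s$below_median_recovery_fastest))
  cat(sprintf("  minimum top-quartile recovery across categories: %.1f%%\n",
              100 * s$min_top_quartile_recovery))
  cat("  RF to true tree maximal in category", s$rf_argmax_category,
      ", minimal in category", s$rf_argmin_category, "\n")
  invisible(x)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(study$recovery, file.path(out_dir, "recovery_table.tsv"))
  write_tsv(study$per_category, file.path(out_dir, "per_category.tsv"))
  write_tsv(study$replicate_stats, file.path(out_dir, "replicate_stats.tsv"))
  write_tsv(study$summary$category_summary,
            file.path(out_dir, "category_summary.tsv"))
  write_config(study$config, file.path(out_dir, "config.json"))
  jsonlite::write_json(
    study$summary[setdiff(names(study$summary), "category_summary")],
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Audit a user-supplied alignment with the slow-fast pipeline
#'
#' Applies the full machinery to data rather than simulations: invariant
#' sites are removed, sites are assigned to rate categories against a guide
#' tree (user-supplied, or an ML-distance NJ tree built from the alignment),
#' the three canonical trimming schemes are materialised, and each
#' tandem-replicated partition is bootstrapped and compared to the guide
#' tree (support, recovery, RF, composition; optional tree-space MDS).
#'
#' @param alignment character matrix, coercible object, or FASTA path.
#' @param tree optional guide `phylo` or Newick path; estimated when `NULL`.
#' @param config `experiment_config` (its `alpha`, `k`, `model`,
#'   `n_bootstrap`, `recovery_threshold`, `seed` fields are used).
#' @param out_dir optional output directory for TSV/FASTA/Newick reports.
#' @param mds also compute a classical MDS embedding of the RF matrix of a
#'   subsample of bootstrap trees (plus the guide tree).
#' @param mds_trees_per_partition trees subsampled per partition for MDS.
#' @return list with `assignment`, `bins`, `trim_report`, `trimmed`
#'   (named list of trimmed alignments), `recovery`, `statistics`,
#'   `composition`, `guide_tree`, and optionally `mds`.
#' @export
run_audit <- function(alignment, tree = NULL, config = experiment_config(),
                      out_dir = NULL, mds = FALSE,
                      mds_trees_per_partition = 100) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) alignment <- read_alignment(alignment)
  alignment <- as_alignment(alignment)
  if (nrow(alignment) < 4L)
    stop("refusing to audit an alignment with fewer than 4 taxa")
  if (is.character(tree) && length(tree) == 1L) tree <- ape::read.tree(tree)
  model <- load_model(config$model, frequencies = config$frequencies)
  cats <- discretize_gamma(config$alpha, config$k)
  grid <- distance_grid(model, cats)
  rsap_grid <- distance_grid(model, discretize_gamma(1, 1))

  vs <- remove_invariant_sites(alignment)
  var_aln <- vs$alignment
  var_codes <- encode_alignment(var_aln)
  if (is.null(tree))
    tree <- nj_tree(distance_matrix(var_codes, grid))
  assignment <- assign_site_categories(var_codes, tree, model, cats)
  bins <- bin_sites(assignment)

  schemes <- c("none", "slow_trim", "fast_trim", "both_trim")
  trimmed <- lapply(schemes, function(s)
    apply_trim(var_aln, assignment, trim_scheme(s)))
  names(trimmed) <- schemes
  trim_report <- data.frame(
    scheme = schemes,
    n_sites = vapply(trimmed, ncol, integer(1)),
    n_removed = vapply(trimmed, function(a)
      length(attr(a, "removed_sites")), integer(1)))

  target <- ncol(alignment)
  tabs <- list(); mean_rf <- numeric(0); kept <- integer(0)
  mds_trees <- list()
  taxa <- sort(tree$tip.label)
  ref <- bipartitions(tree, taxa)
  for (c in seq_len(config$k)) {
    if (!length(bins[[c]])) next
    trees <- bootstrap_rsap(var_codes[, bins[[c]], drop = FALSE], target,
                            config$n_bootstrap, rsap_grid,
                            seed = derive_seed(config$seed, 5, c))
    tabs[[c]] <- compatible_reference_bipartitions(
      tree, trees, threshold = config$recovery_threshold,
      partition = c, mean_rate = cats$rates[c])
    mean_rf <- c(mean_rf, mean_rf_to_keys(trees, ref$key, taxa))
    kept <- c(kept, c)
    if (mds) {
      pick <- with_seed(derive_seed(config$seed, 6, c),
        sample.int(length(trees), min(mds_trees_per_partition, length(trees))))
      sub <- trees[pick]
      names(sub) <- paste0("RSAP", c, "_", seq_along(sub))
      mds_trees <- c(mds_trees, sub)
    }
  }
  recovery <- do.call(rbind, tabs)
  statistics <- recovery_statistics(recovery)
  statistics$mean_rf <- data.frame(category = kept, mean_rf = mean_rf)
  rsaps <- lapply(kept, function(c)
    build_rsap(var_aln, bins[[c]], target, category = c))
  comp <- composition_table(var_aln, rsaps)

  out <- list(assignment = assignment, bins = bins,
              trim_report = trim_report, trimmed = trimmed,
              recovery = recovery, statistics = statistics,
              composition = comp, guide_tree = tree)
  if (mds && length(mds_trees) > 1) {
    mds_trees <- c(mds_trees, list(reference = tree))
    m <- rf_matrix(mds_trees)
    out$mds <- data.frame(tree = names(mds_trees), mds_embedding(m))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in schemes)
      write_alignment(trimmed[[s]], file.path(out_dir, paste0(s, ".fasta")))
    write_site_rates(assignment, file.path(out_dir, "site_rates.tsv"))
    write_tsv(trim_report, file.path(out_dir, "trim_report.tsv"))
    write_tsv(recovery, file.path(out_dir, "recovery_table.tsv"))
    write_tsv(comp, file.path(out_dir, "composition.tsv"))
    ape::write.tree(tree, file.path(out_dir, "guide_tree.nwk"))
    if (!is.null(out$mds)) write_tsv(out$mds, file.path(out_dir, "mds.tsv"))
  }
  out
}
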