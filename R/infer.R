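#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch-length
#' estimates are clamped to zero. Three taxa resolve to the unique star
#' with closed-form lengths.
#'
#' @param d symmetric distance matrix with taxa dimnames, or an
#'   `ml_distances` object from [distance_matrix()].
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "ml_distances")) d <- d$distance
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Nonparametric bootstrap tree sample
#'
#' Classical bootstrap over alignment columns: each replicate resamples
#' columns with replacement, re-estimates all pairwise ML distances (via the
#' shared likelihood grid) and rebuilds a neighbor-joining tree. This is the
#' package's stand-in for ML-search bootstrap methods: it preserves the
#' object the downstream statistics consume, a sample of trees per
#' partition. Externally produced samples can be ingested with
#' [read_tree_sample()].
#'
#' @param alignment character matrix, coercible object, or integer codes.
#' @param n_replicates number of bootstrap trees.
#' @param model `rate_model`.
#' @param cats `gamma_categories`.
#' @param seed RNG seed.
#' @param grid optional precomputed [distance_grid()] (built if missing).
#' @param source identifier of the partition the sample came from.
#' @return object of class `bootstrap_sample`: list with `trees`
#'   (a `multiPhylo` list), `n_replicates`, `source`, `seed`, `method`.
#' @export
bootstrap_trees <- function(alignment, n_replicates, model, cats,
                            seed = NULL, grid = NULL, source = NA_character_) {
  codes <- if (is.matrix(alignment) && is.integer(alignment)) alignment
           else encode_alignment(alignment)
  if (nrow(codes) < 4L) stop("need at least 4 taxa")
  S <- ncol(codes)
  if (S < 1L) stop("need at least 1 site")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (is.null(grid)) grid <- distance_grid(model, cats)
  run <- function() {
    lapply(seq_len(n_replicates), function(r) {
      w <- tabulate(sample.int(S, S, replace = TRUE), nbins = S)
      d <- distance_matrix(codes, grid, weights = w)
      tr <- nj_tree(d)
      attr(tr, "n_saturated_pairs") <- sum(d$saturated) / 2
      tr
    })
  }
  trees <- if (is.null(seed)) run() else with_seed(seed, run())
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, n_replicates = as.integer(n_replicates),
                 source = source, seed = seed,
                 method = "nonparametric bootstrap, ML distance + NJ"),
            class = "bootstrap_sample")
}

#' Wrap externally produced trees as a bootstrap sample
#'
#' @param path multi-tree Newick file (one tree per line).
#' @param source identifier of the partition the sample came from.
#' @return `bootstrap_sample` with `method = "external"`.
#' @export
read_tree_sample <- function(path, source = basename(path)) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    class(trees) <- "multiPhylo"
  }
  structure(list(trees = trees, n_replicates = length(trees),
                 source = source, seed = NA_integer_, method = "external"),
            class = "bootstrap_sample")
}

#' Write a bootstrap sample as multi-tree Newick
#'
#' @param sample `bootstrap_sample`.
#' @param path output file (one Newick tree per line).
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path) {
  stopifnot(inherits(sample, "bootstrap_sample"))
  ape::write.tree(sample$trees, path)
  invisible(path)
}

#' Score a substitution model on a fixed tree
#'
#' Total log-likelihood by pruning under a homogeneous rate (one category),
#' plus a BIC penalty: empirical frequencies (`+F`) add 19 free parameters;
#' `BIC = -2 loglik + p log(n_sites)`.
#'
#' @param alignment character matrix or coercible object.
#' @param tree fixed `phylo` with branch lengths.
#' @param model `rate_model`.
#' @param use_empirical_freqs replace the model's default frequencies by the
#'   alignment's observed residue frequencies.
#' @return list with `log_likelihood`, `n_parameters`, `bic`, `model`,
#'   `frequencies` (`"default"` or `"empirical"`).
#' @export
score_model <- function(alignment, tree, model, use_empirical_freqs = FALSE) {
  codes <- if (is.matrix(alignment) && is.integer(alignment)) alignment
           else encode_alignment(alignment)
  if (use_empirical_freqs) {
    freqs <- tabulate(codes[!is.na(codes)], nbins = 20L)
    model <- rate_model(paste0(model$name, "+F"), model$exchangeabilities,
                        freqs / sum(freqs))
  }
  ll <- sum(site_log_likelihoods(codes, tree, model, rates = 1))
  p <- if (use_empirical_freqs) 19L else 0L
  list(log_likelihood = ll, n_parameters = p,
       bic = -2 * ll + p * log(ncol(codes)),
       model = sub("\\+F$", "", model$name),
       frequencies = if (use_empirical_freqs) "empirical" else "default")
}

#' Fixed-tree model selection over standard models and frequency choices
#'
#' Scores the eight combinations of \{LG, WAG, Dayhoff, JTT\} x
#' \{default, empirical frequencies\} on a fixed tree with homogeneous
#' rates, and selects the BIC-minimal one.
#'
#' @param alignment character matrix or coercible object.
#' @param tree fixed `phylo` with branch lengths.
#' @param models model names to score.
#' @return data.frame (one row per combination: `model`, `frequencies`,
#'   `log_likelihood`, `n_parameters`, `bic`) with the winner in attribute
#'   `best` and flagged in column `best`.
#' @export
select_model <- function(alignment, tree,
                         models = c("LG", "WAG", "Dayhoff", "JTT")) {
  codes <- encode_alignment(as_alignment(alignment))
  rows <- list()
  for (m in models) {
    mod <- load_model(m)
    for (emp in c(FALSE, TRUE)) {
      rows[[length(rows) + 1L]] <-
        as.data.frame(score_model(codes, tree, mod, emp))
    }
  }
  out <- do.call(rbind, rows)[, c("model", "frequencies", "log_likelihood",
                                  "n_parameters", "bic")]
  out$best <- seq_len(nrow(out)) == which.min(out$bic)
  attr(out, "best") <- paste0(out$model[out$best],
                              ifelse(out$frequencies[out$best] == "empirical",
                                     "+F", ""))
  out
}

#' Branch-length profile under taxon subsampling
#'
#' For each sampling fraction, repeatedly draws a random taxon subset
#' without replacement, re-infers the tree on the restricted alignment
#' (ML distances + NJ) and records its mean branch length. Mirrors the
#' observation that denser taxon sampling shortens reconstructed branches.
#'
#' @param alignment character matrix or coercible object.
#' @param fractions sampling fractions in (0, 1].
#' @param n_reps replicates per fraction.
#' @param model `rate_model`.
#' @param cats `gamma_categories`.
#' @param seed RNG seed.
#' @param grid optional precomputed [distance_grid()].
#' @return data.frame with one row per fraction: `fraction`, `n_taxa`,
#'   `mean_branch_length` (averaged over replicates), `n_reps`; per-replicate
#'   values in attribute `replicates`. Fractions yielding fewer than 4 taxa
#'   are skipped with a warning.
#' @export
subsample_branch_profile <- function(alignment, fractions, n_reps, model,
                                     cats, seed = NULL, grid = NULL) {
  codes <- encode_alignment(as_alignment(alignment))
  stopifnot(all(fractions > 0), all(fractions <= 1), n_reps >= 1)
  if (is.null(grid)) grid <- distance_grid(model, cats)
  n <- nrow(codes)
  run <- function() {
    reps <- list()
    for (f in fractions) {
      m <- round(f * n)
      if (m < 4L) {
        warning("fraction ", f, " gives ", m, " taxa (< 4); skipped")
        next
      }
      for (r in seq_len(n_reps)) {
        taxa <- if (m == n) seq_len(n) else sample.int(n, m)
        d <- distance_matrix(codes[taxa, , drop = FALSE], grid)
        tr <- nj_tree(d)
        reps[[length(reps) + 1L]] <-
          data.frame(fraction = f, rep = r, n_taxa = m,
                     mean_branch_length = mean(tr$edge.length))
      }
    }
    do.call(rbind, reps)
  }
  reps <- if (is.null(seed)) run() else with_seed(seed, run())
  if (is.null(reps))
    return(structure(data.frame(fraction = numeric(0), n_taxa = integer(0),
                                mean_branch_length = numeric(0),
                                n_reps = integer(0)),
                     replicates = NULL))
  out <- stats::aggregate(mean_branch_length ~ fraction + n_taxa, reps, mean)
  out <- out[order(out$fraction), c("fraction", "n_taxa", "mean_branch_length")]
  out$n_reps <- n_reps
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}
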