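# Canonical bipartition keys
#
# A bipartition (split) is the pair of leaf sets induced by removing an
# internal edge. Splits are keyed by the member indices (into the sorted
# global taxon vector) of the side containing the first taxon, so the key is
# rooting- and orientation-invariant.

split_key <- function(member_idx, n_taxa) {
  side <- sort(member_idx)
  if (!(1L %in% side)) side <- setdiff(seq_len(n_taxa), side)
  paste(side, collapse = ",")
}

# Fast split extraction shared by all comparison code: canonical keys,
# smaller-side sizes and branch lengths of every non-trivial split.
tree_splits <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  if (length(setdiff(tree$tip.label, taxa)))
    stop("taxa must contain all tip labels")
  tip_global <- match(tree$tip.label, taxa)
  N <- length(taxa)
  pp <- ape::prop.part(tree)   # clades, indexed by internal node - ntip
  internal_edges <- which(tree$edge[, 2] > ntip)
  m <- length(internal_edges)
  keys <- character(m); sizes <- integer(m); lens <- numeric(m)
  keep <- logical(m)
  has_el <- !is.null(tree$edge.length)
  for (idx in seq_len(m)) {
    e <- internal_edges[idx]
    clade <- tip_global[pp[[tree$edge[e, 2] - ntip]]]
    sz <- length(clade)
    if (sz < 2L || sz > N - 2L) next
    keep[idx] <- TRUE
    keys[idx] <- split_key(clade, N)
    sizes[idx] <- min(sz, N - sz)
    lens[idx] <- if (has_el) tree$edge.length[e] else NA_real_
  }
  ok <- keep & !duplicated(keys)
  list(key = keys[ok], size = sizes[ok], length = lens[ok])
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One canonical bipartition per internal edge; a binary unrooted `n`-leaf
#' tree yields `n - 3`. Multifurcating nodes contribute fewer.
#'
#' @param tree `phylo` with >= 4 leaves.
#' @param taxa global taxon ordering used for canonical keys (default: the
#'   tree's sorted tip labels); must contain all tip labels.
#' @return data.frame with columns `key` (canonical split key), `size`
#'   (smaller side size), and `length` (the internal edge's branch length,
#'   `NA` if the tree has none).
#' @export
bipartitions <- function(tree, taxa = sort(tree$tip.label)) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves")
  as.data.frame(tree_splits(tree, taxa), stringsAsFactors = FALSE)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets, plus the variant normalised by the total number of
#' bipartitions in both trees.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets.
#' @return list with `rf` (integer) and `normalized` (in `[0, 1]`, 0 when
#'   both trees are stars).
#' @export
rf_distance <- function(t1, t2) {
  if (length(setdiff(t1$tip.label, t2$tip.label)) ||
      length(setdiff(t2$tip.label, t1$tip.label)))
    stop("leaf sets differ: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  taxa <- sort(t1$tip.label)
  b1 <- bipartitions(t1, taxa)$key
  b2 <- bipartitions(t2, taxa)$key
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  denom <- length(b1) + length(b2)
  list(rf = as.integer(rf),
       normalized = if (denom == 0) 0 else rf / denom)
}

#' Bipartition support frequencies in a tree sample
#'
#' @param sample `bootstrap_sample` (or bare list of `phylo`).
#' @return named numeric vector: canonical split key -> fraction of trees
#'   containing the split.
#' @export
support_frequencies <- function(sample) {
  trees <- if (inherits(sample, "bootstrap_sample")) sample$trees else sample
  if (!length(trees)) stop("empty tree sample")
  taxa <- sort(trees[[1]]$tip.label)
  keysets <- lapply(trees, function(tr) tree_splits(tr, taxa)$key)
  support_from_keysets(keysets)
}

support_from_keysets <- function(keysets) {
  tab <- table(unlist(keysets)) / length(keysets)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Recovery of reference bipartitions by a bootstrap sample
#'
#' One row per non-trivial reference bipartition: its branch length, its
#' support frequency in the sample, and whether it is recovered at the
#' threshold (present in at least `threshold` of the trees).
#'
#' @param reference reference `phylo` (with branch lengths).
#' @param sample `bootstrap_sample` sharing the reference leaf set.
#' @param threshold support threshold in (0, 1] (default 0.8).
#' @param partition identifier of the partition the sample came from.
#' @param mean_rate the partition's mean category rate (carried along).
#' @return data.frame (`recovery_table`): `partition`, `mean_rate`, `key`,
#'   `length`, `support`, `recovered`.
#' @export
compatible_reference_bipartitions <- function(reference, sample,
                                              threshold = 0.8,
                                              partition = NA,
                                              mean_rate = NA_real_) {
  stopifnot(threshold > 0, threshold <= 1)
  trees <- if (inherits(sample, "bootstrap_sample")) sample$trees else sample
  if (length(setdiff(reference$tip.label, trees[[1]]$tip.label)))
    stop("sample trees and reference must share one leaf set")
  taxa <- sort(reference$tip.label)
  ref <- bipartitions(reference, taxa)
  recovery_from_support(ref, support_frequencies(sample), threshold,
                        partition, mean_rate)
}

recovery_from_support <- function(ref, supp, threshold, partition, mean_rate) {
  s <- supp[ref$key]
  s[is.na(s)] <- 0
  data.frame(partition = partition, mean_rate = mean_rate,
             key = ref$key, length = ref$length,
             support = as.numeric(s),
             recovered = as.numeric(s) >= threshold)
}

# Spearman correlation: exact permutation p-values
# below 10 pairs (when ties permit), t approximation otherwise.
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = length(x) < 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Summary statistics of bipartition recovery across partitions
#'
#' Takes the stacked recovery tables of all partitions of one analysis
#' (see [compatible_reference_bipartitions()]) and computes, per partition:
#' the median branch length of recovered splits, the fraction of
#' below-median-branch reference splits recovered, and the fraction of
#' top-quartile-branch reference splits recovered. The median and quartile
#' are taken over the reference tree's internal branch lengths. Across
#' partitions it reports Spearman's correlation between mean category rate
#' and (i) the median recovered branch length and (ii) the pooled branch
#' lengths of all recovered splits.
#'
#' @param tables data.frame: stacked recovery tables with columns
#'   `partition`, `mean_rate`, `key`, `length`, `support`, `recovered`.
#' @return list with `per_partition` (data.frame), `rho_median`, `p_median`,
#'   `rho_pooled`, `p_pooled`.
#' @export
recovery_statistics <- function(tables) {
  need <- c("partition", "mean_rate", "length", "recovered")
  if (!all(need %in% names(tables))) stop("malformed recovery table")
  if (length(unique(tables$partition)) < 3L)
    stop("need at least 3 partitions")
  ref_lengths <- tables$length[!duplicated(tables$key)]
  med <- stats::median(ref_lengths)
  q75 <- stats::quantile(ref_lengths, 0.75, names = FALSE)
  per <- do.call(rbind, lapply(split(tables, tables$partition), function(d) {
    data.frame(
      partition = d$partition[1],
      mean_rate = d$mean_rate[1],
      n_recovered = sum(d$recovered),
      median_recovered_length =
        if (any(d$recovered)) stats::median(d$length[d$recovered]) else NA_real_,
      below_median_recovery =
        mean(d$recovered[d$length < med]),
      top_quartile_recovery =
        mean(d$recovered[d$length >= q75]))
  }))
  per <- per[order(per$mean_rate), ]
  rownames(per) <- NULL
  ct_med <- spearman(per$mean_rate, per$median_recovered_length)
  rec <- tables[tables$recovered, ]
  ct_pool <- spearman(rec$mean_rate, rec$length)
  list(per_partition = per,
       rho_median = ct_med$rho, p_median = ct_med$p,
       rho_pooled = ct_pool$rho, p_pooled = ct_pool$p)
}

#' OLS slope of RF distance on category rate
#'
#' Ordinary least squares of the per-partition mean RF distance (bootstrap
#' trees vs the reference) on the partition's mean category rate, over a
#' selected range of categories.
#'
#' @param mean_rf numeric vector of per-partition mean RF distances.
#' @param rates matching vector of mean category rates.
#' @param category_range indices of the categories to regress over
#'   (default: all).
#' @return OLS slope (scalar).
#' @export
rf_slope <- function(mean_rf, rates, category_range = seq_along(mean_rf)) {
  stopifnot(length(mean_rf) == length(rates))
  x <- rates[category_range]; y <- mean_rf[category_range]
  if (length(x) < 2L) stop("need at least 2 categories in range")
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p vector of p-values (one per simulation replicate or test).
#' @return vector of BH q-values.
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Classical MDS embedding of a tree-distance matrix
#'
#' Torgerson scaling of the squared distances (top-2 eigenvectors scaled by
#' root eigenvalues), deterministic up to axis sign. An all-zero matrix
#' embeds every point at the origin.
#'
#' @param rf_matrix symmetric, zero-diagonal distance matrix.
#' @return n x 2 coordinate matrix.
#' @export
mds_embedding <- function(rf_matrix) {
  d <- as.matrix(rf_matrix)
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (all(d == 0)) return(matrix(0, nrow(d), 2,
                                 dimnames = list(rownames(d), NULL)))
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  rownames(xy) <- rownames(d)
  xy
}

#' Pairwise RF distance matrix among trees
#'
#' @param trees list of `phylo` (or `multiPhylo`) with one shared leaf set.
#' @param normalized use the normalised RF variant.
#' @return symmetric matrix of RF distances.
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  n <- length(trees)
  taxa <- sort(trees[[1]]$tip.label)
  keysets <- lapply(trees, function(tr) bipartitions(tr, taxa)$key)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rf <- length(setdiff(keysets[[i]], keysets[[j]])) +
      length(setdiff(keysets[[j]], keysets[[i]]))
    if (normalized) {
      denom <- length(keysets[[i]]) + length(keysets[[j]])
      rf <- if (denom == 0) 0 else rf / denom
    }
    m[i, j] <- m[j, i] <- rf
  }
  dimnames(m) <- list(names(trees), names(trees))
  m
}
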