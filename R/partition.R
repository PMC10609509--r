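#' Remove invariant alignment columns
#'
#' A column is invariant when it contains at most one distinct non-gap
#' residue (gaps are ignored, so `"AA-A"` counts as invariant).
#'
#' @param alignment character matrix or coercible object.
#' @return list with `alignment` (variable columns only) and `removed`
#'   (1-based original indices of the invariant columns). The retained
#'   columns' original indices are in attribute `kept`.
#' @export
remove_invariant_sites <- function(alignment) {
  alignment <- as_alignment(alignment)
  if (ncol(alignment) == 0L || nrow(alignment) == 0L)
    stop("empty alignment")
  inv <- invariant_columns(encode_alignment(alignment))
  out <- list(alignment = alignment[, !inv, drop = FALSE],
              removed = which(inv), kept = which(!inv))
  out
}

#' Group variable sites by assigned rate category
#'
#' @param assignment `site_rate_assignment`.
#' @return list of `k` ascending integer vectors of column indices (relative
#'   to the alignment the assignment was made on); empty bins are allowed.
#' @export
bin_sites <- function(assignment) {
  stopifnot(inherits(assignment, "site_rate_assignment"))
  k <- assignment$n_categories
  lapply(seq_len(k), function(c) which(!is.na(assignment$category) &
                                       assignment$category == c))
}

#' Build a rate-specific alignment partition (RSAP) by tandem replication
#'
#' The selected source columns are repeated in cyclic tandem order
#' (`a b c a b c a b ...`) and truncated at exactly `target_length`, so all
#' partitions carry the same number of informative sites regardless of how
#' many sites their category contains.
#'
#' @param alignment character matrix or coercible object.
#' @param sites ascending 1-based column indices (non-empty).
#' @param target_length number of columns of the replicated alignment.
#' @param category optional category index, carried along for reporting.
#' @return object of class `rsap`: list with `category`, `source_sites`,
#'   `replicated_alignment`, `target_length`.
#' @export
build_rsap <- function(alignment, sites, target_length, category = NA_integer_) {
  alignment <- as_alignment(alignment)
  if (length(sites) == 0L)
    stop("cannot build RSAP", if (!is.na(category)) paste0(" for category ", category),
         ": empty site list")
  if (target_length < 1) stop("target_length must be >= 1")
  stopifnot(all(sites >= 1), all(sites <= ncol(alignment)))
  idx <- sites[((seq_len(target_length) - 1L) %% length(sites)) + 1L]
  structure(list(category = category,
                 source_sites = sites,
                 replicated_alignment = alignment[, idx, drop = FALSE],
                 target_length = as.integer(target_length)),
            class = "rsap")
}

#' @export
print.rsap <- function(x, ...) {
  cat("RSAP", if (!is.na(x$category)) paste0("(category ", x$category, ")"),
      ": ", length(x$source_sites), " source sites replicated to ",
      x$target_length, " columns\n", sep = "")
  invisible(x)
}

#' Trimming schemes over substitution rate categories
#'
#' The canonical schemes of a 12-category analysis: `slow_trim` drops
#' categories 1-4, `fast_trim` drops 10-12, `both_trim` drops their union
#' (keeping 5-9), `none` drops nothing. A custom set can be given via
#' `dropped`.
#'
#' @param name one of `"slow_trim"`, `"fast_trim"`, `"both_trim"`, `"none"`,
#'   or `"custom"`.
#' @param dropped integer set of dropped categories (required for
#'   `"custom"`, ignored otherwise).
#' @return object of class `trim_scheme`: list with `name`,
#'   `dropped_categories`.
#' @export
trim_scheme <- function(name = c("none", "slow_trim", "fast_trim",
                                 "both_trim", "custom"),
                        dropped = NULL) {
  name <- match.arg(name)
  dropped_categories <- switch(name,
    none = integer(0),
    slow_trim = 1:4,
    fast_trim = 10:12,
    both_trim = c(1:4, 10:12),
    custom = {
      if (is.null(dropped)) stop("custom scheme needs 'dropped'")
      sort(unique(as.integer(dropped)))
    })
  structure(list(name = name, dropped_categories = dropped_categories),
            class = "trim_scheme")
}

#' Trim alignment columns by rate category
#'
#' Removes every column whose assigned category belongs to the scheme's
#' dropped set; column order is preserved. Invariant (category-free)
#' columns are never dropped.
#'
#' @param alignment character matrix or coercible object; columns must
#'   correspond one-to-one to `assignment`.
#' @param assignment `site_rate_assignment` for the same columns.
#' @param scheme `trim_scheme`.
#' @return trimmed alignment with attributes `removed_sites` (1-based
#'   indices removed) and `kept_sites`.
#' @export
apply_trim <- function(alignment, assignment, scheme) {
  alignment <- as_alignment(alignment)
  stopifnot(inherits(assignment, "site_rate_assignment"),
            inherits(scheme, "trim_scheme"),
            ncol(alignment) == length(assignment$category))
  drop <- !is.na(assignment$category) &
    assignment$category %in% scheme$dropped_categories
  out <- alignment[, !drop, drop = FALSE]
  attr(out, "removed_sites") <- which(drop)
  attr(out, "kept_sites") <- which(!drop)
  attr(out, "scheme") <- scheme$name
  out
}

#' Classify alignment columns by the gap content of their flanks
#'
#' Each column is labelled by the gap counts of its neighbouring columns
#' within `window` positions on each side: `"rich"` if every flanking
#' column has at least `rich_threshold` gaps, `"poor"` if every flanking
#' column has at most `poor_threshold` gaps, `"intermediate"` otherwise.
#' Terminal columns use only the side that exists. Thresholds below 1 are
#' interpreted as fractions of the number of taxa, so the scheme scales
#' across alignment sizes.
#'
#' @param alignment character matrix or coercible object (may contain gaps).
#' @param rich_threshold gap count (or fraction of taxa) defining gap-rich
#'   flanks; default 2000 gaps.
#' @param poor_threshold gap count (or fraction) defining gap-poor flanks;
#'   default 500 gaps.
#' @param window flanking columns examined on each side (default 1).
#' @return character vector of per-column labels.
#' @export
classify_gap_context <- function(alignment, rich_threshold = 2000,
                                 poor_threshold = 500, window = 1) {
  alignment <- as_alignment(alignment)
  n_taxa <- nrow(alignment)
  if (rich_threshold < 1) rich_threshold <- rich_threshold * n_taxa
  if (poor_threshold < 1) poor_threshold <- poor_threshold * n_taxa
  if (!(rich_threshold > poor_threshold) || poor_threshold < 0)
    stop("need rich_threshold > poor_threshold >= 0")
  S <- ncol(alignment)
  gaps <- colSums(is.na(encode_alignment(alignment)))
  vapply(seq_len(S), function(j) {
    flanks <- c(if (j > 1L) max(1L, j - window):(j - 1L),
                if (j < S) (j + 1L):min(S, j + window))
    if (!length(flanks)) return("intermediate")
    g <- gaps[flanks]
    if (all(g >= rich_threshold)) "rich"
    else if (all(g <= poor_threshold)) "poor"
    else "intermediate"
  }, character(1))
}
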