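#' Amino-acid composition of an alignment or partition
#'
#' Residue counts over all non-gap cells, normalised to frequencies in PAML
#' residue order.
#'
#' @param alignment character matrix, coercible object, or integer codes.
#' @param partition optional partition identifier carried along.
#' @return object of class `composition_profile`: list with `frequencies`
#'   (named 20-vector), `n_residues`, `partition`.
#' @export
aa_frequencies <- function(alignment, partition = NA) {
  codes <- if (is.matrix(alignment) && is.integer(alignment)) alignment
           else encode_alignment(alignment)
  cnt <- tabulate(codes[!is.na(codes)], nbins = 20L)
  n <- sum(cnt)
  if (n == 0L) stop("alignment contains no residues (all gaps)")
  freqs <- cnt / n
  names(freqs) <- AA_ORDER
  structure(list(frequencies = freqs, n_residues = n, partition = partition),
            class = "composition_profile")
}

#' Sum of squared errors between two composition profiles
#'
#' The compositional-bias statistic: \eqn{\sum_{a} (f^{part}_a -
#' f^{whole}_a)^2} over the 20 residues. Zero iff the profiles coincide;
#' symmetric in its arguments.
#'
#' @param partition `composition_profile` of a partition.
#' @param whole `composition_profile` of the baseline (by convention the
#'   variable-site alignment).
#' @return scalar SSE.
#' @export
composition_sse <- function(partition, whole) {
  stopifnot(inherits(partition, "composition_profile"),
            inherits(whole, "composition_profile"))
  sum((partition$frequencies - whole$frequencies)^2)
}

#' Per-partition composition table
#'
#' One row per partition: the 20 residue frequencies, residue count, and
#' SSE against the whole-alignment baseline. By default the SSE uses each
#' partition's unique source sites (replication multiplies counts, not
#' information); set `use_replicated = TRUE` to count the tandem-replicated
#' columns instead.
#'
#' @param alignment the whole (variable-site) alignment.
#' @param rsaps list of `rsap` objects.
#' @param use_replicated count replicated columns rather than source sites.
#' @return data.frame, one row per partition plus a `whole` row.
#' @export
composition_table <- function(alignment, rsaps, use_replicated = FALSE) {
  alignment <- as_alignment(alignment)
  whole <- aa_frequencies(alignment, partition = "whole")
  row_of <- function(prof, sse) {
    cbind(data.frame(partition = as.character(prof$partition),
                     n_residues = prof$n_residues, sse = sse),
          as.data.frame(as.list(prof$frequencies)))
  }
  rows <- lapply(rsaps, function(r) {
    cols <- if (use_replicated) r$replicated_alignment
            else alignment[, r$source_sites, drop = FALSE]
    prof <- aa_frequencies(cols, partition = r$category)
    row_of(prof, composition_sse(prof, whole))
  })
  out <- rbind(row_of(whole, 0), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
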