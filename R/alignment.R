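#' @useDynLib slowfast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Amino acids in PAML order; all model tables and code matrices follow it.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters treated as fully missing data (all-ones partial likelihood).
AA_MISSING <- c("-", ".", "?", "X", "B", "Z", "J", "U", "O", "*")

#' Encode an amino-acid alignment as integer codes
#'
#' Converts a character matrix (taxa in rows, sites in columns) into an
#' integer matrix with values 1..20 in PAML residue order
#' (`A R N D C Q E G H I L K M F P S T W Y V`). Gaps and ambiguous residues
#' (`-`, `.`, `?`, `X`, `B`, `Z`, ...) become `NA` and are treated as missing
#' data throughout the package.
#'
#' @param alignment character matrix with taxa as rownames, or an object
#'   coercible via [as_alignment()].
#' @return integer matrix of the same dimensions, `NA` for missing data.
#' @export
encode_alignment <- function(alignment) {
  alignment <- as_alignment(alignment)
  codes <- match(toupper(alignment), AA_ORDER)
  dim(codes) <- dim(alignment)
  dimnames(codes) <- dimnames(alignment)
  codes
}

#' Coerce to the package's alignment representation
#'
#' The working representation is a plain character matrix of single upper-case
#' residues, taxa in rows (rownames are taxon labels), sites in columns.
#' Accepts a character matrix, a named character vector of sequences, or a
#' `Biostrings::AAStringSet`.
#'
#' @param x object to coerce.
#' @return character matrix.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x))) stop("alignment must have taxon rownames")
    return(x)
  }
  if (inherits(x, "AAStringSet")) {
    x <- as.character(x)
  }
  if (is.character(x) && !is.null(names(x))) {
    widths <- unique(nchar(x))
    if (length(widths) != 1L)
      stop("sequences have unequal lengths; not an alignment")
    m <- t(vapply(x, function(s) strsplit(s, "")[[1]], character(widths[1])))
    rownames(m) <- names(x)
    return(toupper(m))
  }
  stop("cannot interpret object as an amino-acid alignment")
}

#' Read an amino-acid alignment from FASTA
#'
#' @param path FASTA file.
#' @return character matrix (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  as_alignment(Biostrings::readAAStringSet(path))
}

#' Write an alignment to FASTA
#'
#' @param alignment character matrix or coercible object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  alignment <- as_alignment(alignment)
  seqs <- Biostrings::AAStringSet(apply(alignment, 1, paste0, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Decode an integer code matrix back to characters (NA -> "-").
decode_alignment <- function(codes) {
  out <- AA_ORDER[codes]
  out[is.na(out)] <- "-"
  dim(out) <- dim(codes)
  dimnames(out) <- dimnames(codes)
  out
}

# Shared TSV conventions: header, no quoting, no row names.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
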