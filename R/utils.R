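# Shared internal helpers: base encoding, reverse complements, input checks.

BASES <- c("A", "C", "G", "T")

# Encode sequences of equal length as an integer matrix of base codes 0..3
# (A,C,G,T), one row per sequence. Non-ACGT characters become NA.
encode_sequences <- function(seqs) {
  if (length(seqs) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1) {
    abort("all sequences must have equal length for encoding", class = "pbem_domain_error")
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  codes <- match(unlist(chars), BASES) - 1L
  matrix(codes, nrow = length(seqs), ncol = len, byrow = TRUE)
}

# Reverse complement of a code matrix (rows are sequences).
revcomp_codes <- function(codes) {
  out <- 3L - codes[, rev(seq_len(ncol(codes))), drop = FALSE]
  out
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `A`/`C`/`G`/`T` alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' Canonical form of k-mers
#'
#' The lexicographic minimum of each k-mer and its reverse complement, the
#' standard key for strand-collapsed k-mer summaries.
#'
#' @param kmers character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmer(c("AAAAAAAT", "TTTTTTTA"))
canonical_kmer <- function(kmers) {
  rc <- reverse_complement(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0(what, " must be positive and finite"), class = "pbem_domain_error")
  }
  invisible(x)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(paste0(what, " contains characters outside A/C/G/T"),
      class = "pbem_domain_error"
    )
  }
  invisible(x)
}
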