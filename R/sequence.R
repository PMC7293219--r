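## Plain-character DNA sequence helpers. Sequences are character scalars or
## vectors over {A,C,G,T} (design contexts may carry N placeholders), always
## written 5'->3'. Biostrings containers are used at the FASTA boundary; the
## internal representation stays base character for cheap vectorised work.

#' Validate a DNA sequence
#'
#' @param seq Character vector of DNA sequences (5'->3').
#' @param allow_n Allow `N` placeholders (used in design contexts)?
#' @return Invisibly `seq`; errors if any sequence is empty or contains a
#'   character outside the allowed alphabet (the first offending position is
#'   reported).
#' @export
validate_dna <- function(seq, allow_n = FALSE) {
  stopifnot(is.character(seq))
  if (any(!nzchar(seq))) stop("empty DNA sequence")
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid character '%s' at position %d of sequence %d",
      substr(seq[i], bad[i], bad[i]), bad[i], i
    ))
  }
  invisible(seq)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed, so the result is again written 5'->3'.
#' An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT") # palindrome: "ACGT"
#' revcomp("AAAA") # "TTTT"
#' @export
revcomp <- function(seq) {
  validate_dna(seq, allow_n = TRUE)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Hamming distance between two equal-length sequences
#'
#' Number of mismatching positions. This is the address-orthogonality
#' criterion used throughout the address-design module (addresses are kept at
#' pairwise distance >= 6 from each other and from each other's reverse
#' complements).
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop(sprintf("unequal lengths: %d vs %d", nchar(a), nchar(b)))
  }
  hamming_cpp(a, b)
}

#' GC fraction of a sequence
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of G+C fractions.
#' @export
gc_fraction <- function(seq) {
  validate_dna(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

#' Longest homopolymer run
#' @param seq Character vector of DNA sequences.
#' @return Integer vector: length of the longest single-base run in each.
#' @export
max_homopolymer <- function(seq) {
  validate_dna(seq)
  vapply(strsplit(seq, "", fixed = TRUE), function(x) {
    max(rle(x)$lengths)
  }, integer(1))
}

#' Draw uniform random DNA sequences
#' @param n Number of sequences.
#' @param width Length of each sequence (nt).
#' @return Character vector of `n` random sequences.
#' @export
random_dna <- function(n, width) {
  stopifnot(n >= 0, width >= 1)
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}
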