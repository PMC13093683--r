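# Small shared helpers. All coordinates in the package are 0-based,
# half-open, on the full amplicon (primers included) unless noted.

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length strings (vectorised over x).
hamming <- function(x, y) {
  stopifnot(all(nchar(x) == nchar(y)))
  mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, x, y, USE.NAMES = FALSE)
}

# Round half away from zero: report-level rounding used throughout so that
# e.g. 0.0555... prints as 0.056 regardless of the platform's banker's
# rounding. Internal comparisons always use unrounded values.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_dna <- function(x) {
  grepl("^[ACGTN]+$", x)
}
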