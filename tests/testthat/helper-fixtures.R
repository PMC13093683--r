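# Shared fixtures built in code.

# Brute-force oracle for repeat-array location: enumerate every start and
# count motif copies by repeated substring comparison; longest run wins,
# leftmost on ties. Independent of the package's right-to-left scan.
oracle_repeat_array <- function(reference, motif) {
  m <- nchar(motif)
  n <- nchar(reference)
  best <- c(-1L, -1L)
  best_len <- 0L
  for (s in 0:(n - m)) {
    k <- 0L
    while (s + (k + 1L) * m <= n &&
           substr(reference, s + k * m + 1L, s + (k + 1L) * m) == motif) {
      k <- k + 1L
    }
    if (k >= 3L && k * m > best_len) {
      best <- c(s, s + k * m)
      best_len <- k * m
    }
  }
  if (best_len == 0L) return(NULL)
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiny hand-built locus whose regions are easy to reason about:
# fwd primer 10 bp, FF 6 bp, (GT)x10, RF 6 bp, rev primer 10 bp.
toy_locus <- function() {
  fwd <- "ACGTACGTAC"
  rev <- "TGCATGCATG"             # 5'->3' on its own strand
  ff <- "AATTCC"
  rf <- "GGCCTT"
  ref <- paste0(fwd, ff, strrep("GT", 10), rf, strseq::revcomp(rev))
  validate_panel(tibble::tibble(
    locus_id = "TOY_STR001", fwd_primer = fwd, rev_primer = rev,
    motif = "GT", reference_amplicon = ref,
    min_len = nchar(ref) - 12L, max_len = nchar(ref) + 12L, role = "str"))
}

# Amplicon sequence for the toy locus with a given repeat count and
# optional literal flank/array overrides.
toy_amplicon <- function(panel, n_repeats = 10L, ff = NULL, rf = NULL,
                         mra = NULL) {
  locus <- panel[1, ]
  ref <- locus$reference_amplicon
  fwd <- substr(ref, 1, locus$insert_start)
  rev_rc <- substr(ref, locus$insert_end + 1, nchar(ref))
  ff <- ff %||% substr(ref, locus$insert_start + 1, locus$mra_start)
  rf <- rf %||% substr(ref, locus$mra_end + 1, locus$insert_end)
  mra <- mra %||% strrep(locus$motif, n_repeats)
  paste0(fwd, ff, mra, rf, rev_rc)
}

# Read tibble of n identical copies of an amplicon at constant Q30.
reads_of <- function(sequence, n, qual_char = "?") {  # "?" = Phred 30
  q <- strrep(qual_char, nchar(sequence))
  tibble::tibble(
    id = sprintf("r%05d", seq_len(n)),
    sequence = rep(sequence, n),
    qual = rep(q, n))
}

# Variant tabulation built directly from (length, count) pairs on the toy
# locus, bypassing read generation: sequences are real amplicons of the
# requested lengths (repeat-count changes; same-length variants get an
# interrupted array).
toy_tabulation <- function(panel, lengths, counts, same_length_variant = FALSE) {
  locus <- panel[1, ]
  unit <- nchar(locus$motif)
  ref_len <- nchar(locus$reference_amplicon)
  seqs <- vapply(seq_along(lengths), function(i) {
    k <- 10L + (lengths[i] - ref_len) %/% unit
    toy_amplicon(panel, n_repeats = k)
  }, character(1))
  if (same_length_variant && length(seqs) >= 2L) {
    # second variant: same length, interrupted array
    k <- 10L + (lengths[2] - ref_len) %/% unit
    mra <- paste0(strrep("GT", k - 1L), "GA")
    seqs[2] <- toy_amplicon(panel, mra = mra)
  }
  tab <- tibble::tibble(locus = locus$locus_id, sequence = seqs,
                        length = nchar(seqs), read_count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(read_count), length, sequence)
  class(tab) <- c("strseq_tabulation", class(tibble::tibble()))
  tab
}

# Published per-locus mismatch counts (26-locus canid panel, paired
# scorings of 84 tissue and 18 scat samples).
published_error_counts <- function() {
  readr::read_tsv(system.file("extdata", "scoring_error_counts.tsv",
                              package = "strseq"),
                  show_col_types = FALSE)
}

`%||%` <- rlang::`%||%`
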