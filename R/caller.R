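# Read filtering, locus assignment, variant tabulation and the ratio-rule
# genotype caller.

#' Filter reads on quality and length
#'
#' Keeps reads whose mean Phred score is at least `min_qual` and whose
#' length is at least `min_read_len` (both boundaries inclusive).
#'
#' @param reads Read tibble (`id`, `sequence`, `qual`).
#' @param thresholds A [calling_thresholds()] object.
#' @return The surviving rows of `reads`.
#' @export
filter_reads <- function(reads, thresholds = calling_thresholds()) {
  if (nrow(reads) == 0L) return(reads)
  keep <- nchar(reads$sequence) >= thresholds$min_read_len &
    mean_phred(reads$qual) >= thresholds$min_qual
  reads[keep, , drop = FALSE]
}

#' Assign reads to panel loci by primer matching
#'
#' A read is assigned to the unique locus whose forward primer matches the
#' read prefix and whose reverse-complemented reverse primer matches the
#' read suffix, each with at most `primer_max_mismatch` substitutions.
#' Reads matching zero or more than one locus are left unassigned (the
#' latter flagged ambiguous).
#'
#' @param reads Read tibble.
#' @param panel A validated `strseq_panel`.
#' @param thresholds A [calling_thresholds()] object.
#' @return `reads` with added columns `locus` (`NA` if unassigned) and
#'   `ambiguous` (logical).
#' @export
assign_locus <- function(reads, panel, thresholds = calling_thresholds()) {
  n <- nrow(reads)
  if (n == 0L) {
    reads$locus <- character(0)
    reads$ambiguous <- logical(0)
    return(reads)
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  widths <- nchar(reads$sequence)
  mm <- thresholds$primer_max_mismatch
  n_hits <- integer(n)
  locus <- rep(NA_character_, n)
  for (i in seq_len(nrow(panel))) {
    nf <- nchar(panel$fwd_primer[i])
    nr <- nchar(panel$rev_primer[i])
    fwd <- Biostrings::DNAString(panel$fwd_primer[i])
    rev_rc <- Biostrings::DNAString(revcomp(panel$rev_primer[i]))
    idx <- which(widths >= nf + nr)
    if (length(idx) == 0L) next
    pre <- Biostrings::subseq(seqs[idx], start = 1L, width = nf)
    suf <- Biostrings::subseq(seqs[idx], start = widths[idx] - nr + 1L,
                              width = nr)
    mism_f <- drop(Biostrings::neditStartingAt(fwd, pre, starting.at = 1L))
    mism_r <- drop(Biostrings::neditStartingAt(rev_rc, suf, starting.at = 1L))
    hit <- logical(n)
    hit[idx] <- mism_f <= mm & mism_r <= mm
    locus[hit] <- panel$locus_id[i]
    n_hits <- n_hits + hit
  }
  ambiguous <- n_hits > 1L
  locus[ambiguous | n_hits == 0L] <- NA_character_
  reads$locus <- locus
  reads$ambiguous <- ambiguous
  reads
}

#' Tabulate amplicon sequence variants for one locus
#'
#' Groups assigned reads by exact full-amplicon sequence. Variants are
#' ordered by descending read count; ties by ascending length, then
#' lexicographic sequence.
#'
#' @param reads Read tibble of reads assigned to a single locus.
#' @param locus_id Locus identifier recorded in the result (defaults to
#'   the `locus` column if present).
#' @return A `strseq_tabulation` tibble with columns `locus`, `sequence`,
#'   `length`, `read_count`, and attribute `total_assigned`.
#' @export
tabulate_variants <- function(reads, locus_id = NULL) {
  locus_id <- locus_id %||% (if ("locus" %in% names(reads) && nrow(reads) > 0L)
    reads$locus[1L] else NA_character_)
  tab <- reads |>
    dplyr::count(.data$sequence, name = "read_count") |>
    dplyr::mutate(length = nchar(.data$sequence), locus = locus_id) |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$length, .data$sequence) |>
    dplyr::select("locus", "sequence", "length", "read_count")
  attr(tab, "total_assigned") <- nrow(reads)
  class(tab) <- c("strseq_tabulation", class(tibble::tibble()))
  tab
}

# Flank mismatch fraction of an observed full amplicon against the locus
# reference: positional comparison of the FF bases (just after the forward
# primer) and RF bases (just before the reverse primer). Variants shorter
# than primers + flanks get fraction 1 (cannot carry intact flanks).
flank_mismatch_frac <- function(sequence, locus) {
  ff_len <- locus$mra_start - locus$insert_start
  rf_len <- locus$insert_end - locus$mra_end
  ref <- locus$reference_amplicon
  ref_ff <- substr(ref, locus$insert_start + 1L, locus$mra_start)
  ref_rf <- substr(ref, locus$mra_end + 1L, locus$insert_end)
  n_rev <- nchar(ref) - locus$insert_end
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < locus$insert_start + n_rev + ff_len + rf_len) return(1)
    obs_ff <- substr(s, locus$insert_start + 1L, locus$insert_start + ff_len)
    obs_rf <- substr(s, n - n_rev - rf_len + 1L, n - n_rev)
    (hamming(obs_ff, ref_ff) + hamming(obs_rf, ref_rf)) / (ff_len + rf_len)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Call a genotype from a variant tabulation
#'
#' Applies the read-ratio rules to candidate variants (those within the
#' locus length bounds whose flank mismatch fraction is at most
#' `max_flank_mismatch_frac`), in descending read count:
#' \enumerate{
#'   \item The top candidate T must have at least `min_reads_allele`
#'     reads, else the locus is missing (`low_depth`).
#'   \item A second allele S must have at least `min_reads_allele` reads
#'     and at least `min_pct_vs_top` of T's reads.
#'   \item One repeat unit from T: heterozygous iff S/T >= `ratio_1unit`.
#'   \item Two repeat units from T: heterozygous iff S/T >= `ratio_2unit`.
#'   \item More than two units from T: heterozygous.
#'   \item Same length, different sequence: heterozygous iff
#'     T/S <= `max_same_length_variant_ratio`.
#' }
#' Candidates failing rules 3-4 are labelled stutter and their reads are
#' not pooled into the parent allele. Length differences that are not a
#' whole number of repeat units (1 bp shift alleles) fall in the nearest
#' band at or above their distance, so a 1 bp neighbour of a dinucleotide
#' allele must clear the one-unit ratio.
#'
#' @param tab A `strseq_tabulation` (from [tabulate_variants()]).
#' @param locus One row of a validated `strseq_panel`.
#' @param thresholds A [calling_thresholds()] object.
#' @return One-row tibble: `locus`, `allele1_len`, `allele2_len`,
#'   `allele1_seq`, `allele2_seq`, `reads1`, `reads2`, `zygosity`
#'   (`"hom"`, `"het"` or `"missing"`), `flags` (semicolon-joined).
#'   Alleles are ordered by ascending length (ties by sequence).
#' @export
call_genotype <- function(tab, locus, thresholds = calling_thresholds()) {
  miss <- function(flags) tibble::tibble(
    locus = locus$locus_id,
    allele1_len = NA_integer_, allele2_len = NA_integer_,
    allele1_seq = NA_character_, allele2_seq = NA_character_,
    reads1 = NA_integer_, reads2 = NA_integer_,
    zygosity = "missing", flags = paste(flags, collapse = ";")
  )
  if (nrow(tab) == 0L) return(miss("no_reads"))
  len_ok <- tab$length >= locus$min_len & tab$length <= locus$max_len
  cand <- tab[len_ok, , drop = FALSE]
  if (nrow(cand) > 0L) {
    fmf <- flank_mismatch_frac(cand$sequence, locus)
    cand <- cand[fmf <= thresholds$max_flank_mismatch_frac, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(miss("no_candidates"))
  flags <- character(0)
  top <- cand[1L, ]
  if (top$read_count < thresholds$min_reads_allele) {
    return(miss("low_depth"))
  }
  unit <- nchar(locus$motif)
  second <- NULL
  if (nrow(cand) > 1L) {
    for (i in seq(2L, nrow(cand))) {
      s <- cand[i, ]
      if (s$read_count < thresholds$min_reads_allele ||
          s$read_count < thresholds$min_pct_vs_top * top$read_count) next
      d <- abs(s$length - top$length)
      ratio <- s$read_count / top$read_count
      if (d == 0L) {
        if (top$read_count / s$read_count <=
            thresholds$max_same_length_variant_ratio) {
          second <- s; flags <- c(flags, "het_same_length"); break
        }
        flags <- c(flags, "seq_variant_dropped")
      } else if (d <= unit) {
        if (ratio >= thresholds$ratio_1unit) {
          second <- s; flags <- c(flags, "het_1unit"); break
        }
        flags <- c(flags, "stutter_1unit")
      } else if (d <= 2L * unit) {
        if (ratio >= thresholds$ratio_2unit) {
          second <- s; flags <- c(flags, "het_2unit"); break
        }
        flags <- c(flags, "stutter_2unit")
      } else {
        second <- s; flags <- c(flags, "het_far"); break
      }
    }
  }
  if (is.null(second)) {
    a <- top; b <- top
    zyg <- "hom"
  } else {
    ord <- order(c(top$length, second$length),
                 c(top$sequence, second$sequence))
    pair <- dplyr::bind_rows(top, second)[ord, ]
    a <- pair[1L, ]; b <- pair[2L, ]
    zyg <- "het"
  }
  tibble::tibble(
    locus = locus$locus_id,
    allele1_len = as.integer(a$length), allele2_len = as.integer(b$length),
    allele1_seq = a$sequence, allele2_seq = b$sequence,
    reads1 = as.integer(a$read_count), reads2 = as.integer(b$read_count),
    zygosity = zyg, flags = paste(flags, collapse = ";")
  )
}

#' Call genetic sex from X and Y marker read counts
#'
#' Inconclusive below `sex_min_total_reads` total reads; male iff the Y
#' variant has at least `sex_min_variant_reads` reads and the unrounded
#' Y/X ratio is at least `sex_yx_ratio` (Y reads with zero X reads count
#' as male); female iff the ratio falls below `sex_yx_ratio`; otherwise
#' inconclusive. All comparisons use the unrounded ratio: rounding the
#' ratio before comparison is exactly the discrepancy that produced
#' conflicting female/inconclusive calls between scorings in practice.
#'
#' @param x_reads,y_reads Reads assigned to the X and Y amplicons.
#' @param thresholds A [calling_thresholds()] object.
#' @return One-row tibble: `x_reads`, `y_reads`, `yx_ratio` (unrounded;
#'   `Inf` when `x_reads` is 0 and `y_reads` > 0), `call` (`"female"`,
#'   `"male"` or `"inconclusive"`).
#' @export
call_sex <- function(x_reads, y_reads, thresholds = calling_thresholds()) {
  ratio <- if (x_reads > 0L) y_reads / x_reads else if (y_reads > 0L) Inf else NA_real_
  call <- if (x_reads + y_reads < thresholds$sex_min_total_reads) {
    "inconclusive"
  } else if (y_reads >= thresholds$sex_min_variant_reads &&
             (x_reads == 0L || ratio >= thresholds$sex_yx_ratio)) {
    "male"
  } else if (is.na(ratio) || ratio < thresholds$sex_yx_ratio) {
    "female"
  } else {
    # ratio suggests a Y allele but its read support is too thin
    "inconclusive"
  }
  tibble::tibble(x_reads = as.integer(x_reads), y_reads = as.integer(y_reads),
                 yx_ratio = ratio, call = call)
}

#' Genotype one sample from FASTQ (or an in-memory read table)
#'
#' Runs the full per-sample pipeline: quality/length filtering, locus
#' assignment, per-locus variant tabulation, ratio-rule genotype calls at
#' every STR locus, and a sex call from the sexX/sexY amplicon counts (if
#' the panel defines them). Deterministic given input and configuration.
#'
#' @param x Path to a FASTQ file, or a read tibble (`id`, `sequence`,
#'   `qual`). For paired files pass `c(r1, r2)`; pairs are merged by exact
#'   overlap (see [merge_pairs()]) unless `r1_only = TRUE`.
#' @param panel A validated `strseq_panel`.
#' @param thresholds A [calling_thresholds()] object.
#' @param sample_id Sample identifier recorded in the outputs.
#' @param r1_only Ignore the second FASTQ of a pair.
#' @return A list of class `strseq_sample_report`: `genotypes` (one row
#'   per STR locus), `sex` (one-row tibble or `NULL`), `depth` (reads
#'   assigned per locus), `n_reads`, `n_filtered`, `n_assigned`,
#'   `sample_id`.
#' @export
call_sample <- function(x, panel, thresholds = calling_thresholds(),
                        sample_id = "sample", r1_only = FALSE) {
  reads <- if (is.character(x)) {
    if (length(x) == 2L && !r1_only) {
      merge_pairs(read_fastq(x[1L]), read_fastq(x[2L]))
    } else {
      read_fastq(x[1L])
    }
  } else {
    tibble::as_tibble(x)
  }
  n_reads <- nrow(reads)
  reads <- filter_reads(reads, thresholds)
  n_filtered <- nrow(reads)
  reads <- assign_locus(reads, panel, thresholds)
  assigned <- reads[!is.na(reads$locus), , drop = FALSE]

  depth <- panel |>
    dplyr::select(locus = "locus_id") |>
    dplyr::left_join(dplyr::count(assigned, locus = .data$locus, name = "n_reads"),
                     by = "locus") |>
    dplyr::mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L),
                  sample_id = sample_id) |>
    dplyr::select("sample_id", "locus", "n_reads")

  strp <- str_loci(panel)
  genotypes <- purrr::map(seq_len(nrow(strp)), function(i) {
    locus <- strp[i, ]
    tab <- tabulate_variants(
      assigned[assigned$locus == locus$locus_id, , drop = FALSE],
      locus_id = locus$locus_id)
    call_genotype(tab, locus, thresholds)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(sample_id = sample_id) |>
    dplyr::select("sample_id", dplyr::everything())

  sex <- NULL
  if (any(panel$role == "sexX")) {
    xid <- panel$locus_id[panel$role == "sexX"]
    yid <- panel$locus_id[panel$role == "sexY"]
    xr <- sum(assigned$locus == xid)
    yr <- if (length(yid) == 1L) sum(assigned$locus == yid) else 0L
    sex <- call_sex(xr, yr, thresholds) |>
      dplyr::mutate(sample_id = sample_id) |>
      dplyr::select("sample_id", dplyr::everything())
  }

  structure(
    list(genotypes = genotypes, sex = sex, depth = depth,
         n_reads = n_reads, n_filtered = n_filtered,
         n_assigned = nrow(assigned), sample_id = sample_id),
    class = "strseq_sample_report"
  )
}

#' @export
print.strseq_sample_report <- function(x, ...) {
  cat(sprintf("<strseq_sample_report> %s: %d reads, %d passed QC, %d assigned (%.1f%%)\n",
              x$sample_id, x$n_reads, x$n_filtered, x$n_assigned,
              if (x$n_filtered > 0) 100 * x$n_assigned / x$n_filtered else 0))
  called <- sum(x$genotypes$zygosity != "missing")
  cat(sprintf("  %d/%d loci called", called, nrow(x$genotypes)))
  if (!is.null(x$sex)) cat(sprintf("; sex: %s", x$sex$call))
  cat("\n")
  invisible(x)
}
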