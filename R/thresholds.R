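#' Genotype- and sex-calling thresholds
#'
#' Bundles every tunable used by the read caller. Defaults follow the
#' published parameterisation of sequence-based STR scoring for canid
#' panels: up to 2 primer mismatches, a 10-read minimum per allele, the
#' 0.7 / 0.2 read-ratio rules for candidate alleles one / two repeat units
#' below the top allele, a 10% floor against the top allele, a 1.5 cap on
#' the ratio of two same-length sequence variants, Q20 / 80 bp read
#' filters, and the sex-marker settings. `sex_yx_ratio` defaults to 0.1,
#' the value recommended after known females were mis-called male at Y/X
#' ratios up to 0.0993 under the original 0.02 setting; pass 0.02 to
#' reproduce the original runs.
#'
#' @param primer_max_mismatch Max substitutions tolerated in each primer.
#' @param min_reads_allele Minimum reads supporting a called allele.
#' @param max_flank_mismatch_frac Max fraction of mismatching flank bases
#'   for a variant to remain a candidate allele.
#' @param ratio_1unit Minimum second/top read ratio for a candidate one
#'   repeat unit from the top allele to be called (below it the variant is
#'   treated as stutter).
#' @param ratio_2unit Same, at two repeat units.
#' @param min_pct_vs_top Minimum reads of any called allele as a fraction
#'   of the top allele's reads.
#' @param max_same_length_variant_ratio Maximum top/second read ratio for
#'   two same-length sequence variants to be called heterozygous.
#' @param min_qual Minimum mean Phred quality of a read.
#' @param min_read_len Minimum read length in bp.
#' @param sex_min_total_reads Minimum X+Y reads for any sex call.
#' @param sex_min_variant_reads Minimum reads for the Y variant in a male
#'   call.
#' @param sex_yx_ratio Y/X read ratio at or above which (with enough Y
#'   reads) a sample is called male.
#' @return A named list of class `strseq_thresholds`.
#' @export
#' @examples
#' calling_thresholds()$ratio_1unit
#' calling_thresholds(sex_yx_ratio = 0.02)  # original run value
calling_thresholds <- function(primer_max_mismatch = 2L,
                               min_reads_allele = 10L,
                               max_flank_mismatch_frac = 0.5,
                               ratio_1unit = 0.7,
                               ratio_2unit = 0.2,
                               min_pct_vs_top = 0.10,
                               max_same_length_variant_ratio = 1.5,
                               min_qual = 20,
                               min_read_len = 80L,
                               sex_min_total_reads = 20L,
                               sex_min_variant_reads = 10L,
                               sex_yx_ratio = 0.1) {
  th <- list(
    primer_max_mismatch = as.integer(primer_max_mismatch),
    min_reads_allele = as.integer(min_reads_allele),
    max_flank_mismatch_frac = max_flank_mismatch_frac,
    ratio_1unit = ratio_1unit,
    ratio_2unit = ratio_2unit,
    min_pct_vs_top = min_pct_vs_top,
    max_same_length_variant_ratio = max_same_length_variant_ratio,
    min_qual = min_qual,
    min_read_len = as.integer(min_read_len),
    sex_min_total_reads = as.integer(sex_min_total_reads),
    sex_min_variant_reads = as.integer(sex_min_variant_reads),
    sex_yx_ratio = sex_yx_ratio
  )
  fracs <- c("max_flank_mismatch_frac", "ratio_1unit", "ratio_2unit",
             "min_pct_vs_top", "sex_yx_ratio")
  for (f in fracs) {
    if (th[[f]] <= 0 || th[[f]] > 1) {
      rlang::abort(sprintf("`%s` must be in (0, 1], got %s", f, th[[f]]))
    }
  }
  if (th$min_reads_allele < 1L) {
    rlang::abort("`min_reads_allele` must be >= 1")
  }
  structure(th, class = c("strseq_thresholds", "list"))
}

#' @export
print.strseq_thresholds <- function(x, ...) {
  cat("<strseq_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
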