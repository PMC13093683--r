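# Paired-scoring error rates: two analysts independently score the same
# sequencing run; allele-level discordance per locus defines the error
# rate. Rates are per allele: divisor 2 x n paired samples per locus, and
# 2 x n x L overall, which makes the overall rate the locus-weighted mean
# of per-locus rates by construction.

#' Compute per-locus and overall scoring error rates
#'
#' A mismatch is one allele differing between the two scorings of a
#' sample at a locus (0, 1 or 2 per sample per locus; allele pairs are
#' matched as multisets). By default, sample/locus combinations missing in
#' either scoring contribute nothing ("exclude" mode, mirroring the
#' exclusion of samples whose only discordances were missing data);
#' `missing = "count"` scores each such locus as 2 mismatches.
#'
#' @param score_a,score_b Multilocus tibbles (see [as_multilocus()]) of
#'   the two independent scorings; same samples and loci.
#' @param missing `"exclude"` (default) or `"count"`.
#' @return A list of class `strseq_error_report`: `per_locus` (tibble
#'   `locus`, `n_mismatch`, `rate`, `rate_rounded`), `overall` (tibble
#'   `n_mismatch`, `rate`, `rate_rounded`, `n_samples`, `n_loci`),
#'   `n_samples`, `missing`. Rounded rates use 3 decimals, half away from
#'   zero; unrounded rates drive all comparisons.
#' @export
compute_error_rates <- function(score_a, score_b,
                                missing = c("exclude", "count")) {
  missing <- match.arg(missing)
  j <- dplyr::inner_join(score_a, score_b, by = c("sample_id", "locus"),
                         suffix = c("_a", "_b"),
                         relationship = "one-to-one")
  if (nrow(j) == 0L) {
    rlang::abort("no overlapping sample/locus combinations between scorings")
  }
  has_a <- !is.na(j$a1_a)
  has_b <- !is.na(j$a1_b)
  mm <- integer(nrow(j))
  both <- has_a & has_b
  mm[both] <- 2L - pair_matches(j$a1_a[both], j$a2_a[both],
                                j$a1_b[both], j$a2_b[both])
  if (missing == "count") {
    mm[xor(has_a, has_b)] <- 2L
  }
  n_samples <- dplyr::n_distinct(j$sample_id)
  per_locus <- tibble::tibble(locus = j$locus, mm = mm) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n_mismatch = sum(.data$mm), .groups = "drop") |>
    dplyr::mutate(rate = .data$n_mismatch / (2L * n_samples),
                  rate_rounded = round_half_up(.data$rate, 3))
  overall <- tibble::tibble(
    n_mismatch = sum(per_locus$n_mismatch),
    rate = sum(per_locus$n_mismatch) / (2L * n_samples * nrow(per_locus)),
    n_samples = n_samples,
    n_loci = nrow(per_locus)) |>
    dplyr::mutate(rate_rounded = round_half_up(.data$rate, 3))
  structure(
    list(per_locus = per_locus, overall = overall,
         n_samples = n_samples, missing = missing),
    class = "strseq_error_report")
}

#' Drop high-error loci and recompute the overall rate
#'
#' Removes loci whose per-locus rate strictly exceeds `rate_threshold`
#' and recomputes the overall rate over the survivors. When `from` is
#' another error report (e.g. the high-template tissue dataset), the loci
#' to drop are identified there instead - the convention used when the
#' loci flagged in tissue data are also removed from the scat dataset.
#'
#' @param report A `strseq_error_report`.
#' @param rate_threshold Rate above which a locus is removed.
#' @param from Optional `strseq_error_report` in which the offending loci
#'   are identified (defaults to `report` itself).
#' @return A filtered `strseq_error_report` with attribute
#'   `removed_loci`.
#' @export
filter_loci_by_error <- function(report, rate_threshold, from = NULL) {
  src <- from %||% report
  drop <- src$per_locus$locus[src$per_locus$rate > rate_threshold]
  keep <- report$per_locus[!report$per_locus$locus %in% drop, , drop = FALSE]
  if (nrow(keep) == 0L) {
    rlang::abort("all loci removed by the error-rate filter")
  }
  overall <- tibble::tibble(
    n_mismatch = sum(keep$n_mismatch),
    rate = sum(keep$n_mismatch) / (2L * report$n_samples * nrow(keep)),
    n_samples = report$n_samples,
    n_loci = nrow(keep)) |>
    dplyr::mutate(rate_rounded = round_half_up(.data$rate, 3))
  out <- structure(
    list(per_locus = keep, overall = overall,
         n_samples = report$n_samples, missing = report$missing),
    class = "strseq_error_report")
  attr(out, "removed_loci") <- drop
  out
}

#' @export
print.strseq_error_report <- function(x, ...) {
  cat(sprintf(
    "<strseq_error_report> %d samples x %d loci: %d mismatches, rate %.3f\n",
    x$n_samples, x$overall$n_loci, x$overall$n_mismatch,
    x$overall$rate_rounded))
  invisible(x)
}

#' @method tidy strseq_error_report
#' @describeIn compute_error_rates Per-locus rates as a tibble.
#' @param x A `strseq_error_report`.
#' @param ... Unused.
#' @export
tidy.strseq_error_report <- function(x, ...) {
  x$per_locus
}

#' @method glance strseq_error_report
#' @describeIn compute_error_rates One-row overall summary.
#' @export
glance.strseq_error_report <- function(x, ...) {
  x$overall
}

#' Concordance of paired sex calls
#'
#' @param calls_a,calls_b Tibbles with `sample_id` and `call`
#'   (`"female"`, `"male"`, `"inconclusive"`), same samples.
#' @param reference Optional tibble `sample_id`, `sex` of known sexes.
#' @return A list of class `strseq_sex_concordance`: `per_sample` (calls
#'   side by side, `agree` logical, and `reference` /
#'   `discordant_with_reference` when supplied), `summary` (counts of
#'   agree / disagree / inconclusive-involved pairs).
#' @export
sex_concordance <- function(calls_a, calls_b, reference = NULL) {
  j <- dplyr::inner_join(
    dplyr::select(calls_a, "sample_id", call_a = "call"),
    dplyr::select(calls_b, "sample_id", call_b = "call"),
    by = "sample_id")
  j$agree <- j$call_a == j$call_b
  j$inconclusive <- j$call_a == "inconclusive" | j$call_b == "inconclusive"
  if (!is.null(reference)) {
    j <- dplyr::left_join(
      j, dplyr::select(reference, "sample_id", reference = "sex"),
      by = "sample_id")
    j$discordant_with_reference <- !is.na(j$reference) &
      ((j$call_a != "inconclusive" & j$call_a != j$reference) |
         (j$call_b != "inconclusive" & j$call_b != j$reference))
  }
  summary <- tibble::tibble(
    n = nrow(j),
    n_agree = sum(j$agree),
    n_disagree = sum(!j$agree),
    n_inconclusive_pair = sum(j$inconclusive),
    n_discordant_with_reference = if (is.null(reference)) NA_integer_
      else sum(j$discordant_with_reference))
  structure(list(per_sample = j, summary = summary),
            class = "strseq_sex_concordance")
}

#' @export
print.strseq_sex_concordance <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<strseq_sex_concordance> %d pairs: %d agree, %d disagree\n",
              s$n, s$n_agree, s$n_disagree))
  invisible(x)
}
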