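# Constructed multilocus datasets with known discordance structure, used
# to validate the error-rate machinery against published per-locus
# mismatch counts.

#' Build paired scorings with prescribed per-locus mismatch counts
#'
#' Constructs two multilocus scorings of `n_samples` individuals that are
#' identical except for exactly `n_mismatch[l]` allele-level discordances
#' at each locus, spread over samples (at most two per sample per locus).
#' Feeding the result to [compute_error_rates()] reproduces the per-locus
#' rates `n_mismatch / (2 * n_samples)` exactly, which is how published
#' multilocus scoring-error tables are reconstructed and checked.
#'
#' @param counts Tibble with columns `locus` and `n_mismatch`
#'   (0 to `2 * n_samples` each).
#' @param n_samples Number of paired-scored individuals.
#' @return List with multilocus tibbles `score_a` and `score_b` (see
#'   [as_multilocus()] for the layout).
#' @export
#' @examples
#' fx <- paired_scoring_fixture(
#'   tibble::tibble(locus = c("L1", "L2"), n_mismatch = c(3, 0)),
#'   n_samples = 10)
#' glance(compute_error_rates(fx$score_a, fx$score_b))
paired_scoring_fixture <- function(counts, n_samples) {
  if (any(counts$n_mismatch < 0L | counts$n_mismatch > 2L * n_samples)) {
    rlang::abort("n_mismatch must lie in [0, 2 * n_samples] for every locus")
  }
  ids <- sprintf("S%03d", seq_len(n_samples))
  base <- tidyr::expand_grid(sample_id = ids, locus = counts$locus) |>
    dplyr::mutate(a1 = "100", a2 = "102")
  score_b <- base
  for (l in seq_len(nrow(counts))) {
    k <- counts$n_mismatch[l]
    if (k == 0L) next
    for (j in seq_len(k)) {
      sample_idx <- (j - 1L) %% n_samples + 1L
      slot <- if (j <= n_samples) "a1" else "a2"
      row <- score_b$sample_id == ids[sample_idx] &
        score_b$locus == counts$locus[l]
      score_b[[slot]][row] <- as.character(900L + j)
    }
  }
  list(score_a = base, score_b = score_b)
}
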