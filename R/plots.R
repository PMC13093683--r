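# ggplot2 views of the main result objects.

#' @method autoplot strseq_error_report
#' @describeIn compute_error_rates Bar chart of per-locus error rates
#'   with the overall rate as a dashed reference line.
#' @param object A result object.
#' @export
autoplot.strseq_error_report <- function(object, ...) {
  d <- object$per_locus
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$locus, -.data$rate),
                                  y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$overall$rate, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Scoring error rate (per allele)",
                  title = sprintf("Paired-scoring errors (n = %d samples)",
                                  object$n_samples)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @method autoplot strseq_unique_profile
#' @describeIn unique_profile Cluster count against mismatch allowance;
#'   the recommended allowance (first plateau) is marked.
#' @param object A `strseq_unique_profile`.
#' @param ... Unused.
#' @export
autoplot.strseq_unique_profile <- function(object, ...) {
  rec <- attr(object, "recommended")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$allowance,
                                            y = .data$n_unique)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Allele mismatch allowance", y = "Unique individuals",
                  title = "Unique-profile sweep") +
    ggplot2::theme_minimal()
  if (!is.na(rec)) {
    p <- p + ggplot2::geom_vline(xintercept = rec, linetype = "dotted")
  }
  p
}

#' @method autoplot strseq_diversity
#' @describeIn diversity Per-locus Na and Ho side by side.
#' @param object A `strseq_diversity`.
#' @export
autoplot.strseq_diversity <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("na", "ho"),
                           names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          na = "Na (alleles)",
                                          ho = "Ho (obs. heterozygosity)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-locus diversity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a variant tabulation as a read-ratio ladder
#'
#' Read counts by amplicon length for one locus, the visual stutter
#' ladder a scorer inspects when reviewing a call.
#'
#' @param tab A `strseq_tabulation` from [tabulate_variants()].
#' @return A ggplot object.
#' @export
plot_tabulation <- function(tab) {
  d <- tab |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(read_count = sum(.data$read_count), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$read_count)) +
    ggplot2::geom_col(width = 0.8, fill = "grey35") +
    ggplot2::labs(x = "Amplicon length (bp)", y = "Reads",
                  title = tab$locus[1] %||% "variant tabulation") +
    ggplot2::theme_minimal()
}
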