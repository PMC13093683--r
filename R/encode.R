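# The homoplasy-aware allele code: AAAMMFFRR, where AAA is the allele
# length in bp (2 or 3 digits, so codes are 8 or 9 characters), MM the
# repeat-array mutation code, FF the forward-flank code and RR the
# reverse-flank code; "00" means the region matches the reference.

#' Encode a decomposed allele into its AAAMMFFRR code
#'
#' Mutation-free regions encode as `"00"`; mutated regions are registered
#' in (or looked up from) `registry`, which hands out 2-digit codes in
#' first-encounter order. A length-96 allele with no mutations encodes as
#' `"96000000"`; a length-109 allele carrying the locus's second repeat-
#' array mutation and third reverse-flank mutation encodes as
#' `"109020003"`.
#'
#' @param decomp A `strseq_decomposition` (from [decompose_allele()]), or
#'   a list with canonical mutation texts `mra_mut`, `ff_mut`, `rf_mut`
#'   and a `locus` id.
#' @param allele_len Allele length in bp (10-999).
#' @param registry A [mutation_registry()]; mutated regions are added to
#'   it as a side effect.
#' @return One-row tibble of class `strseq_coded_allele`: `locus`,
#'   `allele_len`, `mm`, `ff`, `rr`, `code_text`.
#' @export
encode_allele <- function(decomp, allele_len, registry) {
  allele_len <- as.integer(allele_len)
  if (is.na(allele_len) || allele_len < 10L || allele_len > 999L) {
    rlang::abort(sprintf(
      "allele_len must be 10-999 bp for the 2-3 digit length field, got %s",
      allele_len))
  }
  code_for <- function(region, mut) {
    if (!nzchar(mut)) "00" else
      register_mutation(registry, decomp$locus, region, mut)
  }
  mm <- code_for("MRA", decomp$mra_mut)
  ff <- code_for("FF", decomp$ff_mut)
  rr <- code_for("RF", decomp$rf_mut)
  out <- tibble::tibble(
    locus = decomp$locus, allele_len = allele_len,
    mm = mm, ff = ff, rr = rr,
    code_text = paste0(allele_len, mm, ff, rr))
  class(out) <- c("strseq_coded_allele", class(tibble::tibble()))
  out
}

#' Decode an AAAMMFFRR allele code
#'
#' @param code_text 8- or 9-digit code string(s).
#' @return Tibble with `allele_len` (integer), `mm`, `ff`, `rr`.
#' @export
#' @examples
#' decode_allele("109020003")  # length 109, MRA code 02, RF code 03
decode_allele <- function(code_text) {
  bad <- !grepl("^[0-9]{8,9}$", code_text)
  if (any(bad)) {
    rlang::abort(sprintf("not an 8/9-digit allele code: %s",
                         paste(code_text[bad], collapse = ", ")))
  }
  n <- nchar(code_text)
  tibble::tibble(
    allele_len = as.integer(substr(code_text, 1L, n - 6L)),
    mm = substr(code_text, n - 5L, n - 4L),
    ff = substr(code_text, n - 3L, n - 2L),
    rr = substr(code_text, n - 1L, n)
  )
}

#' Encode every allele in a genotype table
#'
#' Decomposes and codes each called allele sequence against the panel
#' references. Samples are processed in `sample_id` order and alleles in
#' ascending length so code assignment order is deterministic for a given
#' dataset.
#'
#' @param genotypes Genotype tibble from the caller (columns `sample_id`,
#'   `locus`, `allele1_len`, `allele2_len`, `allele1_seq`, `allele2_seq`,
#'   `zygosity`, ...).
#' @param panel A validated `strseq_panel`.
#' @param registry A [mutation_registry()] (default: a fresh one), grown
#'   as a side effect.
#' @param min_observations Mutations seen in fewer distinct samples than
#'   this are reverted to code `"00"` in the output (guard against
#'   sequencing error masquerading as mutation); default 1 keeps all.
#' @return `genotypes` with added columns `allele1_mut`, `allele2_mut`
#'   (code strings, `NA` where missing), plus attribute `registry`.
#' @export
encode_genotypes <- function(genotypes, panel, registry = mutation_registry(),
                             min_observations = 1L) {
  gl <- genotypes |>
    dplyr::arrange(.data$sample_id, .data$locus)
  long <- dplyr::bind_rows(
    gl |> dplyr::transmute(.data$sample_id, .data$locus, which = 1L,
                           len = .data$allele1_len, seq = .data$allele1_seq),
    gl |> dplyr::transmute(.data$sample_id, .data$locus, which = 2L,
                           len = .data$allele2_len, seq = .data$allele2_seq)
  ) |>
    dplyr::arrange(.data$sample_id, .data$locus, .data$len, .data$seq, .data$which)
  strp <- str_loci(panel)
  code <- rep(NA_character_, nrow(long))
  obs_count <- new.env(parent = emptyenv())  # mutation -> set of samples
  for (i in seq_len(nrow(long))) {
    if (is.na(long$seq[i])) next
    locus <- strp[strp$locus_id == long$locus[i], ]
    if (nrow(locus) != 1L) next
    dec <- decompose_allele(amplicon_insert(long$seq[i], locus), locus)
    coded <- encode_allele(dec, long$len[i], registry)
    code[i] <- coded$code_text
    for (reg_mut in list(c("MRA", dec$mra_mut), c("FF", dec$ff_mut),
                         c("RF", dec$rf_mut))) {
      if (nzchar(reg_mut[2L])) {
        key <- paste(long$locus[i], reg_mut[1L], reg_mut[2L], sep = "\r")
        obs_count[[key]] <- union(obs_count[[key]], long$sample_id[i])
      }
    }
  }
  long$code <- code
  if (min_observations > 1L) {
    long$code <- revert_rare_mutations(long, strp, registry, obs_count,
                                       min_observations)
  }
  wide <- long |>
    dplyr::select("sample_id", "locus", "which", "code") |>
    tidyr::pivot_wider(names_from = "which", values_from = "code",
                       names_prefix = "allele_mut")
  out <- gl |>
    dplyr::left_join(wide, by = c("sample_id", "locus")) |>
    dplyr::rename(allele1_mut = "allele_mut1", allele2_mut = "allele_mut2")
  attr(out, "registry") <- registry
  out
}

# Re-derive codes with rarely observed mutations (fewer than
# min_observations distinct samples) treated as no-mutation.
revert_rare_mutations <- function(long, strp, registry, obs_count, min_obs) {
  rare <- function(locus, region, mut) {
    if (!nzchar(mut)) return(FALSE)
    key <- paste(locus, region, mut, sep = "\r")
    length(obs_count[[key]]) < min_obs
  }
  vapply(seq_len(nrow(long)), function(i) {
    if (is.na(long$seq[i])) return(NA_character_)
    locus <- strp[strp$locus_id == long$locus[i], ]
    dec <- decompose_allele(amplicon_insert(long$seq[i], locus), locus)
    if (rare(long$locus[i], "MRA", dec$mra_mut)) dec$mra_mut <- ""
    if (rare(long$locus[i], "FF", dec$ff_mut)) dec$ff_mut <- ""
    if (rare(long$locus[i], "RF", dec$rf_mut)) dec$rf_mut <- ""
    encode_allele(dec, long$len[i], registry)$code_text
  }, character(1))
}

#' Summarise size homoplasy per locus
#'
#' A fragment-size class is a distinct allele length at a locus; it shows
#' homoplasy when at least two distinct allele codes share that length,
#' and is "mutated only" when no code at that length is mutation-free
#' (MM = FF = RR = "00").
#'
#' @param coded Tibble with columns `locus` and `code_text` (one row per
#'   distinct allele, or redundant rows - deduplicated internally).
#' @return Tibble of class `strseq_homoplasy`: `locus`, `n_size_classes`,
#'   `n_with_homoplasy`, `proportion` (2 dp), `n_mutated_only`.
#' @export
summarize_homoplasy <- function(coded) {
  d <- dplyr::distinct(coded, .data$locus, .data$code_text)
  out <- dplyr::bind_cols(d, decode_allele(d$code_text)) |>
    dplyr::mutate(clean = .data$mm == "00" & .data$ff == "00" & .data$rr == "00") |>
    dplyr::group_by(.data$locus, .data$allele_len) |>
    dplyr::summarise(n_variants = dplyr::n(), any_clean = any(.data$clean),
                     .groups = "drop") |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_size_classes = dplyr::n(),
      n_with_homoplasy = sum(.data$n_variants >= 2L),
      proportion = round_half_up(.data$n_with_homoplasy / .data$n_size_classes, 2),
      n_mutated_only = sum(!.data$any_clean),
      .groups = "drop")
  class(out) <- c("strseq_homoplasy", class(tibble::tibble()))
  out
}
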