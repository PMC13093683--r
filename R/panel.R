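#' Locate the microsatellite repeat array in a reference sequence
#'
#' Finds the longest maximal run of exact, consecutive copies of `motif`
#' in `reference`; ties are broken by the leftmost start. The run must
#' span at least three copies, the minimum for a reference to count as an
#' STR amplicon here.
#'
#' @param reference DNA string to scan.
#' @param motif Repeat unit (2 or 4 bp).
#' @return Integer vector `c(start, end)`, a 0-based half-open interval.
#' @export
#' @examples
#' locate_repeat_array("AAGTGTGTGTGTCC", "GT")   # c(2, 12)
#' locate_repeat_array("AGAGAGTTTAGAGAGAG", "AG") # c(9, 17): longer run wins
locate_repeat_array <- function(reference, motif) {
  m <- nchar(motif)
  if (!m %in% c(2L, 4L)) {
    rlang::abort(sprintf("motif must be 2 or 4 bp, got %d (\"%s\")", m, motif))
  }
  n <- nchar(reference)
  if (n < 3L * m) {
    rlang::abort("reference shorter than three motif copies")
  }
  # copies[s+1] = number of consecutive exact motif copies starting at
  # 0-based offset s; filled right to left so each cell is O(1)
  copies <- integer(n)
  for (s in seq(n - m, 0L)) {
    hit <- substr(reference, s + 1L, s + m) == motif
    copies[s + 1L] <- if (!hit) 0L else {
      nxt <- if (s + m <= n - m) copies[s + m + 1L] else 0L
      1L + nxt
    }
  }
  best <- max(copies)
  if (best < 3L) {
    rlang::abort(sprintf(
      "no run of >= 3 consecutive \"%s\" copies: not an STR reference", motif))
  }
  start <- which(copies == best)[1L] - 1L
  c(start, start + best * m)
}

# Compute region intervals (0-based half-open, on the full amplicon) for
# one locus row. The insert is the inter-primer sequence; FF runs from the
# forward primer's 3' end to the repeat-array start, RF from the array end
# to the reverse primer.
locus_regions <- function(reference_amplicon, fwd_primer, rev_primer, motif) {
  nf <- nchar(fwd_primer)
  nr <- nchar(rev_primer)
  n <- nchar(reference_amplicon)
  if (substr(reference_amplicon, 1L, nf) != fwd_primer) {
    rlang::abort("forward primer is not a prefix of the reference amplicon")
  }
  if (substr(reference_amplicon, n - nr + 1L, n) != revcomp(rev_primer)) {
    rlang::abort(
      "reverse-complemented reverse primer is not a suffix of the reference amplicon")
  }
  insert <- substr(reference_amplicon, nf + 1L, n - nr)
  mra <- locate_repeat_array(insert, motif) + nf
  list(insert_start = nf, insert_end = n - nr,
       mra_start = mra[1L], mra_end = mra[2L])
}

#' Load and validate a marker panel
#'
#' Reads a panel definition (one marker per row) and validates it: unique
#' locus ids, primers anchoring the reference amplicon, and a repeat array
#' of at least three motif copies in every STR reference. Rows with
#' `role` `"sexX"` / `"sexY"` describe the X and Y amplicons of the sex
#' marker and are exempt from the repeat-array requirement.
#'
#' TSV columns (JSON uses the same keys): `locus_id`, `fwd_primer`,
#' `rev_primer`, `motif`, `reference_amplicon`, `min_len`, `max_len`, and
#' optionally `role` (`"str"`, `"sexX"` or `"sexY"`).
#'
#' @param path Path to a TSV or JSON panel file.
#' @param format `"tsv"` (default) or `"json"`.
#' @return A `strseq_panel` tibble with the input columns plus computed
#'   0-based half-open region coordinates `insert_start`, `insert_end`,
#'   `mra_start`, `mra_end` on the full amplicon.
#' @export
load_panel <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("panel file not found: %s", path))
  }
  raw <- if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  validate_panel(raw)
}

#' Validate a panel table
#'
#' @param panel Data frame with the panel columns (see [load_panel()]).
#' @return A validated `strseq_panel` tibble with region coordinates.
#' @export
validate_panel <- function(panel) {
  required <- c("locus_id", "fwd_primer", "rev_primer", "motif",
                "reference_amplicon", "min_len", "max_len")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("panel is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  panel <- tibble::as_tibble(panel)
  if (!"role" %in% names(panel)) panel$role <- "str"
  panel$role[is.na(panel$role)] <- "str"
  dup <- panel$locus_id[duplicated(panel$locus_id)]
  if (length(dup) > 0L) {
    rlang::abort(sprintf("duplicate locus_id: %s",
                         paste(unique(dup), collapse = ", ")))
  }
  bad_role <- setdiff(unique(panel$role), c("str", "sexX", "sexY"))
  if (length(bad_role) > 0L) {
    rlang::abort(sprintf("unknown role value(s): %s",
                         paste(bad_role, collapse = ", ")))
  }
  if (sum(panel$role == "sexX") > 1L || sum(panel$role == "sexY") > 1L) {
    rlang::abort("at most one sexX and one sexY row allowed")
  }
  seqcols <- c("fwd_primer", "rev_primer", "motif", "reference_amplicon")
  for (col in seqcols) {
    if (!all(is_dna(panel[[col]]))) {
      rlang::abort(sprintf("non-DNA characters in column %s", col))
    }
  }
  str_rows <- panel$role == "str"
  if (any(str_rows & !nchar(panel$motif) %in% c(2L, 4L))) {
    rlang::abort("STR motifs must be 2 or 4 bp")
  }
  regions <- purrr::pmap(
    list(panel$reference_amplicon, panel$fwd_primer, panel$rev_primer,
         panel$motif, panel$role, panel$locus_id),
    function(ref, fwd, rev, motif, role, id) {
      if (role != "str") {
        nf <- nchar(fwd)
        n <- nchar(ref)
        if (substr(ref, 1L, nf) != fwd) {
          rlang::abort(sprintf("%s: forward primer does not anchor reference", id))
        }
        return(list(insert_start = nf, insert_end = n - nchar(rev),
                    mra_start = NA_integer_, mra_end = NA_integer_))
      }
      tryCatch(
        locus_regions(ref, fwd, rev, motif),
        error = function(e) {
          rlang::abort(sprintf("%s: %s", id, conditionMessage(e)))
        }
      )
    }
  )
  panel$insert_start <- purrr::map_int(regions, ~ as.integer(.x$insert_start))
  panel$insert_end <- purrr::map_int(regions, ~ as.integer(.x$insert_end))
  panel$mra_start <- purrr::map_int(regions, ~ as.integer(.x$mra_start %||% NA))
  panel$mra_end <- purrr::map_int(regions, ~ as.integer(.x$mra_end %||% NA))
  tet <- str_rows & nchar(panel$motif) == 4L
  if (any(tet)) {
    rlang::warn(sprintf(
      "tetranucleotide motif at: %s (supported, but stutter display tools built for dinucleotides may score these poorly)",
      paste(panel$locus_id[tet], collapse = ", ")))
  }
  class(panel) <- c("strseq_panel", class(tibble::tibble()))
  panel
}

#' Extract the STR loci (non-sex rows) of a panel
#' @param panel A `strseq_panel`.
#' @return The subset of rows with `role == "str"`.
#' @export
str_loci <- function(panel) {
  panel[panel$role == "str", , drop = FALSE]
}

#' Write a panel table to TSV
#' @param panel A `strseq_panel` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("locus_id", "fwd_primer", "rev_primer", "motif",
            "reference_amplicon", "min_len", "max_len", "role")
  readr::write_tsv(panel[, intersect(cols, names(panel))], path)
  invisible(path)
}
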