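# The per-locus, per-region mutation catalogue. Codes "01".."99" are
# handed out in first-encounter order and never reassigned; "00" is the
# reserved no-mutation code and is never stored. The registry is a small
# mutable object (environment-backed) because append-only, order-preserving
# assignment across a whole dataset is inherently stateful.

#' Create an empty mutation registry
#'
#' @return An object of class `strseq_registry`.
#' @export
mutation_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- tibble::tibble(
    locus_id = character(0), region = character(0),
    mutation = character(0), code = character(0), first_seen = integer(0))
  structure(e, class = "strseq_registry")
}

#' Register a mutation and return its 2-digit code
#'
#' Returns the existing code if the (locus, region, mutation) triple has
#' been seen, else assigns the next zero-padded code for that locus and
#' region in first-encounter order. A (locus, region) pair can hold at
#' most 99 distinct mutations; the 100th raises a capacity error because
#' the 2-digit code format cannot express it.
#'
#' @param registry A [mutation_registry()].
#' @param locus_id Locus identifier.
#' @param region `"MRA"`, `"FF"` or `"RF"`.
#' @param mutation Canonical mutation text (nonempty; reference-identical
#'   regions are never registered).
#' @return The 2-digit code as a string.
#' @export
register_mutation <- function(registry, locus_id, region, mutation) {
  stopifnot(inherits(registry, "strseq_registry"))
  region <- match.arg(region, c("MRA", "FF", "RF"))
  if (!nzchar(mutation)) {
    rlang::abort("empty mutation text: reference-identical regions are not registered (code \"00\")")
  }
  tbl <- registry$entries
  hit <- tbl$locus_id == locus_id & tbl$region == region & tbl$mutation == mutation
  if (any(hit)) return(tbl$code[hit][1L])
  n_here <- sum(tbl$locus_id == locus_id & tbl$region == region)
  if (n_here >= 99L) {
    rlang::abort(sprintf(
      "capacity: %s/%s already holds 99 mutations; the 2-digit code format cannot express a 100th",
      locus_id, region))
  }
  code <- sprintf("%02d", n_here + 1L)
  registry$entries <- dplyr::bind_rows(tbl, tibble::tibble(
    locus_id = locus_id, region = region, mutation = mutation,
    code = code, first_seen = nrow(tbl) + 1L))
  code
}

#' Look up a mutation code without registering
#'
#' @inheritParams register_mutation
#' @return The code, or `NA_character_` if unseen.
#' @export
mutation_code <- function(registry, locus_id, region, mutation) {
  tbl <- registry$entries
  hit <- tbl$locus_id == locus_id & tbl$region == region & tbl$mutation == mutation
  if (any(hit)) tbl$code[hit][1L] else NA_character_
}

#' Registry contents as a tibble
#' @param registry A [mutation_registry()].
#' @return Tibble with `locus_id`, `region`, `mutation`, `code`,
#'   `first_seen`.
#' @export
registry_table <- function(registry) {
  registry$entries
}

#' Persist / restore a registry as TSV
#'
#' The TSV form is the interchange format for sharing a mutation
#' catalogue across runs and labs; re-encoding a dataset against a
#' restored registry yields identical codes.
#'
#' @param registry A [mutation_registry()].
#' @param path TSV path.
#' @return `write_registry`: `path` invisibly; `read_registry`: a
#'   `strseq_registry`.
#' @export
write_registry <- function(registry, path) {
  readr::write_tsv(registry$entries, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tbl <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      locus_id = "c", region = "c", mutation = "c",
      code = "c", first_seen = "i"))
  reg <- mutation_registry()
  reg$entries <- tbl[order(tbl$first_seen), ]
  reg
}

#' @export
print.strseq_registry <- function(x, ...) {
  cat(sprintf("<strseq_registry> %d mutation(s) across %d locus/region pair(s)\n",
              nrow(x$entries),
              nrow(unique(x$entries[, c("locus_id", "region")]))))
  invisible(x)
}
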