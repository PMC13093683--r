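# Decomposition of an observed allele insert into forward-flank (FF),
# repeat-array (MRA) and reverse-flank (RF) regions, with positional edit
# calls against the locus reference. This is the substrate for the
# homoplasy-aware allele codes.

# End-anchored semi-global alignment: the whole of `ref` is aligned
# against a prefix of `obs`, anchored at the left edge, with unit costs
# (match 0, mismatch 1, gap 1). Returns the consumed observed prefix
# length and single-base edits in 0-based ref coordinates. Ties are broken
# deterministically: the minimal-cost endpoint closest to the reference
# flank length (then the shorter prefix), and diagonal > ref-gap >
# obs-gap during traceback (prefers substitutions over indels).
align_prefix <- function(ref, obs, max_shift = 8L) {
  f <- nchar(ref)
  w <- min(nchar(obs), f + max_shift)
  r <- strsplit(ref, "")[[1]]
  o <- strsplit(substr(obs, 1L, w), "")[[1]]
  D <- matrix(0L, f + 1L, w + 1L)
  D[, 1L] <- 0:f
  D[1L, ] <- 0:w
  for (i in seq_len(f)) {
    for (j in seq_len(w)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j] + (r[i] != o[j]),
        D[i, j + 1L] + 1L,   # gap in observed: ref base deleted
        D[i + 1L, j] + 1L    # gap in ref: observed base inserted
      )
    }
  }
  costs <- D[f + 1L, ]
  # among minimal-cost endpoints prefer the one closest to the reference
  # flank length (no net indel), then the shorter prefix
  cand_j <- which(costs == min(costs)) - 1L
  j_end <- cand_j[order(abs(cand_j - f), cand_j)][1L]
  # traceback from (f, j_end)
  i <- f; j <- j_end
  edits <- list()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (r[i] != o[j])) {
      if (r[i] != o[j]) {
        edits[[length(edits) + 1L]] <- list(
          pos = i - 1L, ref = r[i], alt = o[j], kind = "sub")
      }
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      edits[[length(edits) + 1L]] <- list(
        pos = i - 1L, ref = r[i], alt = "", kind = "del")
      i <- i - 1L
    } else {
      edits[[length(edits) + 1L]] <- list(
        pos = i, ref = "", alt = o[j], kind = "ins")  # between pos-1 and pos
      j <- j - 1L
    }
  }
  list(cost = min(costs), consumed = j_end, edits = rev(edits))
}

str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Mirror of align_prefix: `ref` aligned against a suffix of `obs`,
# anchored at the right edge. Edits are reported in forward ref
# coordinates.
align_suffix <- function(ref, obs, max_shift = 8L) {
  f <- nchar(ref)
  res <- align_prefix(str_rev(ref), str_rev(obs), max_shift)
  edits <- lapply(res$edits, function(e) {
    if (e$kind == "ins") {
      list(pos = f - e$pos, ref = "", alt = e$alt, kind = "ins")
    } else {
      list(pos = f - 1L - e$pos, ref = e$ref, alt = e$alt, kind = e$kind)
    }
  })
  list(cost = res$cost, consumed = res$consumed,
       edits = edits[order(vapply(edits, `[[`, integer(1), "pos"))])
}

edits_to_tbl <- function(edits) {
  if (length(edits) == 0L) {
    return(tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), kind = character(0)))
  }
  tibble::tibble(
    pos = vapply(edits, `[[`, integer(1), "pos"),
    ref = vapply(edits, `[[`, character(1), "ref"),
    alt = vapply(edits, `[[`, character(1), "alt"),
    kind = vapply(edits, `[[`, character(1), "kind")
  )
}

# Canonical textual form of a region's edit list, e.g. "4C>T",
# "2_3insA", "5delC", multiple edits joined by ";" in position order.
canonical_mutation <- function(edit_tbl) {
  if (nrow(edit_tbl) == 0L) return("")
  txt <- vapply(seq_len(nrow(edit_tbl)), function(i) {
    e <- edit_tbl[i, ]
    switch(e$kind,
      sub = sprintf("%d%s>%s", e$pos, e$ref, e$alt),
      ins = sprintf("%d_%dins%s", e$pos - 1L, e$pos, e$alt),
      del = sprintf("%ddel%s", e$pos, e$ref)
    )
  }, character(1))
  paste(txt, collapse = ";")
}

#' Canonical repeat-composition descriptor of an MRA sequence
#'
#' Spells the repeat array as maximal runs of the motif with interruptions
#' written out, e.g. `"(GT)12"`, `"(GT)5A(GT)6"`; a literal tail after the
#' final run is written as a trailing insertion, e.g. `"(GT)12+A"`.
#'
#' @param mra_seq Observed repeat-array sequence.
#' @param motif Repeat unit.
#' @return A descriptor string.
#' @export
mra_descriptor <- function(mra_seq, motif) {
  m <- nchar(motif)
  n <- nchar(mra_seq)
  parts <- character(0)
  i <- 1L
  lit <- ""
  while (i <= n) {
    k <- 0L
    while (i + (k + 1L) * m - 1L <= n &&
           substr(mra_seq, i + k * m, i + (k + 1L) * m - 1L) == motif) {
      k <- k + 1L
    }
    if (k > 0L) {
      if (nzchar(lit)) {
        parts <- c(parts, lit)
        lit <- ""
      }
      parts <- c(parts, sprintf("(%s)%d", motif, k))
      i <- i + k * m
    } else {
      lit <- paste0(lit, substr(mra_seq, i, i))
      i <- i + 1L
    }
  }
  if (nzchar(lit)) {
    # literal tail after the last run: a trailing insertion
    parts <- c(parts, paste0("+", lit))
  }
  paste(parts, collapse = "")
}

#' Decompose an observed allele insert into FF / MRA / RF regions
#'
#' Aligns the reference forward flank against the start of the observed
#' insert and the reference reverse flank against its end (end-anchored,
#' unit costs); the remainder between them is the observed repeat array.
#' Point edits are reported per flank in 0-based region coordinates, and
#' the repeat array is canonicalised with [mra_descriptor()].
#'
#' @param observed_insert Inter-primer sequence of a called allele.
#' @param locus One row of a validated `strseq_panel`.
#' @return A list of class `strseq_decomposition`: `locus`, `ff_seq`,
#'   `mra_seq`, `rf_seq`, `ff_muts`, `rf_muts` (edit tibbles: `pos`,
#'   `ref`, `alt`, `kind`), `mra_desc`, `mra_ref_desc`, and canonical
#'   mutation texts `ff_mut`, `rf_mut`, `mra_mut` (empty string when the
#'   region matches the reference).
#' @export
decompose_allele <- function(observed_insert, locus) {
  ref <- locus$reference_amplicon
  ref_ff <- substr(ref, locus$insert_start + 1L, locus$mra_start)
  ref_rf <- substr(ref, locus$mra_end + 1L, locus$insert_end)
  ref_mra <- substr(ref, locus$mra_start + 1L, locus$mra_end)
  al_ff <- align_prefix(ref_ff, observed_insert)
  al_rf <- align_suffix(ref_rf, observed_insert)
  if (al_ff$cost > 0.5 * nchar(ref_ff) || al_rf$cost > 0.5 * nchar(ref_rf)) {
    rlang::abort(sprintf(
      "%s: flank identity below 50%% (FF cost %d/%d, RF cost %d/%d); sequence likely from another locus",
      locus$locus_id, al_ff$cost, nchar(ref_ff), al_rf$cost, nchar(ref_rf)))
  }
  n <- nchar(observed_insert)
  ff_seq <- substr(observed_insert, 1L, al_ff$consumed)
  rf_seq <- substr(observed_insert, n - al_rf$consumed + 1L, n)
  if (al_ff$consumed + al_rf$consumed > n) {
    rlang::abort(sprintf("%s: flanks overlap; insert too short", locus$locus_id))
  }
  mra_seq <- substr(observed_insert, al_ff$consumed + 1L, n - al_rf$consumed)
  ff_muts <- edits_to_tbl(al_ff$edits)
  rf_muts <- edits_to_tbl(al_rf$edits)
  desc <- mra_descriptor(mra_seq, locus$motif)
  ref_desc <- mra_descriptor(ref_mra, locus$motif)
  # pure length change stays "no mutation": compare composition shapes
  mra_mut <- if (mra_shape(desc, locus$motif) == mra_shape(ref_desc, locus$motif))
    "" else desc
  structure(
    list(locus = locus$locus_id,
         ff_seq = ff_seq, mra_seq = mra_seq, rf_seq = rf_seq,
         ff_muts = ff_muts, rf_muts = rf_muts,
         mra_desc = desc, mra_ref_desc = ref_desc,
         ff_mut = canonical_mutation(ff_muts),
         rf_mut = canonical_mutation(rf_muts),
         mra_mut = mra_mut),
    class = "strseq_decomposition"
  )
}

# Shape of a descriptor with run lengths blanked: "(GT)12" and "(GT)9"
# share shape "(GT)n" (plain length variation, not a mutation), while
# "(GT)5A(GT)6" or "(GT)12+A" differ.
mra_shape <- function(desc, motif) {
  gsub(sprintf("\\(%s\\)\\d+", motif), sprintf("(%s)n", motif), desc)
}

#' @export
print.strseq_decomposition <- function(x, ...) {
  cat(sprintf("<strseq_decomposition> %s\n", x$locus))
  cat(sprintf("  FF  %s%s\n", x$ff_seq,
              if (nzchar(x$ff_mut)) paste0("  [", x$ff_mut, "]") else ""))
  cat(sprintf("  MRA %s  [%s]\n", x$mra_seq, x$mra_desc))
  cat(sprintf("  RF  %s%s\n", x$rf_seq,
              if (nzchar(x$rf_mut)) paste0("  [", x$rf_mut, "]") else ""))
  invisible(x)
}

# Strip primers from a full amplicon sequence for a locus.
amplicon_insert <- function(sequence, locus) {
  n_rev <- nchar(locus$reference_amplicon) - locus$insert_end
  substr(sequence, locus$insert_start + 1L, nchar(sequence) - n_rev)
}
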