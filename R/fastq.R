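# FASTQ I/O and paired-end merging. Reads travel through the package as a
# tibble with columns id, sequence, qual (Phred+33 string).

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return Tibble with columns `id`, `sequence`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTQ file not found: %s", path))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = names(x) %||% as.character(seq_along(x)),
    sequence = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `sequence`, `qual`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# Mean Phred score of a quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Merge read pairs by exact overlap
#'
#' Reverse-complements R2 and joins it to R1 at the longest exact suffix /
#' prefix overlap of at least `min_overlap` bp. Pairs without such an
#' overlap fall back to R1 alone. With 2 x 150 bp sequencing over inserts
#' of at most ~150 bp, most pairs overlap fully; exact matching suffices
#' because discordant pairs are rescued by the R1 fallback.
#'
#' @param r1,r2 Read tibbles of equal length (columns `id`, `sequence`,
#'   `qual`).
#' @param min_overlap Minimum exact overlap in bp (default 30).
#' @return A merged read tibble.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 30L) {
  if (nrow(r1) != nrow(r2)) {
    rlang::abort("r1 and r2 have different numbers of reads")
  }
  if (nrow(r1) == 0L) return(r1)
  out <- purrr::pmap(
    list(r1$sequence, r1$qual, r2$sequence, r2$qual),
    function(s1, q1, s2, q2) {
      s2rc <- revcomp(s2)
      q2rc <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
      n1 <- nchar(s1); n2 <- nchar(s2rc)
      for (ov in seq(min(n1, n2), min_overlap)) {
        if (substr(s1, n1 - ov + 1L, n1) == substr(s2rc, 1L, ov)) {
          return(list(sequence = paste0(s1, substr(s2rc, ov + 1L, n2)),
                      qual = paste0(q1, substr(q2rc, ov + 1L, n2))))
        }
      }
      list(sequence = s1, qual = q1)  # no overlap: keep R1
    }
  )
  tibble::tibble(
    id = r1$id,
    sequence = purrr::map_chr(out, "sequence"),
    qual = purrr::map_chr(out, "qual")
  )
}
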