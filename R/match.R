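# Multilocus genotype matching: similarity scores, single-linkage
# duplicate clustering, and the unique-profile sweep used to pick a
# mismatch allowance.
#
# A multilocus genotype is a long tibble with columns sample_id, locus,
# a1, a2 (character or integer allele values; both NA when the locus is
# missing). Homozygotes repeat the value.

#' Convert a caller genotype table to multilocus form
#'
#' @param genotypes Caller output (or coded output from
#'   [encode_genotypes()]).
#' @param allele `"len"` to use allele lengths, `"mut"` to use the
#'   homoplasy-aware codes.
#' @return Tibble with `sample_id`, `locus`, `a1`, `a2` (character).
#' @export
as_multilocus <- function(genotypes, allele = c("len", "mut")) {
  allele <- match.arg(allele)
  cols <- if (allele == "len") c("allele1_len", "allele2_len")
          else c("allele1_mut", "allele2_mut")
  tibble::tibble(
    sample_id = genotypes$sample_id,
    locus = genotypes$locus,
    a1 = as.character(genotypes[[cols[1L]]]),
    a2 = as.character(genotypes[[cols[2L]]])
  )
}

# Number of matching alleles between two unordered allele pairs
# (multiset intersection size: 0, 1 or 2).
pair_matches <- function(a1, a2, b1, b2) {
  direct <- (a1 == b1) + (a2 == b2)
  crossed <- (a1 == b2) + (a2 == b1)
  # multiset-correct for all cases with pairs of two
  pmin(pmax(direct, crossed), 2L)
}

# Per-locus comparison of two multilocus genotypes; loci missing in
# either genotype are excluded. Returns a tibble locus/matched (0-2).
compare_loci <- function(g1, g2) {
  j <- dplyr::inner_join(g1, g2, by = "locus", suffix = c("_1", "_2"),
                         relationship = "one-to-one")
  j <- j[!is.na(j$a1_1) & !is.na(j$a1_2), , drop = FALSE]
  tibble::tibble(
    locus = j$locus,
    matched = as.integer(pair_matches(j$a1_1, j$a2_1, j$a1_2, j$a2_2))
  )
}

#' Similarity score between two multilocus genotypes
#'
#' Matched alleles divided by total compared alleles over the loci where
#' both genotypes have data (allele pairs matched as multisets). Over a
#' 26-locus panel, 0/1/2/3 allele mismatches give 1.00 / 0.98 / 0.96 /
#' 0.94 when rounded to two decimals; the returned value is unrounded.
#'
#' @param g1,g2 Multilocus tibbles (see [as_multilocus()]) covering the
#'   same locus set.
#' @return Unrounded fraction in `[0, 1]`; `NA` (with a warning) when no
#'   locus is comparable.
#' @export
similarity_score <- function(g1, g2) {
  cmp <- compare_loci(g1, g2)
  if (nrow(cmp) == 0L) {
    rlang::warn("no comparable loci; similarity undefined")
    return(NA_real_)
  }
  sum(cmp$matched) / (2L * nrow(cmp))
}

# Allele mismatches between two samples (2 - matched per compared locus).
mismatch_count <- function(g1, g2) {
  cmp <- compare_loci(g1, g2)
  if (nrow(cmp) == 0L) return(NA_integer_)
  sum(2L - cmp$matched)
}

# Pairwise mismatch matrix over a list of multilocus genotypes (split by
# sample). Missing-data pairs with no comparable loci get NA.
mismatch_matrix <- function(genotypes) {
  ids <- unique(genotypes$sample_id)
  gl <- split(genotypes[, c("locus", "a1", "a2")], genotypes$sample_id)[ids]
  n <- length(ids)
  m <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  diag(m) <- 0L
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- mismatch_count(gl[[i]], gl[[j]])
    }
  }
  m
}

#' Cluster samples into putative duplicate individuals
#'
#' Single-linkage clusters in which every edge joins two samples whose
#' genotypes differ at no more than `max_mismatch` alleles (loci missing
#' in either sample are excluded from the count). Because linkage is
#' single, chains of pairwise-similar samples merge; the cluster count is
#' the estimated number of unique individuals.
#'
#' @param genotypes Multilocus tibble for all samples.
#' @param max_mismatch Allele mismatch allowance.
#' @return Tibble `sample_id`, `cluster` (integer; clusters numbered by
#'   first appearance), with attribute `n_unique`.
#' @export
find_duplicates <- function(genotypes, max_mismatch = 4L) {
  ids <- unique(genotypes$sample_id)
  if (length(ids) < 2L) {
    out <- tibble::tibble(sample_id = ids, cluster = seq_along(ids))
    attr(out, "n_unique") <- length(ids)
    return(out)
  }
  m <- mismatch_matrix(genotypes)
  adj <- !is.na(m) & m <= max_mismatch
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber clusters by order of first appearance
  cl <- as.integer(factor(comp, levels = unique(comp)))
  out <- tibble::tibble(sample_id = ids, cluster = cl)
  attr(out, "n_unique") <- max(cl)
  out
}

#' Sweep the mismatch allowance to profile unique-individual counts
#'
#' Runs [find_duplicates()] at every allowance from 0 to `max_sweep` and
#' reports the number of clusters plus a multiple-match diagnostic (how
#' many samples match two or more distinct exact-genotype classes at that
#' allowance). The recommended allowance is the smallest at which the
#' cluster count is stable over two consecutive steps.
#'
#' @param genotypes Multilocus tibble.
#' @param max_sweep Largest allowance to test.
#' @return Tibble of class `strseq_unique_profile`: `allowance`,
#'   `n_unique`, `n_multiple_match`; attribute `recommended`.
#' @export
unique_profile <- function(genotypes, max_sweep = 8L) {
  m <- mismatch_matrix(genotypes)
  ids <- rownames(m)
  exact_class <- integer(length(ids))
  if (length(ids) > 0L) {
    adj0 <- !is.na(m) & m == 0L
    g0 <- igraph::graph_from_adjacency_matrix(adj0, mode = "undirected")
    exact_class <- igraph::components(g0)$membership
  }
  rows <- purrr::map(0:max_sweep, function(a) {
    adj <- !is.na(m) & m <= a
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    n_unique <- igraph::components(g)$no
    n_multi <- sum(vapply(seq_along(ids), function(i) {
      nb <- which(adj[i, ])
      nb <- nb[nb != i]
      length(unique(exact_class[c(i, nb)])) >= 2L
    }, logical(1)))
    tibble::tibble(allowance = a, n_unique = n_unique,
                   n_multiple_match = n_multi)
  })
  out <- dplyr::bind_rows(rows)
  stable <- which(diff(out$n_unique) == 0L)
  attr(out, "recommended") <- if (length(stable) > 0L)
    out$allowance[stable[1L]] else NA_integer_
  class(out) <- c("strseq_unique_profile", class(tibble::tibble()))
  out
}
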