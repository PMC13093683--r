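# A complete 26-locus diploid genotype; values are allele lengths.
full_genotype <- function(id, overrides = list()) {
  g <- tibble::tibble(
    sample_id = id,
    locus = sprintf("L%02d", 1:26),
    a1 = as.character(seq(90, 140, 2))[1:26],
    a2 = as.character(seq(92, 142, 2))[1:26])
  for (l in names(overrides)) {
    g$a1[g$locus == l] <- as.character(overrides[[l]][1])
    g$a2[g$locus == l] <- as.character(overrides[[l]][2])
  }
  g
}

test_that("similarity_score reproduces the 26-locus mismatch ladder", {
  g <- full_genotype("A")
  expect_equal(similarity_score(g, full_genotype("B")), 1)
  one <- full_genotype("B", list(L01 = c(90, 999)))
  expect_equal(round(similarity_score(g, one), 2), 0.98)
  expect_equal(similarity_score(g, one), 51 / 52)
  two <- full_genotype("B", list(L01 = c(999, 998)))
  expect_equal(round(similarity_score(g, two), 2), 0.96)
  three <- full_genotype("B", list(L01 = c(999, 998), L02 = c(94, 997)))
  expect_equal(round(similarity_score(g, three), 2), 0.94)
})

test_that("similarity_score is symmetric, multiset-correct and missing-aware", {
  g <- full_genotype("A")
  h <- full_genotype("B", list(L05 = c(999, 998)))
  expect_equal(similarity_score(g, h), similarity_score(h, g))
  # swapped allele order at a locus is not a mismatch
  sw <- full_genotype("B")
  sw$a1[1] <- g$a2[1]; sw$a2[1] <- g$a1[1]
  expect_equal(similarity_score(g, sw), 1)
  # missing loci are excluded from the denominator
  miss <- full_genotype("B")
  miss$a1[1:6] <- NA; miss$a2[1:6] <- NA
  expect_equal(similarity_score(g, miss), 1)
  expect_warning(
    expect_true(is.na(similarity_score(
      g, dplyr::mutate(full_genotype("B"), a1 = NA_character_,
                       a2 = NA_character_)))),
    "no comparable loci")
})

test_that("find_duplicates clusters at the allowance boundary", {
  g1 <- full_genotype("S1")
  g2 <- full_genotype("S2")                      # exact duplicate of S1
  g3 <- full_genotype("S3", list(L01 = c(999, 998), L02 = c(997, 996)))
  all3 <- dplyr::bind_rows(g1, g2, g3)
  cl <- find_duplicates(all3, max_mismatch = 0)
  expect_equal(attr(cl, "n_unique"), 2)
  expect_equal(cl$cluster[cl$sample_id == "S1"], cl$cluster[cl$sample_id == "S2"])

  # pair differing at exactly 4 alleles: merged at 4, separate at 3
  g4 <- full_genotype("S4", list(L01 = c(999, 998), L02 = c(997, 996)))
  g5 <- full_genotype("S5")
  pair <- dplyr::bind_rows(g4, g5)
  expect_equal(attr(find_duplicates(pair, 4), "n_unique"), 1)
  expect_equal(attr(find_duplicates(pair, 3), "n_unique"), 2)
})

test_that("allowance 0 reproduces exact-genotype classes from hash grouping", {
  set.seed(77)
  pool <- purrr::map(1:6, function(i) {
    full_genotype(sprintf("T%d", i),
                  setNames(list(c(900 + i, 900 + i)), "L10"))
  })
  # duplicate some genotypes under new ids
  dup <- purrr::map(1:4, function(i) {
    dplyr::mutate(pool[[sample(6, 1)]], sample_id = sprintf("D%d", i))
  })
  all_g <- dplyr::bind_rows(pool, dup)
  cl <- find_duplicates(all_g, 0)
  # oracle: group by the concatenated genotype string
  key <- all_g |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(k = paste(locus, a1, a2, collapse = "|"), .groups = "drop")
  expect_equal(attr(cl, "n_unique"), dplyr::n_distinct(key$k))
  joined <- dplyr::left_join(cl, key, by = "sample_id")
  expect_equal(
    dplyr::n_distinct(paste(joined$cluster, joined$k)),
    dplyr::n_distinct(joined$k))
})

test_that("unique_profile plateaus at the true individual count and recommends the first stable allowance", {
  g <- dplyr::bind_rows(
    full_genotype("A1"), dplyr::mutate(full_genotype("A2")),  # dup pair
    full_genotype("B1", list(L01 = c(999, 999))),
    full_genotype("C1", list(L02 = c(500, 502), L03 = c(504, 506))))
  prof <- unique_profile(g, max_sweep = 5)
  expect_equal(prof$allowance, 0:5)
  # with one scoring error (1 mismatch) separating B1 from A1/A2:
  expect_equal(prof$n_unique[1], 3)  # 0 allowance: A pair merged already
  expect_true(all(diff(prof$n_unique) <= 0))
  expect_equal(attr(unique_profile(full_genotype("solo"), 3), "recommended"), 0)
  expect_equal(unique_profile(full_genotype("solo"), 3)$n_unique, rep(1, 4))
})

test_that("error rates reproduce the published 26-locus paired-scoring table", {
  counts <- published_error_counts()
  fx_ti <- paired_scoring_fixture(
    dplyr::transmute(counts, locus, n_mismatch = tissue_errors), 84)
  rep_ti <- compute_error_rates(fx_ti$score_a, fx_ti$score_b)
  # every printed per-locus tissue rate (3 dp)
  expect_equal(
    rep_ti$per_locus$rate_rounded[match(counts$locus, rep_ti$per_locus$locus)],
    round(counts$tissue_errors / 168, 3) * 1)
  expect_equal(rep_ti$overall$n_mismatch, 91)
  expect_equal(rep_ti$overall$rate_rounded, 0.021)

  fx_sc <- paired_scoring_fixture(
    dplyr::transmute(counts, locus, n_mismatch = scat_errors), 18)
  rep_sc <- compute_error_rates(fx_sc$score_a, fx_sc$score_b)
  expect_equal(
    rep_sc$per_locus$rate_rounded[rep_sc$per_locus$locus == "Cfam_STR009"],
    0.194)
  expect_equal(rep_sc$overall$rate_rounded, 0.022)

  # identical scorings -> all zero
  rep0 <- compute_error_rates(fx_ti$score_a, fx_ti$score_a)
  expect_true(all(rep0$per_locus$rate == 0))
})

test_that("locus filtering removes high-error loci and recomputes totals", {
  counts <- published_error_counts()
  fx_ti <- paired_scoring_fixture(
    dplyr::transmute(counts, locus, n_mismatch = tissue_errors), 84)
  rep_ti <- compute_error_rates(fx_ti$score_a, fx_ti$score_b)

  f08 <- filter_loci_by_error(rep_ti, 0.08)
  expect_equal(f08$overall$n_loci, 23)
  expect_equal(f08$overall$n_mismatch, 46)
  expect_equal(f08$overall$rate_rounded, 0.012)
  expect_setequal(attr(f08, "removed_loci"),
                  c("Cfam_STR009", "Cfam_STR019", "Cfam_STR033"))

  f05 <- filter_loci_by_error(rep_ti, 0.05)
  expect_equal(f05$overall$n_loci, 21)
  expect_equal(f05$overall$n_mismatch, 27)
  expect_equal(f05$overall$rate_rounded, 0.008)

  # scat totals filtered by the loci flagged in the tissue data
  fx_sc <- paired_scoring_fixture(
    dplyr::transmute(counts, locus, n_mismatch = scat_errors), 18)
  rep_sc <- compute_error_rates(fx_sc$score_a, fx_sc$score_b)
  expect_equal(
    filter_loci_by_error(rep_sc, 0.08, from = rep_ti)$overall$rate_rounded,
    0.014)
  expect_equal(
    filter_loci_by_error(rep_sc, 0.05, from = rep_ti)$overall$rate_rounded,
    0.008)

  # threshold 1.0 changes nothing
  expect_equal(filter_loci_by_error(rep_ti, 1)$overall, rep_ti$overall)
  expect_error(filter_loci_by_error(rep_ti, -1), "all loci removed")
})

test_that("overall rate equals the locus-weighted mean of per-locus rates", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    counts <- tibble::tibble(
      locus = sprintf("L%02d", 1:sample(3:12, 1)))
    counts$n_mismatch <- sample(0:(2 * n), nrow(counts), replace = TRUE)
    fx <- paired_scoring_fixture(counts, n)
    rep <- compute_error_rates(fx$score_a, fx$score_b)
    expect_equal(rep$overall$rate, mean(rep$per_locus$rate))
    expect_equal(rep$per_locus$rate,
                 rep$per_locus$n_mismatch / (2 * n))
  }
})

test_that("missing loci are excluded by default but countable on request", {
  g <- full_genotype("S1")
  h <- full_genotype("S1")
  h$a1[h$locus == "L03"] <- NA
  h$a2[h$locus == "L03"] <- NA
  rep_ex <- compute_error_rates(g, h)
  expect_equal(rep_ex$overall$n_mismatch, 0)
  rep_ct <- compute_error_rates(g, h, missing = "count")
  expect_equal(rep_ct$overall$n_mismatch, 2)
})

test_that("sex_concordance counts agreement and reference discordance", {
  a <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                      call = c("female", "male", "female"))
  b <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                      call = c("female", "male", "inconclusive"))
  out <- sex_concordance(a, b)
  expect_equal(out$summary$n_agree, 2)
  expect_equal(out$summary$n_disagree, 1)
  expect_equal(out$summary$n_inconclusive_pair, 1)

  # a known female called male in both scorings is flagged against the
  # reference even though the two scorings agree
  ref <- tibble::tibble(sample_id = "S2", sex = "female")
  out2 <- sex_concordance(a, b, reference = ref)
  expect_equal(out2$summary$n_discordant_with_reference, 1)
  expect_true(out2$per_sample$discordant_with_reference[
    out2$per_sample$sample_id == "S2"])
})
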