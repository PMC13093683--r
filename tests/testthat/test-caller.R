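panel <- toy_locus()
locus <- panel[1, ]
th <- calling_thresholds()

test_that("filter_reads applies inclusive Q20 and 80 bp boundaries", {
  q20 <- rawToChar(as.raw(20 + 33))
  q19 <- rawToChar(as.raw(19 + 33))
  reads <- tibble::tibble(
    id = c("len79", "len80", "q19.9", "q20"),
    sequence = c(strrep("A", 79), strrep("A", 80), strrep("A", 100),
                 strrep("A", 100)),
    qual = c(strrep(q20, 79), strrep(q20, 80),
             paste0(strrep(q19, 90), strrep(q20, 10)),  # mean 19.1
             strrep(q20, 100)))
  kept <- filter_reads(reads, th)
  expect_setequal(kept$id, c("len80", "q20"))
  # empty input passes through
  expect_equal(nrow(filter_reads(reads[0, ], th)), 0)
})

test_that("assign_locus honours the 2-mismatch primer rule", {
  amp <- toy_amplicon(panel)
  mism3 <- amp
  substr(mism3, 1, 3) <- "TTT"   # 3 mismatches in the forward primer
  mism2 <- amp
  substr(mism2, 1, 2) <- "TT"    # 2 mismatches: still accepted
  reads <- tibble::tibble(
    id = c("exact", "mm3", "mm2", "offtarget"),
    sequence = c(amp, mism3, mism2, random_dna_str(nchar(amp))),
    qual = strrep("?", nchar(amp)))
  out <- assign_locus(reads, panel, th)
  expect_equal(out$locus, c("TOY_STR001", NA, "TOY_STR001", NA))
  expect_false(any(out$ambiguous))
})

test_that("tabulate_variants orders by count, then length, then sequence", {
  a100 <- toy_amplicon(panel, n_repeats = 9)   # shorter
  a102 <- toy_amplicon(panel, n_repeats = 10)
  reads <- dplyr::bind_rows(reads_of(a102, 50), reads_of(a100, 50),
                            reads_of(toy_amplicon(panel, n_repeats = 11), 60))
  tab <- tabulate_variants(reads, "TOY_STR001")
  expect_equal(tab$read_count, c(60, 50, 50))
  # 50/50 tie: shorter amplicon first
  expect_equal(tab$length[2:3], sort(nchar(c(a100, a102))))
  expect_equal(attr(tab, "total_assigned"), 160)
  # 100 identical reads -> a single variant
  tab1 <- tabulate_variants(reads_of(a100, 100), "TOY_STR001")
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$read_count, 100)
})

test_that("call_genotype applies the ratio rules at their published boundaries", {
  ref_len <- nchar(locus$reference_amplicon)
  call_for <- function(counts, lengths, ...) {
    call_genotype(toy_tabulation(panel, lengths, counts, ...), locus, th)
  }
  # one unit apart: 70/100 = 0.70 >= 0.7 -> het
  het1 <- call_for(c(100, 70), c(ref_len, ref_len - 2))
  expect_equal(het1$zygosity, "het")
  expect_equal(sort(c(het1$allele1_len, het1$allele2_len)),
               c(ref_len - 2, ref_len))
  # one unit apart: 60/100 = 0.6 < 0.7 -> stutter, hom for top
  hom1 <- call_for(c(100, 60), c(ref_len, ref_len - 2))
  expect_equal(hom1$zygosity, "hom")
  expect_equal(hom1$allele1_len, ref_len)
  expect_match(hom1$flags, "stutter_1unit")
  # two units apart: 25/100 = 0.25 >= 0.2 -> het
  expect_equal(call_for(c(100, 25), c(ref_len, ref_len - 4))$zygosity, "het")
  # two units apart: 15/100 < 0.2 -> hom
  expect_equal(call_for(c(100, 15), c(ref_len, ref_len - 4))$zygosity, "hom")
  # far apart but above the 10% floor -> het
  expect_equal(call_for(c(100, 12), c(ref_len, ref_len - 8))$zygosity, "het")
  # below the 10% floor -> never a second allele
  expect_equal(call_for(c(100, 9), c(ref_len, ref_len - 8))$zygosity, "hom")
  # top variant under the 10-read minimum -> missing
  low <- call_for(c(8), ref_len)
  expect_equal(low$zygosity, "missing")
  expect_match(low$flags, "low_depth")
  # same length, two sequence variants, ratio 100/70 = 1.43 <= 1.5 -> het
  same <- call_genotype(
    toy_tabulation(panel, c(ref_len, ref_len), c(100, 70),
                   same_length_variant = TRUE), locus, th)
  expect_equal(same$zygosity, "het")
  expect_equal(same$allele1_len, same$allele2_len)
  # same length, ratio 100/60 = 1.67 > 1.5 -> variant dropped
  same2 <- call_genotype(
    toy_tabulation(panel, c(ref_len, ref_len), c(100, 60),
                   same_length_variant = TRUE), locus, th)
  expect_equal(same2$zygosity, "hom")
})

test_that("variants outside length bounds or with bad flanks are not candidates", {
  ref_len <- nchar(locus$reference_amplicon)
  # only variant is 20 bp beyond max_len -> missing
  tab <- toy_tabulation(panel, ref_len + 20, 100)
  expect_equal(call_genotype(tab, locus, th)$zygosity, "missing")
  # flank trashed beyond the 50% mismatch fraction -> not a candidate
  bad_ff <- toy_amplicon(panel, ff = "GCGGAG", rf = "ATTAGC")  # 6/6+5/6 mismatches
  tab2 <- tibble::tibble(locus = locus$locus_id, sequence = bad_ff,
                         length = nchar(bad_ff), read_count = 100L)
  expect_equal(call_genotype(tab2, locus, th)$zygosity, "missing")
})

test_that("raising min_reads_allele never rescues a missing call", {
  ref_len <- nchar(locus$reference_amplicon)
  set.seed(12)
  n_missing_lo <- 0L
  for (i in 1:50) {
    counts <- sample(1:8, 3)
    tab <- toy_tabulation(panel, ref_len - c(0, 2, 4), sort(counts, TRUE))
    zyg_lo <- call_genotype(tab, locus, calling_thresholds(min_reads_allele = 5))
    zyg_hi <- call_genotype(tab, locus, calling_thresholds(min_reads_allele = 25))
    if (zyg_lo$zygosity == "missing") {
      n_missing_lo <- n_missing_lo + 1L
      expect_equal(zyg_hi$zygosity, "missing")
    }
  }
  # the sweep must actually have exercised the missing branch
  expect_gt(n_missing_lo, 0)
})

test_that("call_sex uses unrounded ratios and both depth gates", {
  expect_equal(call_sex(1000, 0, th)$call, "female")
  # ratio 0.05: male under the original 0.02 setting, female at 0.1
  expect_equal(call_sex(1000, 50, calling_thresholds(sex_yx_ratio = 0.02))$call,
               "male")
  expect_equal(call_sex(1000, 50, calling_thresholds(sex_yx_ratio = 0.1))$call,
               "female")
  # below the 20-read total -> inconclusive regardless of ratio
  expect_equal(call_sex(10, 5, th)$call, "inconclusive")
  # regression for the rounding discrepancy: 0.0178 rounds to 0.02 but
  # must still compare as < 0.02
  s <- call_sex(10000, 178, calling_thresholds(sex_yx_ratio = 0.02))
  expect_equal(s$call, "female")
  expect_equal(s$yx_ratio, 0.0178)
  # no X reads but solid Y support -> male
  expect_equal(call_sex(0, 30, th)$call, "male")
  expect_equal(call_sex(0, 0, th)$call, "inconclusive")
})

test_that("call_sample is deterministic and handles empty/off-target input", {
  empty <- tibble::tibble(id = character(0), sequence = character(0),
                          qual = character(0))
  rep0 <- call_sample(empty, panel, th, sample_id = "E")
  expect_true(all(rep0$genotypes$zygosity == "missing"))

  set.seed(5)
  offtarget <- tibble::tibble(
    id = sprintf("r%d", 1:200),
    sequence = replicate(200, random_dna_str(100)),
    qual = strrep("?", 100))
  rep1 <- call_sample(offtarget, panel, th, sample_id = "P")
  expect_equal(rep1$n_assigned, 0)
  expect_true(all(rep1$genotypes$zygosity == "missing"))

  th_short <- calling_thresholds(min_read_len = 40L)  # toy amplicon is 52 bp
  reads <- reads_of(toy_amplicon(panel), 50)
  r1 <- call_sample(reads, panel, th_short, sample_id = "A")
  r2 <- call_sample(reads, panel, th_short, sample_id = "A")
  expect_identical(r1$genotypes, r2$genotypes)
  expect_equal(r1$genotypes$zygosity, "hom")
})
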