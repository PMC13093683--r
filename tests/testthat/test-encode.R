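test_that("registry assigns codes in first-encounter order and is idempotent", {
  reg <- mutation_registry()
  expect_equal(register_mutation(reg, "L1", "FF", "4C>T"), "01")
  expect_equal(register_mutation(reg, "L1", "FF", "2A>G"), "02")
  # same mutation again: same code
  expect_equal(register_mutation(reg, "L1", "FF", "4C>T"), "01")
  # independent numbering per region and per locus
  expect_equal(register_mutation(reg, "L1", "RF", "4C>T"), "01")
  expect_equal(register_mutation(reg, "L2", "FF", "4C>T"), "01")
  expect_equal(nrow(registry_table(reg)), 4)
  expect_error(register_mutation(reg, "L1", "FF", ""), "empty mutation")
})

test_that("the 2-digit format caps a region at 99 mutations", {
  reg <- mutation_registry()
  for (i in 1:99) register_mutation(reg, "L1", "MRA", sprintf("mut%02d", i))
  expect_equal(mutation_code(reg, "L1", "MRA", "mut99"), "99")
  expect_error(register_mutation(reg, "L1", "MRA", "one_too_many"), "capacity")
})

test_that("encode_allele reproduces the documented worked examples", {
  reg <- mutation_registry()
  clean <- list(locus = "Cfam_STR001", mra_mut = "", ff_mut = "", rf_mut = "")
  expect_equal(encode_allele(clean, 96, reg)$code_text, "96000000")

  # locus with two documented MRA mutations and three RF mutations;
  # the allele carries MRA #2 and RF #3 with a clean forward flank
  reg2 <- mutation_registry()
  register_mutation(reg2, "Cfam_STR007", "MRA", "(GT)4A(GT)8")
  register_mutation(reg2, "Cfam_STR007", "MRA", "(GT)6A(GT)7")
  register_mutation(reg2, "Cfam_STR007", "RF", "2C>T")
  register_mutation(reg2, "Cfam_STR007", "RF", "5G>A")
  register_mutation(reg2, "Cfam_STR007", "RF", "7T>C")
  allele <- list(locus = "Cfam_STR007", mra_mut = "(GT)6A(GT)7",
                 ff_mut = "", rf_mut = "7T>C")
  out <- encode_allele(allele, 109, reg2)
  expect_equal(out$code_text, "109020003")
  expect_equal(out$mm, "02")
  expect_equal(out$ff, "00")
  expect_equal(out$rr, "03")

  # 3-digit length with only a forward-flank mutation
  reg3 <- mutation_registry()
  ff_only <- list(locus = "L", mra_mut = "", ff_mut = "0A>C", rf_mut = "")
  expect_equal(encode_allele(ff_only, 100, reg3)$code_text, "100000100")

  expect_error(encode_allele(clean, 1000, reg), "10-999")
  expect_error(encode_allele(clean, 9, reg), "10-999")
})

test_that("decode_allele inverts the code format", {
  expect_equal(decode_allele("109020003"),
               tibble::tibble(allele_len = 109L, mm = "02", ff = "00",
                              rr = "03"))
  expect_equal(decode_allele("96000000")$allele_len, 96L)
  expect_equal(decode_allele("96000000")$mm, "00")
  expect_error(decode_allele("12345"), "8/9-digit")
  expect_error(decode_allele("12345678x"), "8/9-digit")
})

test_that("decode is the exact inverse of encode on random valid codes", {
  set.seed(123)
  lens <- sample(10:999, 2000, replace = TRUE)
  mm <- sprintf("%02d", sample(0:99, 2000, replace = TRUE))
  ff <- sprintf("%02d", sample(0:99, 2000, replace = TRUE))
  rr <- sprintf("%02d", sample(0:99, 2000, replace = TRUE))
  code <- paste0(lens, mm, ff, rr)
  dec <- decode_allele(code)
  expect_equal(dec$allele_len, lens)
  expect_equal(dec$mm, mm)
  expect_equal(dec$ff, ff)
  expect_equal(dec$rr, rr)
  expect_equal(paste0(dec$allele_len, dec$mm, dec$ff, dec$rr), code)
})

test_that("summarize_homoplasy counts size classes, homoplasy and mutated-only classes", {
  # 7 size classes, 5 with >= 2 code variants, 1 length existing only in
  # mutated form
  codes <- c(
    "90000000", "90010000",             # homoplasy
    "92000000", "92000100",             # homoplasy
    "94000000", "94000001",             # homoplasy
    "96000000", "96020000",             # homoplasy
    "98000000", "98010000", "98000200", # homoplasy (3 variants)
    "100000000",                        # clean singleton
    "102010000")                        # mutated-only singleton
  out <- summarize_homoplasy(tibble::tibble(locus = "Cfam_STR012",
                                            code_text = codes))
  expect_equal(out$n_size_classes, 7)
  expect_equal(out$n_with_homoplasy, 5)
  expect_equal(out$proportion, 0.71)
  expect_equal(out$n_mutated_only, 1)

  # all mutation-free -> no homoplasy
  clean <- sprintf("%d000000", seq(90, 98, 2))
  out2 <- summarize_homoplasy(tibble::tibble(locus = "L", code_text = clean))
  expect_equal(out2$n_with_homoplasy, 0)
  expect_equal(out2$proportion, 0)
  expect_equal(out2$n_mutated_only, 0)

  # one length, two sequence variants
  out3 <- summarize_homoplasy(
    tibble::tibble(locus = "L", code_text = c("96000000", "96010000")))
  expect_equal(out3$n_size_classes, 1)
  expect_equal(out3$proportion, 1)
  expect_equal(out3$n_mutated_only, 0)
})

test_that("encode_genotypes codes called alleles and persists registry order", {
  panel <- toy_locus()
  locus <- panel[1, ]
  amp_clean <- toy_amplicon(panel)
  amp_mut <- toy_amplicon(panel, rf = "GGCCAT")  # RF 4T>A, same length
  genotypes <- tibble::tibble(
    sample_id = c("S1", "S2"),
    locus = locus$locus_id,
    allele1_len = nchar(amp_clean), allele2_len = nchar(amp_mut),
    allele1_seq = amp_clean, allele2_seq = amp_mut,
    zygosity = "het", flags = "")
  reg <- mutation_registry()
  coded <- encode_genotypes(genotypes, panel, reg)
  expect_equal(coded$allele1_mut, rep(paste0(nchar(amp_clean), "000000"), 2))
  expect_equal(coded$allele2_mut, rep(paste0(nchar(amp_mut), "000001"), 2))
  expect_equal(registry_table(reg)$mutation, "4T>A")

  # re-encoding against a persisted registry yields identical codes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  coded2 <- encode_genotypes(genotypes, panel, reg2)
  expect_identical(coded2$allele2_mut, coded$allele2_mut)
})
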