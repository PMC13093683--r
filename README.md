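# strseq

Sequence-based microsatellite (STR) genotyping for multiplexed amplicon
panels, built for non-invasive genetic monitoring of canids (wolves,
coyotes, dogs) but applicable to any di-/tetranucleotide panel with
defined primers and reference amplicons.

Traditional fragment-size genotyping by capillary electrophoresis suffers
from binning ambiguity, allelic dropout in low-template (scat) DNA, and
undetected **size homoplasy** — distinct allele sequences that share a
fragment length. Genotyping by sequencing fixes all three, but only if the
calling rules, the mutation bookkeeping, and the error accounting are
explicit and reproducible. That is what this package provides:

- **Read calling** (`call_sample()` and friends): quality/length
  filtering (mean Q ≥ 20, ≥ 80 bp), primer-based locus assignment
  (≤ 2 mismatches per primer), variant tabulation by exact amplicon
  sequence, and genotype calls from read-ratio rules — a candidate allele
  one repeat unit from the top allele must reach 0.7 of its reads (below
  that it is PCR stutter), 0.2 at two units, with a 10-read minimum and a
  10% floor against the top allele. Genetic sex comes from the Y/X read
  ratio of an amelogenin-style marker (default threshold 0.1, compared
  unrounded).
- **Homoplasy-aware allele codes** (`decompose_allele()`,
  `encode_allele()`): each called allele is decomposed into forward
  flank (FF), microsatellite repeat array (MRA) and reverse flank (RF)
  against the locus reference; mutations per region get stable 2-digit
  codes from an append-only registry, yielding the `AAAMMFFRR` code —
  e.g. a 96 bp allele with no mutations is `96000000`, a 109 bp allele
  with the locus's 2nd MRA mutation and 3rd RF mutation is `109020003`.
  `summarize_homoplasy()` reports, per locus, how many fragment-size
  classes hide multiple sequence variants.
- **Matching and error rates** (`similarity_score()`,
  `find_duplicates()`, `unique_profile()`, `compute_error_rates()`):
  multiset allele matching over multilocus genotypes, single-linkage
  duplicate clustering with a mismatch allowance, and per-allele scoring
  error rates between two independent scorings
  (rate = mismatches / (2 × n samples) per locus), with locus filtering
  at a rate threshold.
- **Diversity** (`diversity()`, `compare_datasets()`): per-locus allele
  counts (Na) and observed heterozygosity (Ho) for length-only versus
  mutation-aware allele datasets, plus Structure / GenAlEx export.
- **Simulation** (`simulate_population()`, `simulate_reads()`): a seeded
  generator of multiplexed STR amplicon reads with stutter ladders
  (25% / 6% one and two units below, 8% above), sequencing error, flank
  mutations and low-template dropout, with full truth tables so every
  stage is testable without external data.

## Worked example

Simulate a small run, call genotypes, and code mutations:

```r
library(strseq)

panel <- example_panel(n_loci = 26)          # synthetic 26-locus panel + sex marker
cfg   <- simulation_config(panel, n_samples = 8, depth_mean = 300, seed = 42)
truth <- simulate_population(cfg)
sim   <- simulate_reads(truth, cfg)
run   <- call_simulated(sim, panel)
run$reports[[1]]
#> <strseq_sample_report> SIM001: 11178 reads, 11178 passed QC, 11178 assigned (100.0%)
#>   26/26 loci called; sex: female
head(run$genotypes[, c("locus", "allele1_len", "allele2_len", "reads1", "reads2", "zygosity")], 3)
#>   locus      allele1_len allele2_len reads1 reads2 zygosity
#> 1 SIM_STR001         105         105    274    274 hom
#> 2 SIM_STR002         108         114    143    153 het
#> 3 SIM_STR003          94          98    145    143 het
```

Reconstruct a paired-scoring error table from per-locus mismatch counts
(here the published 26-locus counts shipped in `inst/extdata/`, 84
paired-scored tissue samples):

```r
library(dplyr)
counts <- readr::read_tsv(system.file("extdata", "scoring_error_counts.tsv",
                                      package = "strseq"))
fx  <- paired_scoring_fixture(transmute(counts, locus, n_mismatch = tissue_errors),
                              n_samples = 84)
rep <- compute_error_rates(fx$score_a, fx$score_b)
rep
#> <strseq_error_report> 84 samples x 26 loci: 91 mismatches, rate 0.021
glance(filter_loci_by_error(rep, 0.05))   # drop loci with rate > 0.05
#>   n_mismatch    rate n_samples n_loci rate_rounded
#> 1         27 0.00765        84     21        0.008
```

An overall per-allele error rate of 0.021 (2.1%) falls to 0.008 (0.8%)
after removing the five loci whose individual rates exceed 0.05.

Code an allele against a locus's mutation registry:

```r
reg <- mutation_registry()
for (m in c("(GT)3A(GT)9", "(GT)7A(GT)5")) register_mutation(reg, "Cfam_STR007", "MRA", m)
for (m in c("1C>T", "4G>A", "6T>C"))       register_mutation(reg, "Cfam_STR007", "RF", m)
encode_allele(list(locus = "Cfam_STR007", mra_mut = "(GT)7A(GT)5",
                   ff_mut = "", rf_mut = "6T>C"), 109, reg)$code_text
#> [1] "109020003"
decode_allele("109020003")
#>   allele_len mm    ff    rr
#> 1        109 02    00    03
```

A command-line wrapper over the same functions lives at
`inst/cli/strseq.R` (`simulate`, `call`, `code`, `match`, `errors`,
`stats`, `export` subcommands); `run_pipeline()` is the programmatic
equivalent and writes a reproducibility manifest with config hash, input
checksums and seed.

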