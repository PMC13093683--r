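---
title: "Methods: sequence-based STR genotyping, allele coding and error accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based STR genotyping, allele coding and error accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strseq)
```

# The problem

Microsatellite (STR) genotypes have underpinned wildlife population
genetics for decades, but fragment-size scoring by capillary
electrophoresis carries three structural weaknesses: scoring is
bin-dependent and lab-specific, low-template samples (scat, hair) suffer
allelic dropout, and alleles of equal length but different sequence
(size homoplasy) are invisible. Sequencing the amplicons instead makes
every allele an explicit sequence, so calling rules, stutter handling and
mutation bookkeeping can be stated exactly and re-run identically in any
lab. `strseq` implements that pipeline end to end for multiplexed canid
panels: read calling, region-aware allele coding, duplicate matching,
paired-scoring error rates, diversity summaries, and a read simulator
that provides ground truth for all of it.

# The calling model

A panel (`load_panel()`, `validate_panel()`) defines per locus: primer
pair, repeat motif (2 or 4 bp), a reference amplicon, and plausible
length bounds. Validation locates the microsatellite repeat array (MRA)
as the longest maximal run of exact motif copies (ties to the leftmost;
at least three copies required) and derives the forward flank (FF,
between the forward primer's 3' end and the array) and reverse flank
(RF). All coordinates are 0-based half-open; the reverse primer is given
5'→3' on its own strand and reverse-complemented internally. The three
regions tile the inter-primer insert exactly — an invariant the test
suite fuzzes. Allele length is defined as the *full amplicon length in
bp, primers included*; the reference literature prints calls on that
scale (e.g. 96, 109 for ~100–150 bp amplicons), and an insert-only
convention would just shift every code.

Reads are kept when mean Phred ≥ 20 and length ≥ 80 bp. Mean rather than
minimum per-base quality is used deliberately: for 150 bp reads a single
low tail base should not discard an otherwise clean read, and the
downstream plurality-sequence grouping absorbs isolated errors. A read is
assigned to the unique locus whose forward primer matches its prefix and
whose reverse-complemented reverse primer matches its suffix, each with
at most 2 substitutions (Biostrings' mismatch-tolerant search); reads
matching two loci are dropped as ambiguous. Paired reads are merged by
exact reverse-complement overlap of ≥ 30 bp, falling back to R1 — with
2 × 150 bp sequencing over ≤ 150 bp inserts each read covers the
amplicon, so an external merger adds nothing.

Assigned reads are grouped by exact amplicon sequence, ordered by
descending read count (ties: ascending length, then sequence). Candidate
alleles must fall within the locus length bounds and have a flank
mismatch fraction ≤ 0.5 (fraction of FF+RF bases differing from the
reference, measured positionally). The caller then walks candidates in
descending read count:

1. the top candidate `T` needs ≥ 10 reads, else the locus is missing;
2. a second allele `S` needs ≥ 10 reads and ≥ 10% of `T`'s reads;
3. at one repeat unit from `T`: heterozygous iff `S/T ≥ 0.7`;
4. at two units: heterozygous iff `S/T ≥ 0.2`;
5. beyond two units: heterozygous;
6. same length, different sequence: heterozygous iff `T/S ≤ 1.5`.

Candidates failing rules 3–4 are labelled stutter and their reads are
*not* pooled into the parent allele: pooling semantics differ between
tools and are unstated in the assay literature, and the un-pooled variant
is simpler and directly testable. Length differences that are not whole
repeat units (real 1 bp insertion alleles exist, sitting between
whole-unit size classes) are handled by distance bands — a 1 bp
neighbour must clear the one-unit ratio — and the allele is reported at
its exact length, never rounded to motif phase.

Sex is called from the X/Y amplicon read counts: inconclusive below 20
total reads; male iff Y ≥ 10 reads and the *unrounded* Y/X ratio meets
the threshold; female below it. The default threshold is 0.1: at the
historical 0.02 setting, known females have been mis-called male at
ratios up to 0.0993, and two independent scorings of one sample have
disagreed purely because one rounded 0.0178 to 0.02 before comparing.
Both failure modes are regression-tested.

# Allele coding and homoplasy

Each called allele is decomposed against its locus reference
(`decompose_allele()`): the reference FF is aligned to the start of the
observed insert and the reference RF to its end with an end-anchored
semi-global alignment under unit costs (match 0, mismatch 1, gap 1); the
remainder between the consumed prefix and suffix is the observed MRA.
Tie-breaks are fixed — the minimal-cost endpoint closest to the reference
flank length, substitutions preferred over indels in traceback — so the
same sequence always yields the same decomposition. A flank with < 50%
identity aborts with a wrong-locus error. This aligner is written in the
package because the decomposition, its edit coordinates and its
tie-breaks *are* the coding scheme; a general-purpose aligner is used
only as an independent cross-check in the tests.

Flank edits are canonicalised as region-relative text (`"4C>T"`,
`"2_3insA"`, `"5delC"`, joined by `;`), and the MRA as a composition
descriptor: `"(GT)12"`, interrupted `"(GT)5A(GT)6"`, or with a trailing
insertion `"(GT)12+A"`. A pure change in repeat count is a length
difference, not a mutation, so only descriptors whose *shape* differs
from the reference register as MRA mutations. Each distinct
(locus, region, mutation text) receives a 2-digit code `"01"`–`"99"` in
first-encounter order from an append-only registry (persisted as TSV so
catalogues can be shared and extended across labs); `"00"` is reserved
for reference-identical regions, and a 100th mutation in one region is a
hard capacity error because the format cannot express it. The allele
code concatenates length and region codes as `AAAMMFFRR` (8 or 9 digits
for 2- or 3-digit lengths). Because the registry order is
dataset-dependent, codes are internally consistent rather than globally
canonical; re-encoding against a persisted registry is code-stable, which
the tests assert. Encoding order (samples by id, alleles by ascending
length) fixes the remaining order dependence.

`summarize_homoplasy()` counts, per locus, fragment-size classes
(distinct lengths), classes carrying ≥ 2 distinct codes (homoplasy), and
classes that occur only in mutated form. A `min_observations` knob can
revert mutations seen in fewer than *k* samples to `"00"` as a guard
against sequencing error promoted to allele status; the default (1) keeps
everything, since no error model is fitted — recurrence across samples is
the intended evidence.

# Matching and error rates

Multilocus genotypes are compared as unordered allele pairs (multisets)
per locus, skipping loci missing in either sample. The similarity score
is matched alleles over compared alleles; over a complete 26-locus
panel, 0–3 mismatches give 1.00, 0.98, 0.96, 0.94. Duplicate detection
is single-linkage clustering with edges at ≤ *k* allele mismatches —
single linkage mirrors the behaviour of established matching software
but can merge chains, which is why `unique_profile()` sweeps the
allowance and recommends the smallest value where the cluster count is
stable for two consecutive steps. The profile's multiple-match column (a
sample whose neighbourhood spans ≥ 2 exact-genotype classes) is a
diagnostic heuristic, not a calibrated statistic.

Scoring error between two independent scorings is per allele: at each
locus a sample contributes 0, 1 or 2 mismatches; the locus rate divides
the mismatch total by 2 × n samples, and the overall rate by
2 × n × L. With that convention the overall rate is exactly the
locus-weighted mean of per-locus rates (fuzz-tested identity), and the
published 26-locus error table — every per-locus rate and all raw and
locus-filtered totals — is reproduced exactly from its mismatch counts
(84 tissue, 18 scat paired samples; the scat filtered totals remove the
loci flagged in the *tissue* data, via the `from` argument of
`filter_loci_by_error()`). Sample/locus entries missing in one scoring
are excluded from the numerator by default, matching the practice of
excluding samples whose only discordances were missing data; a
`"count"` mode scores them as 2 mismatches. Reports round half away
from zero (3 decimals for rates, 2 for similarity); every comparison
inside the package uses unrounded values.

# Diversity

Na is the number of distinct alleles per locus and Ho the fraction of
heterozygous individuals among those scored; totals sum Na over loci and
average Ho, with the standard error taken across loci (sd/√L — the
presentation convention of the reference results, which never state a
formula). Because mutation-aware codes refine the partition induced by
lengths, Na(mut) ≥ Na(len) and Ho(mut) ≥ Ho(len) locus-wise; both are
property-tested on random recodings. `compare_datasets()` reports the
percent increase in total alleles (253 → 334 gives 32%).
Expected heterozygosity and F-statistics are deliberately out of scope —
practitioners run those in GenAlEx/Structure on the exported files
(`export_structure()`: two rows per individual, missing −9;
`export_genalex()`), and Bayesian clustering itself is external.

# The simulator and what it does (not) show

`simulate_population()` draws, per locus, 4–12 alleles (repeat-count
shifts of −5…+6 units around the reference) with Dirichlet-uniform
frequencies; 5% of allele lineages carry one mutation, split evenly
between an FF substitution, an RF substitution and an MRA interruption.
Genotypes follow Hardy–Weinberg; each sample gets a true sex.
`simulate_reads()` emits, per allele copy, Poisson(depth/2) parent reads
plus stutter at whole motif units — 25% one unit below, 6% two below,
8% one above, binomial in the parent depth — with i.i.d. substitution
errors at 0.1% per base (Q30 bases, errored bases Q15). Low-template
mode thins depth to 30% and drops each allele copy with probability
0.2, emulating scat DNA. All draws hang off one seed; FASTQ output is
byte-stable.

The stutter fractions sit below the calling ratios on purpose: they
represent a well-behaved dinucleotide assay, and with the default depth
of 300 reads/locus (the recommended floor is 150) the caller recovers
≥ 99% of genotypes, region decomposition recovers ≥ 95% of simulated
mutations, and injected read-level duplicates are recovered exactly by
the unique-profile sweep — the package's seeded stand-ins for results
that would otherwise require the original sequencing data. What passing
these checks does *not* show: robustness to primer-site variation,
chimeric/mixed profiles (excluded rather than modelled, as in the
reference workflow), locus-specific stutter idiosyncrasies, or
tetranucleotide stutter display. A "hard mode" (e.g. `minus1 = 0.6`)
exercises the ratio-rule edge cases where calls genuinely become
ambiguous.

Problem sizes in the shipped tests — 26 loci × 50 samples at depth 300
for the end-to-end check, 1,000-case property sweeps elsewhere — were
chosen as the smallest sizes at which the stochastic checks are stable,
and match the scale of the motivating study (84 individuals, 26 loci).

# Numerical and design notes

- Rounding: half away from zero everywhere a report rounds; raw values
  kept for logic. Motivated by a real sex-call discrepancy caused by
  pre-comparison rounding.
- Determinism: identical input and configuration give byte-identical
  outputs; `run_pipeline()` writes a manifest (version, config hash,
  input checksums, seed) so a run can be audited.
- The X and Y sex amplicons are modelled as separate primer pairs in the
  synthetic panel; a shared-primer amelogenin design would need
  sequence-level disambiguation that the locus-assignment step does not
  attempt (reads matching two loci are deliberately unassigned).
- `min_len`/`max_len` bounds are part of the panel definition, not
  inferred; variants outside them never become candidates.
- Known limitations: no mixture deconvolution, no PCR chimeras, no
  statistical error model for mutation validation (the registry records
  what recurs; it does not test it), and registry codes are
  dataset-order-dependent unless a shared registry TSV is used.
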