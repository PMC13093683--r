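# Seeded simulator for multiplexed STR amplicon sequencing: allele pools
# with flank/repeat mutations, Hardy-Weinberg genotypes, stutter ladders,
# per-base sequencing error, and a low-template mode with allelic
# dropout. Every read derives from a recorded truth allele, so the whole
# calling / coding / matching stack can be validated end to end.

#' Simulation configuration
#'
#' Defaults model a high-template (tissue) run of the assay: mean 300
#' assigned reads per locus (150 per allele copy, comfortably above the
#' recommended 150-read floor), a stutter ladder of 25% one unit below,
#' 6% two units below and 8% one unit above the parent allele, 0.1%
#' per-base substitution error, a 5% chance per allele lineage of one
#' flank or repeat-array mutation, and 4-12 alleles per locus with
#' Dirichlet-uniform frequencies. `low_template = TRUE` thins depth and
#' applies per-allele dropout, emulating scat-quality DNA.
#'
#' @param panel A validated `strseq_panel`.
#' @param n_samples Number of individuals.
#' @param depth_mean Mean assigned reads per locus per sample.
#' @param stutter Named list `minus1`, `minus2`, `plus1`: stutter read
#'   fractions relative to parent allele reads.
#' @param error_rate Per-base substitution error probability.
#' @param flank_mut_rate Probability that a simulated allele lineage
#'   carries one mutation (split evenly between FF, RF and an MRA
#'   interruption).
#' @param dropout Per-allele dropout probability (low-template mode
#'   only).
#' @param low_template Thin depth (x 0.3) and apply dropout.
#' @param n_alleles_range Integer range of allele-pool sizes per locus.
#' @param seed Integer seed driving every random draw.
#' @return A list of class `strseq_sim_config`.
#' @export
simulation_config <- function(panel,
                              n_samples = 50L,
                              depth_mean = 300,
                              stutter = list(minus1 = 0.25, minus2 = 0.06,
                                             plus1 = 0.08),
                              error_rate = 0.001,
                              flank_mut_rate = 0.05,
                              dropout = 0.2,
                              low_template = FALSE,
                              n_alleles_range = c(4L, 12L),
                              seed = 1L) {
  fr <- c(unlist(stutter), error_rate, flank_mut_rate, dropout)
  if (any(fr < 0 | fr >= 1)) {
    rlang::abort("all simulation fractions must lie in [0, 1)")
  }
  structure(
    list(panel = panel, n_samples = as.integer(n_samples),
         depth_mean = depth_mean, stutter = stutter,
         error_rate = error_rate, flank_mut_rate = flank_mut_rate,
         dropout = dropout, low_template = low_template,
         n_alleles_range = as.integer(n_alleles_range),
         seed = as.integer(seed)),
    class = c("strseq_sim_config", "list"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic marker panel
#'
#' Generates `n_loci` dinucleotide STR loci (24 bp primers, 12-15 bp
#' flanks, 13-16 reference repeat copies) plus an X/Y sex-marker pair,
#' with length bounds wide enough for the simulated allele range.
#' Deterministic for a given `seed`; the global RNG state is preserved.
#'
#' @param n_loci Number of STR loci.
#' @param seed Seed for panel construction.
#' @return A validated `strseq_panel`.
#' @export
example_panel <- function(n_loci = 26L, seed = 101L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  motifs <- c("GT", "CA", "AG", "TC")
  rows <- purrr::map(seq_len(n_loci), function(i) {
    motif <- motifs[(i - 1L) %% length(motifs) + 1L]
    fwd <- random_dna(24L)
    rev <- random_dna(24L)
    ff <- random_dna(sample(12:15, 1L))
    rf <- random_dna(sample(12:15, 1L))
    k <- sample(13:16, 1L)
    ref <- paste0(fwd, ff, strrep(motif, k), rf, revcomp(rev))
    tibble::tibble(
      locus_id = sprintf("SIM_STR%03d", i),
      fwd_primer = fwd, rev_primer = rev, motif = motif,
      reference_amplicon = ref,
      min_len = nchar(ref) - 13L, max_len = nchar(ref) + 15L,
      role = "str")
  })
  sex <- purrr::map2(c("sexX", "sexY"), c("SIM_AMGX", "SIM_AMGY"), function(role, id) {
    fwd <- random_dna(24L)
    rev <- random_dna(24L)
    core <- random_dna(60L)
    ref <- paste0(fwd, core, revcomp(rev))
    tibble::tibble(locus_id = id, fwd_primer = fwd, rev_primer = rev,
                   motif = "NN", reference_amplicon = ref,
                   min_len = nchar(ref), max_len = nchar(ref), role = role)
  })
  validate_panel(dplyr::bind_rows(rows, sex))
}

# Build one allele of a locus: shift the repeat count by delta units and
# optionally add one mutation. Returns the structural parts plus a truth
# annotation (region + canonical description).
build_allele <- function(locus, delta, mutate_region) {
  ref <- locus$reference_amplicon
  fwd <- substr(ref, 1L, locus$insert_start)
  ff <- substr(ref, locus$insert_start + 1L, locus$mra_start)
  rf <- substr(ref, locus$mra_end + 1L, locus$insert_end)
  rev_rc <- substr(ref, locus$insert_end + 1L, nchar(ref))
  m <- nchar(locus$motif)
  k <- (locus$mra_end - locus$mra_start) %/% m + delta
  mra <- strrep(locus$motif, k)
  mut_desc <- ""
  subst <- function(s, pos1) {  # 1-based substitution to a different base
    old <- substr(s, pos1, pos1)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(s, pos1, pos1) <- new
    list(s = s, old = old, new = new)
  }
  if (mutate_region == "FF") {
    pos <- sample(nchar(ff), 1L)
    r <- subst(ff, pos)
    ff <- r$s
    mut_desc <- sprintf("%d%s>%s", pos - 1L, r$old, r$new)
  } else if (mutate_region == "RF") {
    pos <- sample(nchar(rf), 1L)
    r <- subst(rf, pos)
    rf <- r$s
    mut_desc <- sprintf("%d%s>%s", pos - 1L, r$old, r$new)
  } else if (mutate_region == "MRA") {
    # interrupt an interior repeat copy so the composition shape changes
    pos <- sample(seq(m + 1L, nchar(mra) - m), 1L)
    r <- subst(mra, pos)
    mra <- r$s
    mut_desc <- mra_descriptor(mra, locus$motif)
  }
  list(ff = ff, mra = mra, rf = rf,
       sequence = paste0(fwd, ff, mra, rf, rev_rc),
       fwd = fwd, rev_rc = rev_rc,
       mut_region = mutate_region, mut_desc = mut_desc)
}

#' Simulate an allele pool and population truth table
#'
#' Draws a per-locus allele pool (distinct repeat-count shifts, a
#' fraction of lineages carrying a flank or repeat-array mutation) with
#' Dirichlet-uniform frequencies, then genotypes `n_samples` individuals
#' under Hardy-Weinberg and assigns each a sex. Fully determined by
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `strseq_truth`: `pool` (tibble: `locus`,
#'   `allele_id`, `length`, `sequence`, `freq`, `mut_region`,
#'   `mut_desc`, structural parts), `genotypes` (tibble: `sample_id`,
#'   `locus`, `allele1_len`, `allele2_len`, `allele1_seq`,
#'   `allele2_seq`), `sex` (tibble: `sample_id`, `sex`).
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  panel <- str_loci(config$panel)
  pool <- purrr::map(seq_len(nrow(panel)), function(i) {
    locus <- panel[i, ]
    n_all <- sample(seq(config$n_alleles_range[1L], config$n_alleles_range[2L]), 1L)
    deltas <- sample(-5:6, n_all, replace = FALSE)
    mutated <- runif(n_all) < config$flank_mut_rate
    regions <- ifelse(mutated, sample(c("FF", "RF", "MRA"), n_all, replace = TRUE),
                      "none")
    alleles <- purrr::map2(deltas, regions, ~ build_allele(locus, .x, .y))
    freq <- rgamma(n_all, 1)
    freq <- freq / sum(freq)
    locus_id <- locus$locus_id
    tibble::tibble(
      locus = locus_id,
      allele_id = sprintf("%s_a%02d", locus_id, seq_len(n_all)),
      length = vapply(alleles, function(a) nchar(a$sequence), integer(1)),
      sequence = vapply(alleles, `[[`, character(1), "sequence"),
      ff = vapply(alleles, `[[`, character(1), "ff"),
      mra = vapply(alleles, `[[`, character(1), "mra"),
      rf = vapply(alleles, `[[`, character(1), "rf"),
      fwd = vapply(alleles, `[[`, character(1), "fwd"),
      rev_rc = vapply(alleles, `[[`, character(1), "rev_rc"),
      freq = freq,
      mut_region = vapply(alleles, `[[`, character(1), "mut_region"),
      mut_desc = vapply(alleles, `[[`, character(1), "mut_desc"))
  }) |>
    dplyr::bind_rows()

  sample_ids <- sprintf("SIM%03d", seq_len(config$n_samples))
  genotypes <- purrr::map(split(pool, pool$locus), function(p) {
    idx1 <- sample(nrow(p), config$n_samples, replace = TRUE, prob = p$freq)
    idx2 <- sample(nrow(p), config$n_samples, replace = TRUE, prob = p$freq)
    swap <- p$length[idx2] < p$length[idx1] |
      (p$length[idx2] == p$length[idx1] & p$sequence[idx2] < p$sequence[idx1])
    a <- ifelse(swap, idx2, idx1)
    b <- ifelse(swap, idx1, idx2)
    tibble::tibble(
      sample_id = sample_ids, locus = p$locus[1L],
      allele1_len = p$length[a], allele2_len = p$length[b],
      allele1_seq = p$sequence[a], allele2_seq = p$sequence[b],
      allele1_id = p$allele_id[a], allele2_id = p$allele_id[b])
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$sample_id, .data$locus)

  sex <- tibble::tibble(
    sample_id = sample_ids,
    sex = sample(c("female", "male"), config$n_samples, replace = TRUE))
  structure(list(pool = pool, genotypes = genotypes, sex = sex,
                 config = config),
            class = "strseq_truth")
}

# Apply i.i.d. substitution errors to n copies of one amplicon; returns
# tibble(sequence, qual). Error-free reads share one Q30 string.
seq_with_errors <- function(sequence, n, error_rate) {
  len <- nchar(sequence)
  q30 <- strrep(rawToChar(as.raw(30L + 33L)), len)
  if (n == 0L) {
    return(tibble::tibble(sequence = character(0), qual = character(0)))
  }
  n_err <- rbinom(n, len, error_rate)
  out_seq <- rep(sequence, n)
  out_q <- rep(q30, n)
  bad <- which(n_err > 0L)
  for (i in bad) {
    s <- strsplit(sequence, "")[[1]]
    q <- rep(30L, len)
    pos <- sample(len, n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      q[p] <- 15L
    }
    out_seq[i] <- paste(s, collapse = "")
    out_q[i] <- rawToChar(as.raw(q + 33L))
  }
  tibble::tibble(sequence = out_seq, qual = out_q)
}

# Stutter variants of an allele: whole motif units removed from / added
# to the end of the repeat array.
stutter_sequence <- function(pool_row, units, motif) {
  m <- nchar(motif)
  mra <- pool_row$mra
  new_mra <- if (units < 0L) {
    substr(mra, 1L, nchar(mra) + units * m)
  } else {
    paste0(mra, strrep(motif, units))
  }
  paste0(pool_row$fwd, pool_row$ff, new_mra, pool_row$rf, pool_row$rev_rc)
}

#' Simulate amplicon reads from a truth table
#'
#' For each sample, locus and allele copy: parent reads at depth
#' Poisson(`depth_mean` / 2), stutter reads one and two units below and
#' one unit above the parent at the configured fractions (binomial in
#' the parent depth), i.i.d. substitution errors, constant Q30 qualities
#' with errored bases at Q15. Sex-marker reads are generated from the X
#' and Y amplicons according to the sample's true sex. Low-template mode
#' thins depth to 30% and drops each allele copy with probability
#' `dropout`. Fully determined by `config$seed`.
#'
#' @param truth A `strseq_truth` from [simulate_population()].
#' @param config The same [simulation_config()].
#' @param out_dir Optional directory; when given, one FASTQ per sample is
#'   written (`<sample_id>.fastq`) along with `depth_log.tsv`.
#' @return A list of class `strseq_sim_reads`: `reads` (tibble
#'   `sample_id`, `id`, `sequence`, `qual`), `depth_log` (tibble
#'   `sample_id`, `locus`, `n_reads`), `files` (paths or `NULL`).
#' @export
simulate_reads <- function(truth, config, out_dir = NULL) {
  set.seed(config$seed + 1L)
  panel <- config$panel
  strp <- str_loci(panel)
  depth_mean <- config$depth_mean * (if (config$low_template) 0.3 else 1)
  pool_by <- split(truth$pool, truth$pool$allele_id)
  all_reads <- vector("list", config$n_samples)
  gl <- split(truth$genotypes, truth$genotypes$sample_id)
  for (si in seq_len(config$n_samples)) {
    sid <- truth$sex$sample_id[si]
    g <- gl[[sid]]
    sample_reads <- list()
    for (ri in seq_len(nrow(g))) {
      locus <- strp[strp$locus_id == g$locus[ri], ]
      for (aid in c(g$allele1_id[ri], g$allele2_id[ri])) {
        if (config$low_template && runif(1) < config$dropout) next
        p <- pool_by[[aid]]
        n_parent <- rpois(1L, depth_mean / 2)
        if (n_parent == 0L) next
        variants <- list(list(seq = p$sequence, n = n_parent))
        for (st in list(c(-1L, config$stutter$minus1),
                        c(-2L, config$stutter$minus2),
                        c(1L, config$stutter$plus1))) {
          n_st <- rbinom(1L, n_parent, st[2L])
          if (n_st > 0L) {
            variants[[length(variants) + 1L]] <-
              list(seq = stutter_sequence(p, as.integer(st[1L]), locus$motif),
                   n = n_st)
          }
        }
        for (v in variants) {
          chunk <- seq_with_errors(v$seq, v$n, config$error_rate)
          chunk$locus <- locus$locus_id
          sample_reads[[length(sample_reads) + 1L]] <- chunk
        }
      }
    }
    # sex-marker reads
    sex_rows <- panel[panel$role %in% c("sexX", "sexY"), ]
    if (nrow(sex_rows) == 2L) {
      is_male <- truth$sex$sex[si] == "male"
      xn <- rpois(1L, if (is_male) depth_mean / 2 else depth_mean)
      yn <- if (is_male) rpois(1L, depth_mean / 2) else 0L
      xref <- sex_rows$reference_amplicon[sex_rows$role == "sexX"]
      yref <- sex_rows$reference_amplicon[sex_rows$role == "sexY"]
      chunk <- seq_with_errors(xref, xn, config$error_rate)
      chunk$locus <- sex_rows$locus_id[sex_rows$role == "sexX"]
      sample_reads[[length(sample_reads) + 1L]] <- chunk
      if (yn > 0L) {
        chunk <- seq_with_errors(yref, yn, config$error_rate)
        chunk$locus <- sex_rows$locus_id[sex_rows$role == "sexY"]
        sample_reads[[length(sample_reads) + 1L]] <- chunk
      }
    }
    reads <- dplyr::bind_rows(sample_reads)
    if (nrow(reads) > 0L) {
      reads <- reads[sample(nrow(reads)), ]  # shuffle as a sequencer would
      reads$id <- sprintf("%s_read%06d", sid, seq_len(nrow(reads)))
      reads$sample_id <- sid
      all_reads[[si]] <- reads[, c("sample_id", "id", "locus", "sequence", "qual")]
    }
  }
  reads <- dplyr::bind_rows(all_reads)
  depth_log <- dplyr::count(reads, .data$sample_id, .data$locus,
                            name = "n_reads")
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(split(reads, reads$sample_id), function(r) {
      path <- file.path(out_dir, paste0(r$sample_id[1L], ".fastq"))
      write_fastq(r, path)
      path
    }, character(1))
    readr::write_tsv(reads |> dplyr::count(.data$sample_id, name = "n_reads"),
                     file.path(out_dir, "depth_log.tsv"))
  }
  structure(list(reads = reads, depth_log = depth_log, files = files),
            class = "strseq_sim_reads")
}

#' Genotype every simulated sample
#'
#' Convenience wrapper: runs [call_sample()] on each sample's reads.
#'
#' @param sim A `strseq_sim_reads`.
#' @param panel The panel used for simulation.
#' @param thresholds A [calling_thresholds()] object.
#' @return A list of `strseq_sample_report`s, plus combined `genotypes`
#'   and `sex` tibbles, class `strseq_run_report`.
#' @export
call_simulated <- function(sim, panel, thresholds = calling_thresholds()) {
  reports <- lapply(split(sim$reads, sim$reads$sample_id), function(r) {
    call_sample(r[, c("id", "sequence", "qual")], panel, thresholds,
                sample_id = r$sample_id[1L])
  })
  structure(
    list(reports = reports,
         genotypes = dplyr::bind_rows(lapply(reports, `[[`, "genotypes")),
         sex = dplyr::bind_rows(lapply(reports, `[[`, "sex"))),
    class = "strseq_run_report")
}
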