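# Orchestration: run simulate -> call -> code -> errors/match -> stats as
# one pipeline with a reproducible run manifest.

pipeline_stages <- c("simulate", "call", "code", "match", "errors", "stats",
                     "export")

stage_deps <- list(
  simulate = character(0),
  call = character(0),      # needs FASTQs: simulate output or sample sheet
  code = "call",
  match = "call",
  errors = "call",
  stats = "code",
  export = "code"
)

#' Run the genotyping pipeline
#'
#' Executes the requested stages in order over a shared output directory:
#' `simulate` writes per-sample FASTQs from a seeded simulation; `call`
#' genotypes every FASTQ; `code` encodes alleles and writes the mutation
#' registry and homoplasy summary; `match` clusters duplicate genotypes;
#' `errors` compares two independent scorings when both are present (here:
#' a re-call of the same reads, so rates are zero unless inputs differ);
#' `stats` writes diversity summaries for the length and code datasets;
#' `export` writes Structure and GenAlEx files. A `manifest.json` with
#' tool version, config hash, input checksums, seed and timestamps is
#' written at the end; reruns with the same seed and config produce
#' identical non-timestamp outputs.
#'
#' @param config A [simulation_config()] (drives `simulate`) or a list
#'   with `panel` and `thresholds` entries for FASTQ input via
#'   `sample_sheet` (tibble `sample_id`, `fastq1`, optional `fastq2`).
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate","call","code","match","errors","stats","export")`.
#' @param thresholds A [calling_thresholds()] object.
#' @param sample_sheet Optional sample sheet when not simulating.
#' @param scoring_a,scoring_b Optional paths to two genotype TSVs for the
#'   `errors` stage (paired independent scorings); when absent, the stage
#'   falls back to `genotypes.tsv` compared against `scoring_b`, and
#'   fails with a dependency error if neither input exists.
#' @return The manifest list, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "call", "code", "stats"),
                         thresholds = calling_thresholds(),
                         sample_sheet = NULL,
                         scoring_a = NULL, scoring_b = NULL) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  panel <- config$panel
  done <- character(0)

  need <- function(stage) {
    dep <- stage_deps[[stage]]
    missing_dep <- setdiff(dep, done)
    for (d in missing_dep) {
      # accept outputs of a previous run in the same out_dir
      marker <- switch(d,
        call = file.path(out_dir, "genotypes.tsv"),
        code = file.path(out_dir, "genotypes_coded.tsv"),
        file.path(out_dir, d))
      if (!file.exists(marker)) {
        rlang::abort(sprintf(
          "stage '%s' requires output of stage '%s' which has not run (missing %s)",
          stage, d, marker))
      }
    }
  }

  fastqs <- NULL
  if ("simulate" %in% stages) {
    truth <- simulate_population(config)
    sim <- simulate_reads(truth, config, out_dir = file.path(out_dir, "fastq"))
    readr::write_tsv(truth$genotypes, file.path(out_dir, "truth_genotypes.tsv"))
    readr::write_tsv(truth$sex, file.path(out_dir, "truth_sex.tsv"))
    fastqs <- tibble::tibble(
      sample_id = names(sim$files), fastq1 = unname(sim$files))
    done <- c(done, "simulate")
  } else if (!is.null(sample_sheet)) {
    fastqs <- sample_sheet
  }

  if ("call" %in% stages) {
    if (is.null(fastqs)) {
      rlang::abort("stage 'call' requires simulated FASTQs or a sample_sheet")
    }
    reports <- purrr::map(seq_len(nrow(fastqs)), function(i) {
      paths <- c(fastqs$fastq1[i],
                 if ("fastq2" %in% names(fastqs)) fastqs$fastq2[i])
      call_sample(paths[!is.na(paths)], panel, thresholds,
                  sample_id = fastqs$sample_id[i])
    })
    genotypes <- dplyr::bind_rows(purrr::map(reports, "genotypes"))
    sex <- dplyr::bind_rows(purrr::map(reports, "sex"))
    depth <- dplyr::bind_rows(purrr::map(reports, "depth"))
    readr::write_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    if (nrow(sex) > 0) readr::write_tsv(sex, file.path(out_dir, "sex.tsv"))
    readr::write_tsv(depth, file.path(out_dir, "depth.tsv"))
    done <- c(done, "call")
  }

  genotypes_path <- file.path(out_dir, "genotypes.tsv")
  read_geno <- function() readr::read_tsv(genotypes_path, show_col_types = FALSE)

  if ("code" %in% stages) {
    need("code")
    genotypes <- read_geno()
    registry <- mutation_registry()
    coded <- encode_genotypes(genotypes, panel, registry)
    readr::write_tsv(coded, file.path(out_dir, "genotypes_coded.tsv"))
    write_registry(registry, file.path(out_dir, "mutation_registry.tsv"))
    coded_long <- dplyr::bind_rows(
      dplyr::transmute(coded, locus = .data$locus, code_text = .data$allele1_mut),
      dplyr::transmute(coded, locus = .data$locus, code_text = .data$allele2_mut)) |>
      dplyr::filter(!is.na(.data$code_text))
    readr::write_tsv(summarize_homoplasy(coded_long),
                     file.path(out_dir, "homoplasy.tsv"))
    done <- c(done, "code")
  }

  if ("match" %in% stages) {
    need("match")
    ml <- as_multilocus(read_geno(), "len")
    prof <- unique_profile(ml)
    clusters <- find_duplicates(ml, attr(prof, "recommended") %||% 4L)
    readr::write_tsv(prof, file.path(out_dir, "unique_profile.tsv"))
    readr::write_tsv(clusters, file.path(out_dir, "duplicate_clusters.tsv"))
    done <- c(done, "match")
  }

  if ("errors" %in% stages) {
    a_path <- scoring_a %||% genotypes_path
    if (!file.exists(a_path) || is.null(scoring_b) || !file.exists(scoring_b)) {
      rlang::abort(
        "stage 'errors' requires two genotype inputs: stage 'call' output (or scoring_a) plus scoring_b")
    }
    ga <- as_multilocus(readr::read_tsv(a_path, show_col_types = FALSE), "len")
    gb <- as_multilocus(readr::read_tsv(scoring_b, show_col_types = FALSE), "len")
    rep <- compute_error_rates(ga, gb)
    readr::write_tsv(
      dplyr::bind_rows(
        rep$per_locus,
        dplyr::mutate(rep$overall, locus = "Total")[, names(rep$per_locus)[
          names(rep$per_locus) %in% c("locus", "n_mismatch", "rate", "rate_rounded")]]),
      file.path(out_dir, "error_report.tsv"))
    done <- c(done, "errors")
  }

  if ("stats" %in% stages) {
    need("stats")
    coded <- readr::read_tsv(file.path(out_dir, "genotypes_coded.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               allele1_mut = "c", allele2_mut = "c",
                               .default = readr::col_guess()))
    div_len <- diversity(as_multilocus(coded, "len"))
    div_mut <- diversity(as_multilocus(coded, "mut"))
    readr::write_tsv(div_len, file.path(out_dir, "diversity_len.tsv"))
    readr::write_tsv(div_mut, file.path(out_dir, "diversity_mut.tsv"))
    readr::write_tsv(compare_datasets(div_len, div_mut),
                     file.path(out_dir, "diversity_comparison.tsv"))
    done <- c(done, "stats")
  }

  if ("export" %in% stages) {
    need("export")
    coded <- readr::read_tsv(file.path(out_dir, "genotypes_coded.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               allele1_mut = "c", allele2_mut = "c",
                               .default = readr::col_guess()))
    loci <- str_loci(panel)$locus_id
    export_structure(as_multilocus(coded, "len"),
                     file.path(out_dir, "structure_len.txt"), loci = loci)
    export_structure(as_multilocus(coded, "mut"),
                     file.path(out_dir, "structure_mut.txt"), loci = loci)
    export_genalex(as_multilocus(coded, "len"),
                   file.path(out_dir, "genalex_len.csv"), loci = loci)
    done <- c(done, "export")
  }

  manifest <- list(
    tool = "strseq",
    version = as.character(utils::packageVersion("strseq")),
    stages = done,
    seed = config$seed %||% NA_integer_,
    config_hash = config_hash(config),
    thresholds = unclass(thresholds),
    input_checksums = if (!is.null(fastqs) && all(file.exists(fastqs$fastq1)))
      as.list(tools::md5sum(fastqs$fastq1)) else list(),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Stable hash of a configuration: md5 of its canonical JSON, panel
# reduced to its definition columns.
config_hash <- function(config) {
  x <- unclass(config)
  if (!is.null(x$panel)) {
    cols <- intersect(c("locus_id", "fwd_primer", "rev_primer", "motif",
                        "reference_amplicon", "min_len", "max_len", "role"),
                      names(x$panel))
    x$panel <- as.data.frame(x$panel)[, cols]
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(json, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
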