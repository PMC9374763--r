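#' Build and validate a pipeline run configuration
#'
#' A single seed drives every stage; per-library seeds are derived from
#' it. The defaults describe the emulated experiment: three dose levels
#' of an induction series, 50,000 reads per library at 50 cycles, the
#' standard small-RNA 3' adapter, genome/category mapping at 1 mismatch
#' with fragment counting at 0 mismatches and full-length counting at 1,
#' and a 0.05 significance threshold for the dose correlation.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory for all artifacts.
#' @param doses Dose covariate values, one library each.
#' @param trf_fractions Intended fragment fraction per dose.
#' @param n_reads Reads per library.
#' @param adapter 3' adapter sequence.
#' @param read_length Read length in cycles.
#' @param composition Relative non-fragment category weights.
#' @param mismatches Named list: `genome`, `category`, `fragment`,
#'   `full_length`.
#' @param alpha Significance threshold for the dose correlation,
#'   in (0, 1).
#' @param trna_fasta Optional path to an external tRNA reference FASTA
#'   used for quantification instead of the bundle's tRNA set; must be
#'   readable at validation time.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("trfkit_run_"),
                            doses = c(0, 0.5, 1),
                            trf_fractions = c(0.005, 0.02, 0.05),
                            n_reads = 50000L,
                            adapter = default_adapter(),
                            read_length = 50L,
                            composition = default_composition(),
                            mismatches = list(genome = 1L, category = 1L,
                                              fragment = 0L,
                                              full_length = 1L),
                            alpha = 0.05,
                            trna_fasta = NULL) {
  config <- list(seed = as.integer(seed), out_dir = out_dir,
                 doses = as.numeric(doses),
                 trf_fractions = as.numeric(trf_fractions),
                 n_reads = as.integer(n_reads), adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 composition = composition, mismatches = mismatches,
                 alpha = alpha, trna_fasta = trna_fasta)
  validate_config(config)
  structure(config, class = "run_config")
}

validate_config <- function(config) {
  if (length(config$doses) != length(config$trf_fractions)) {
    stop("configuration error: doses and trf_fractions lengths differ")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("configuration error: alpha must lie in (0, 1)")
  }
  if (grepl("[^ACGT]", config$adapter)) {
    stop("configuration error: adapter must be ACGT DNA")
  }
  if (!all(c("genome", "category", "fragment", "full_length") %in%
           names(config$mismatches))) {
    stop("configuration error: mismatches must name genome, category, ",
         "fragment and full_length")
  }
  if (!is.null(config$trna_fasta) && !file.exists(config$trna_fasta)) {
    stop("configuration error: trna_fasta path is not readable: ",
         config$trna_fasta)
  }
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' Flat `key: value` file in Debian-control (DCF) format, the base-R
#' native key-value layout. Vector fields (`doses`, `trf_fractions`)
#' are comma-separated; `composition` entries are `name=value` pairs.
#' Missing keys fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to the DCF configuration file.
#' @return A validated `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  args <- list()
  num_vec <- function(x) as.numeric(strsplit(x, ",")[[1L]])
  if (!is.null(raw$seed)) args$seed <- as.integer(raw$seed)
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  if (!is.null(raw$doses)) args$doses <- num_vec(raw$doses)
  if (!is.null(raw$trf_fractions)) {
    args$trf_fractions <- num_vec(raw$trf_fractions)
  }
  if (!is.null(raw$n_reads)) args$n_reads <- as.integer(raw$n_reads)
  if (!is.null(raw$adapter)) args$adapter <- raw$adapter
  if (!is.null(raw$read_length)) {
    args$read_length <- as.integer(raw$read_length)
  }
  if (!is.null(raw$alpha)) args$alpha <- as.numeric(raw$alpha)
  if (!is.null(raw$trna_fasta)) args$trna_fasta <- raw$trna_fasta
  if (!is.null(raw$composition)) {
    parts <- strsplit(strsplit(raw$composition, ",")[[1L]], "=")
    args$composition <- stats::setNames(
      as.numeric(vapply(parts, `[`, character(1L), 2L)),
      trimws(vapply(parts, `[`, character(1L), 1L))
    )
  }
  do.call(pipeline_config, args)
}

#' Run the simulate-trim-classify-quantify-correlate pipeline
#'
#' Executes the full analysis as one reproducible run: builds a
#' synthetic reference bundle, simulates the dose-series libraries,
#' trims adapter read-through and partitions each library, profiles the
#' library composition by sequential precedence classification, counts
#' the 31-nt fragment (percent of the trimmed library) and full-length
#' tRNAs, computes read-length profiles, and correlates the fragment
#' share with dose. All tables are written as TSV under
#' `config$out_dir`, plus a JSON manifest echoing the configuration.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return The run manifest, invisibly: output paths, per-library
#'   summaries, and `rho` / `p` for the dose series.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, 2L)

  bundle <- build_reference_bundle(seed = seeds[1L])
  trna_refs <- if (!is.null(config$trna_fasta)) {
    fa <- read_fasta(config$trna_fasta)
    stats::setNames(fa$seq, fa$id)
  } else {
    bundle$categories[["tRNA"]]
  }
  series <- simulate_dose_series(
    bundle, config$doses, config$trf_fractions, config$n_reads,
    composition = config$composition, adapter = config$adapter,
    read_length = config$read_length, seed = seeds[2L]
  )

  oligos <- trimet_sequences()
  trf_dna <- oligos[["trf31_dna"]]
  libs <- list()
  files <- character()
  for (i in seq_along(series)) {
    lib <- series[[i]]
    tag <- sprintf("dose%02d", i)
    fq <- file.path(config$out_dir, paste0(tag, ".fastq"))
    write_fastq(lib$reads, fq)
    truth_path <- file.path(config$out_dir, paste0(tag, "_truth.tsv"))
    write_table(lib$truth$reads, truth_path)

    part <- partition_library(lib$reads, config$adapter,
                              full_length_window = c(50L, 51L))
    cls <- classify_reads(part$trimmed, bundle$categories, bundle$genome,
                          max_mismatches = config$mismatches$category)
    comp_path <- file.path(config$out_dir, paste0(tag, "_composition.tsv"))
    write_table(composition_report(cls$composition), comp_path)

    quant <- quantify_fragment(part$trimmed, trna_refs,
                               max_mismatches = config$mismatches$fragment,
                               total_reads = nrow(part$trimmed),
                               library_id = tag)
    trf_path <- file.path(config$out_dir, paste0(tag, "_trf.tsv"))
    write_table(data.frame(ref_id = names(quant$trf_counts),
                           count = as.integer(quant$trf_counts),
                           stringsAsFactors = FALSE), trf_path)

    full_counts <- quantify_full_length(
      part$full_length, trna_refs,
      max_mismatches = config$mismatches$full_length
    )
    prof <- length_profile(part$trimmed, total_reads = nrow(part$trimmed),
                           library_id = tag)
    prof_path <- file.path(config$out_dir, paste0(tag, "_lenprof.tsv"))
    write_table(prof, prof_path)

    ft <- quant$fragment_table
    trimet_count <- if (trf_dna %in% ft$sequence) {
      ft$count[ft$sequence == trf_dna]
    } else 0L
    libs[[tag]] <- list(
      dose = lib$dose,
      intended_trf_fraction = lib$truth$intended_trf_fraction,
      n_input = part$n_input, n_trimmed = part$n_trimmed,
      n_full_length = part$n_full_length, n_discarded = part$n_discarded,
      trf_percent = quant$trf_percent,
      trimet_percent = 100 * trimet_count / quant$total_reads,
      top_fragment = quant$top_fragment,
      full_length_total = sum(full_counts)
    )
    files <- c(files, fq, truth_path, comp_path, trf_path, prof_path)
  }

  corr <- dose_correlation(
    vapply(libs, `[[`, numeric(1L), "dose"),
    vapply(libs, `[[`, numeric(1L), "trimet_percent")
  )
  corr_path <- file.path(config$out_dir, "dose_correlation.tsv")
  write_table(data.frame(
    statistic = "spearman_rho", rho = corr$rho, p = corr$p, n = corr$n,
    significant = !is.na(corr$p) && corr$p < config$alpha
  ), corr_path)
  files <- c(files, corr_path)

  manifest <- list(
    package = "trfkit",
    version = as.character(utils::packageVersion("trfkit")),
    config = unclass(config),
    libraries = libs,
    dose_correlation = corr,
    significant = !is.na(corr$p) && corr$p < config$alpha,
    files = files,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}
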