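#' Precedence-ordered category database
#'
#' The annotation hierarchy for sequential read classification, as an
#' ordered list of named reference-sequence sets. The default order is
#' the one used for small-RNA library composition profiling: miRNA,
#' piRNA, snoRNA, rRNA, tRNA, CDS, Promoters, 5'UTR, 3'UTR, Introns,
#' repeats (earlier categories claim reads first).
#'
#' @param sets Named list; each element a named character vector of
#'   reference DNA sequences. List order is the precedence order.
#' @return The validated list, classed `category_db`.
#' @export
category_db <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) ||
      any(!nzchar(names(sets))) || anyDuplicated(names(sets))) {
    stop("categories must be a named list with unique non-empty names")
  }
  for (nm in names(sets)) {
    if (length(sets[[nm]]) > 0L) sets[[nm]] <- validate_refs(sets[[nm]])
  }
  structure(sets, class = "category_db")
}

#' @rdname category_db
#' @export
trf_category_order <- function() {
  c("miRNA", "piRNA", "snoRNA", "rRNA", "tRNA", "CDS", "Promoters",
    "5'UTR", "3'UTR", "Introns", "repeats")
}

#' @export
print.category_db <- function(x, ...) {
  cat("Category database (precedence order):\n")
  for (nm in names(x)) cat("  ", nm, ": ", length(x[[nm]]),
                           " reference(s)\n", sep = "")
  invisible(x)
}

default_n_per_category <- function() {
  stats::setNames(
    c(30L, 30L, 10L, 2L, 15L, 8L, 6L, 6L, 6L, 6L, 6L),
    trf_category_order()
  )
}

default_length_ranges <- function() {
  r <- list(c(20, 24), c(26, 31), c(60, 100), c(500, 800), c(70, 90),
            c(300, 600), c(200, 400), c(100, 200), c(150, 300),
            c(200, 500), c(100, 300))
  stats::setNames(r, trf_category_order())
}

random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Build a synthetic reference bundle
#'
#' Generates a deterministic set of random reference sequences for every
#' annotation category plus a concatenated "genome" containing them all.
#' The tRNA category always contains a tRNA-iMet-like reference whose
#' first 31 nt are the published fragment sequence (DNA form), followed
#' by the reverse complement of the published FISH probe and a fixed
#' 10-nt tail -- 73 nt in all, so the fragment is its exact 5' prefix.
#' References are rejection-sampled so that no reference is a substring
#' of a reference in an earlier-precedence category.
#'
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param n_per_category Named integer vector, references per category.
#' @param length_ranges Named list of `(min, max)` reference lengths (nt).
#' @return A list of class `reference_bundle`: `categories` (a
#'   [category_db()]), `genome` (single concatenated DNA string) and
#'   `trna_imet_like` (the 73-nt constructed tRNA).
#' @examples
#' b <- build_reference_bundle(seed = 1)
#' nchar(b$trna_imet_like) # 73
#' @export
build_reference_bundle <- function(seed,
                                   n_per_category = default_n_per_category(),
                                   length_ranges = default_length_ranges()) {
  stopifnot(all(n_per_category >= 0L),
            all(names(n_per_category) %in% names(length_ranges)))
  set.seed(as.integer(seed))
  oligos <- trimet_sequences()
  imet <- paste0(oligos[["trf31_dna"]],
                 reverse_complement(oligos[["fish_probe"]]),
                 "TCTGCTACCA")
  sets <- list()
  earlier <- character()
  for (cat in names(n_per_category)) {
    n <- n_per_category[[cat]]
    rng <- length_ranges[[cat]]
    seqs <- character(0L)
    if (cat == "tRNA") {
      seqs <- c(tRNA_iMet_like = imet)
      n <- max(0L, n - 1L)
    }
    if (n > 0L) {
      lens <- sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
      cand <- character(n)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (attempt in 1:100) {
          s <- random_dna(1L, lens[i])
          if (!any(vapply(earlier, grepl, logical(1L), x = s, fixed = TRUE) |
                   vapply(earlier, function(e) grepl(s, e, fixed = TRUE),
                          logical(1L)))) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("reference generation failed for category '", cat,
                      "' after 100 rejection attempts")
        cand[i] <- s
      }
      names(cand) <- sprintf("%s_%03d", gsub("'", "p", cat),
                             seq_len(n) + (cat == "tRNA"))
      seqs <- c(seqs, cand)
    }
    sets[[cat]] <- seqs
    earlier <- c(earlier, seqs)
  }
  structure(list(
    categories = category_db(sets),
    genome = paste(unlist(sets, use.names = FALSE), collapse = ""),
    trna_imet_like = unname(imet)
  ), class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("Reference bundle: ", sum(lengths(x$categories)), " references in ",
      length(x$categories), " categories; genome ", nchar(x$genome),
      " nt\n", sep = "")
  invisible(x)
}

#' Simulate one small-RNA sequencing library with ground truth
#'
#' Emulates 50-cycle single-end small-RNA sequencing with 3' adapter
#' read-through. Each read is an insert followed by the adapter,
#' truncated to `read_length`; when insert + adapter still falls short of
#' the read length the remainder is filled with random bases (as after
#' running off a short template). Inserts are 5'-anchored fragments
#' (prefixes) of their source reference -- mature small RNAs and 5' tRNA
#' fragments -- of 18-35 nt; a `full_length_fraction` share of tRNA-category
#' reads instead carries the whole tRNA, yielding adapter-free reads. A
#' `trf_fraction` share of all reads has the published 31-nt fragment as
#' its exact insert. Quality is a constant 'I' (Phred 40): downstream
#' analysis never uses it.
#'
#' @param bundle A [build_reference_bundle()] result.
#' @param composition Named fractions over the bundle's categories for
#'   non-fragment reads; together with `trf_fraction` must sum to 1.
#' @param trf_fraction Fraction of reads that are the tRiMetF31 insert.
#' @param n_reads Number of reads to simulate.
#' @param adapter 3' adapter sequence.
#' @param read_length Sequencer read length (cycles).
#' @param seed Integer seed.
#' @param library_id Prefix for read ids.
#' @param insert_range `(min, max)` fragment insert length in nt.
#' @param full_length_fraction Share of tRNA-category reads carrying the
#'   full-length tRNA as insert.
#' @return List with `reads` (sequence records) and `truth`: per-read
#'   data frame (`read_id`, `category`, `ref_id`, `insert_len`, `is_trf`)
#'   plus per-library metadata (`dose`, `intended_trf_fraction`,
#'   `n_reads`, `seed`).
#' @export
simulate_library <- function(bundle, composition, trf_fraction, n_reads,
                             adapter = default_adapter(), read_length = 50L,
                             seed = 1L, library_id = "lib1",
                             insert_range = c(18L, 35L),
                             full_length_fraction = 0.05) {
  cats <- bundle$categories
  stopifnot(all(names(composition) %in% names(cats)))
  if (any(composition < 0) || trf_fraction < 0) {
    stop("composition fractions must be non-negative")
  }
  if (abs(sum(composition) + trf_fraction - 1) > 1e-9) {
    stop("composition fractions plus trf_fraction must sum to 1")
  }
  set.seed(as.integer(seed))
  oligos <- trimet_sequences()
  trf <- oligos[["trf31_dna"]]

  src <- sample(c(names(composition), ".trf"), n_reads, replace = TRUE,
                prob = c(composition, trf_fraction))
  category <- ifelse(src == ".trf", "tRNA", src)
  ref_id <- character(n_reads)
  insert <- character(n_reads)

  is_trf <- src == ".trf"
  ref_id[is_trf] <- "tRNA_iMet_like"
  insert[is_trf] <- trf

  for (cat in unique(src[!is_trf])) {
    idx <- which(src == cat)
    refs <- cats[[cat]]
    if (length(refs) == 0L) stop("category '", cat, "' has no references")
    pick <- sample.int(length(refs), length(idx), replace = TRUE)
    ref_id[idx] <- names(refs)[pick]
    rlen <- nchar(refs)[pick]
    ilen <- pmin(rlen, sample(seq(insert_range[1L], insert_range[2L]),
                              length(idx), replace = TRUE))
    if (cat == "tRNA" && full_length_fraction > 0) {
      fl <- runif(length(idx)) < full_length_fraction
      ilen[fl] <- rlen[fl]
    }
    insert[idx] <- substr(refs[pick], 1L, ilen)
  }

  read <- substr(paste0(insert, adapter), 1L, read_length)
  pad <- pmax(0L, read_length - nchar(read))
  if (any(pad > 0L)) {
    big <- paste(sample(c("A", "C", "G", "T"), sum(pad), replace = TRUE),
                 collapse = "")
    ends <- cumsum(pad)
    starts <- ends - pad + 1L
    need <- pad > 0L
    read[need] <- paste0(read[need],
                         substring(big, starts[need], ends[need]))
  }

  ids <- sprintf("%s_r%06d", library_id, seq_len(n_reads))
  reads <- seq_records(ids, read, strrep("I", nchar(read)))
  truth_reads <- data.frame(read_id = ids, category = category,
                            ref_id = ref_id, insert_len = nchar(insert),
                            is_trf = is_trf, stringsAsFactors = FALSE)
  list(reads = reads,
       truth = list(reads = truth_reads,
                    dose = NA_real_,
                    intended_trf_fraction = trf_fraction,
                    n_reads = n_reads,
                    seed = as.integer(seed)))
}

#' Simulate a dose series of libraries
#'
#' One library per dose with the fragment share rising with dose while
#' the relative composition of all non-fragment reads is held constant
#' (each library's non-fragment fractions are the same `composition`
#' rescaled to `1 - trf_fraction`). Per-dose seeds are derived
#' deterministically from the base seed.
#'
#' @param bundle A [build_reference_bundle()] result.
#' @param doses Ordered numeric dose values (arbitrary units).
#' @param trf_fractions Intended fragment fraction per dose; must be
#'   non-decreasing when doses increase.
#' @param n_reads Reads per library.
#' @param composition Relative (will be normalized) non-fragment category
#'   weights; default is the profiled library composition used throughout
#'   the package: miRNA .40, piRNA .05, snoRNA .05, rRNA .10, tRNA .25
#'   and .15 split evenly over the six mRNA-region/repeat categories.
#' @param adapter,read_length,seed,... Passed to [simulate_library()].
#' @return List with one element per dose: `dose`, `reads`, `truth`.
#' @export
simulate_dose_series <- function(bundle, doses, trf_fractions, n_reads,
                                 composition = default_composition(),
                                 adapter = default_adapter(),
                                 read_length = 50L, seed = 1L, ...) {
  if (length(doses) != length(trf_fractions)) {
    stop("doses and trf_fractions must have the same length")
  }
  if (length(doses) > 1L && all(diff(doses) > 0) &&
      any(diff(trf_fractions) < 0)) {
    stop("trf_fractions must be non-decreasing when doses increase")
  }
  rel <- composition / sum(composition)
  set.seed(as.integer(seed))
  child <- sample.int(2147483646L, length(doses))
  lapply(seq_along(doses), function(i) {
    f <- trf_fractions[i]
    lib <- simulate_library(bundle, rel * (1 - f), f, n_reads,
                            adapter = adapter, read_length = read_length,
                            seed = child[i],
                            library_id = sprintf("dose%02d", i), ...)
    lib$truth$dose <- doses[i]
    list(dose = doses[i], reads = lib$reads, truth = lib$truth)
  })
}

#' @rdname simulate_dose_series
#' @export
default_composition <- function() {
  c(miRNA = 0.40, piRNA = 0.05, snoRNA = 0.05, rRNA = 0.10, tRNA = 0.25,
    CDS = 0.025, Promoters = 0.025, `5'UTR` = 0.025, `3'UTR` = 0.025,
    Introns = 0.025, repeats = 0.025)
}

#' Simulate 2x2 study tables for odds-ratio meta-analysis
#'
#' Study `i` draws a true log odds ratio from Normal(`log_or_mean`,
#' `tau^2`), converts the control exposure probability to the case
#' exposure probability through that odds ratio, and samples the table
#' cells binomially: `a`/`b` exposed/unexposed cases, `c`/`d`
#' exposed/unexposed controls.
#'
#' @param k Number of studies (>= 1).
#' @param log_or_mean Mean true log odds ratio.
#' @param tau Between-study standard deviation of the log odds ratio.
#' @param control_risk Exposure probability among controls, in (0, 1).
#' @param group_sizes Per-arm sample size(s), recycled to `k`; >= 10.
#' @param seed Integer seed.
#' @return Data frame: `study_id`, `a`, `b`, `c`, `d`, `true_log_or`.
#' @export
simulate_meta_studies <- function(k, log_or_mean, tau, control_risk,
                                  group_sizes, seed = 1L) {
  stopifnot(k >= 1L, tau >= 0)
  if (control_risk <= 0 || control_risk >= 1) {
    stop("control_risk must lie strictly inside (0, 1)")
  }
  n <- rep_len(as.integer(group_sizes), k)
  if (any(n < 10L)) stop("group sizes must be at least 10")
  set.seed(as.integer(seed))
  theta <- rnorm(k, log_or_mean, tau)
  odds1 <- control_risk / (1 - control_risk) * exp(theta)
  p1 <- odds1 / (1 + odds1)
  a <- rbinom(k, n, p1)
  c_ <- rbinom(k, n, control_risk)
  data.frame(study_id = sprintf("study%02d", seq_len(k)),
             a = a, b = n - a, c = c_, d = n - c_,
             true_log_or = theta, stringsAsFactors = FALSE)
}
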