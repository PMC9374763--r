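#' Quantify tRNA-derived fragments in a trimmed library
#'
#' Counts trimmed reads that place as substrings of any tRNA reference at
#' most `max_mismatches` apart (best-mode, read-level: a read counts once,
#' toward the first best-tied reference). The default bound is 0
#' mismatches, the setting under which the fragment was originally
#' counted. The percent share is computed against the full trimmed
#' library size, which may exceed the number of rows passed in (pass
#' `total_reads` explicitly when quantifying a subset).
#'
#' @param trimmed_reads Sequence record data frame of trimmed inserts
#'   (zero-length inserts are ignored).
#' @param trna_refs Named character vector of tRNA reference sequences.
#' @param max_mismatches Hamming bound (0, 1 or 2).
#' @param total_reads Library-size denominator; defaults to
#'   `nrow(trimmed_reads)`. Must be positive.
#' @param library_id Label carried into the result.
#' @return A list of class `trf_quant`: `library_id`, `total_reads`,
#'   `trf_counts` (per-reference read counts), `matched_reads`,
#'   `trf_percent` (100 x matched / total), `fragment_table` (matched
#'   read sequences with counts, most abundant first), `top_fragment`,
#'   and `k_used`.
#' @export
quantify_fragment <- function(trimmed_reads, trna_refs, max_mismatches = 0L,
                              total_reads = nrow(trimmed_reads),
                              library_id = "library") {
  if (is.null(total_reads) || total_reads == 0L) {
    stop("total_reads must be positive: an empty library has no ",
         "percent scale")
  }
  k <- as.integer(max_mismatches)
  seqs <- toupper(trimmed_reads$seq)
  seqs <- seqs[nzchar(seqs)]
  counts <- stats::setNames(integer(length(trna_refs)), names(trna_refs))
  fragment_table <- data.frame(sequence = character(), count = integer(),
                               stringsAsFactors = FALSE)
  matched <- 0L
  if (length(seqs) > 0L && length(trna_refs) > 0L) {
    trna_refs <- validate_refs(trna_refs)
    uniq <- unique(seqs)
    mult <- as.integer(table(factor(seqs, levels = uniq)))
    best <- best_ref_cpp(uniq, rc_dna(uniq), unname(trna_refs), k, TRUE)
    hit <- best$ref > 0L
    if (any(hit)) {
      per_ref <- tapply(mult[hit],
                        factor(best$ref[hit], levels = seq_along(trna_refs)),
                        sum)
      per_ref[is.na(per_ref)] <- 0L
      counts[] <- as.integer(per_ref)
      matched <- sum(mult[hit])
      fragment_table <- data.frame(sequence = uniq[hit], count = mult[hit],
                                   stringsAsFactors = FALSE)
      fragment_table <- fragment_table[order(-fragment_table$count,
                                             fragment_table$sequence), ,
                                       drop = FALSE]
      rownames(fragment_table) <- NULL
    }
  }
  structure(list(
    library_id = library_id,
    total_reads = as.integer(total_reads),
    trf_counts = counts,
    matched_reads = as.integer(matched),
    trf_percent = 100 * matched / total_reads,
    fragment_table = fragment_table,
    top_fragment = if (nrow(fragment_table) > 0L)
      fragment_table$sequence[1L] else NA_character_,
    k_used = k
  ), class = "trf_quant")
}

#' @export
print.trf_quant <- function(x, ...) {
  cat("tRF quantification for '", x$library_id, "' (k = ", x$k_used,
      "): ", x$matched_reads, "/", x$total_reads, " reads = ",
      sprintf("%.4f", x$trf_percent), "%\n", sep = "")
  if (!is.na(x$top_fragment)) {
    cat("  top fragment: ", x$top_fragment, " (",
        x$fragment_table$count[1L], " reads)\n", sep = "")
  }
  invisible(x)
}

#' Count full-length tRNA transcripts among adapter-free reads
#'
#' Adapter-free reads in the 50-51 nt window are candidates for
#' full-length (or near-full-length) transcripts; each is matched as a
#' substring of the tRNA references (read-level, best mode).
#'
#' @param full_length_reads Sequence records from the full-length bucket
#'   of [partition_library()].
#' @param trna_refs Named character vector of tRNA references.
#' @param max_mismatches Hamming bound, default 1.
#' @return Named integer vector of read counts per reference.
#' @export
quantify_full_length <- function(full_length_reads, trna_refs,
                                 max_mismatches = 1L) {
  if (length(trna_refs) == 0L || nrow(full_length_reads) == 0L) {
    return(stats::setNames(integer(length(trna_refs)), names(trna_refs)))
  }
  count_valid_alignments(full_length_reads, trna_refs,
                         max_mismatches = max_mismatches,
                         mode = "best")$counts
}

#' Read-length profile scaled to reads per million
#'
#' Histogram of insert lengths scaled by 1e6 / `total_reads`, so the RPM
#' column sums to one million when every library read is profiled.
#'
#' @param trimmed_reads Sequence record data frame.
#' @param total_reads Library-size denominator; defaults to the number of
#'   profiled reads and must not be smaller than it.
#' @param library_id Label column value.
#' @return Data frame: `library_id`, `length`, `count`, `rpm`.
#' @export
length_profile <- function(trimmed_reads, total_reads = nrow(trimmed_reads),
                           library_id = "library") {
  n <- nrow(trimmed_reads)
  stopifnot(total_reads >= n)
  if (n == 0L) {
    return(data.frame(library_id = character(), length = integer(),
                      count = integer(), rpm = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(nchar(trimmed_reads$seq))
  data.frame(library_id = library_id,
             length = as.integer(names(tab)),
             count = as.integer(tab),
             rpm = 1e6 * as.integer(tab) / total_reads,
             stringsAsFactors = FALSE)
}

#' Correlate fragment abundance with dose
#'
#' Rank (Spearman, default) or Pearson correlation of the fragment
#' percent share against the dose covariate, with the two-sided p-value
#' from the t approximation on n - 2 degrees of freedom (n >= 4;
#' otherwise p is reported as 1). Accepts a data frame of
#' `(dose, value)` pairs or the two vectors.
#'
#' @param doses Numeric dose values, or a data frame whose first two
#'   columns are dose and value.
#' @param values Fragment percents (or any response), same length.
#' @param method `"spearman"` or `"pearson"`.
#' @return List: `rho`, `p`, `method`, `n`.
#' @export
dose_correlation <- function(doses, values = NULL,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(doses)) {
    values <- doses[[2L]]
    doses <- doses[[1L]]
  }
  stopifnot(length(doses) == length(values), length(doses) >= 2L)
  if (method == "spearman") {
    res <- spearman_rho(doses, values)
    list(rho = res$rho, p = res$p, method = method, n = length(doses))
  } else {
    n <- length(doses)
    r <- cor(doses, values)
    p <- if (n >= 4L && is.finite(r) && abs(r) < 1) {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), n - 2)
    } else if (n >= 4L && is.finite(r)) 0 else 1
    list(rho = r, p = p, method = method, n = n)
  }
}
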