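#' Sequential precedence classification of trimmed reads
#'
#' Library composition profiling with count-and-remove semantics.
#' Zero-length inserts are excluded up front and tallied separately.
#' Step 0 maps every read to the genome (both strands, at most
#' `max_mismatches` mismatches); reads with no genome match are counted
#' as unmapped and removed. Surviving reads are then tested against the
#' categories in database order and each read is assigned to the first
#' category in which it has any valid placement, then removed. Reads
#' surviving every category are the unannotated residual.
#'
#' @param trimmed_reads Sequence record data frame of trimmed inserts.
#' @param db A [category_db()].
#' @param genome Single DNA string containing every reference.
#' @param max_mismatches Hamming bound used for the genome prefilter and
#'   every category step (0, 1 or 2).
#' @return List with `composition` (a `library_composition`: counts and
#'   percent shares) and `assignments` (per-read data frame `read_id`,
#'   `category`, where category is a category name, `"unmapped"`, or
#'   `"unannotated"`).
#' @export
classify_reads <- function(trimmed_reads, db, genome, max_mismatches = 1L) {
  stopifnot(inherits(db, "category_db"), length(db) > 0L,
            is.character(genome), nchar(genome) > 0L,
            max_mismatches %in% 0:2)
  k <- as.integer(max_mismatches)
  seqs <- toupper(trimmed_reads$seq)
  nonempty <- nzchar(seqs)
  dropped <- sum(!nonempty)
  ids <- trimmed_reads$id[nonempty]
  seqs <- seqs[nonempty]
  total <- length(seqs)

  uniq <- unique(seqs)
  assign_u <- rep(NA_character_, length(uniq))
  if (length(uniq) > 0L) {
    uniq_rc <- rc_dna(uniq)
    mapped <- any_hit_cpp(uniq, uniq_rc, genome, k, TRUE)
    assign_u[!mapped] <- "unmapped"
    remaining <- which(mapped)
    for (cat in names(db)) {
      if (length(remaining) == 0L) break
      refs <- db[[cat]]
      if (length(refs) == 0L) next
      hit <- any_hit_cpp(uniq[remaining], uniq_rc[remaining],
                         unname(refs), k, TRUE)
      assign_u[remaining[hit]] <- cat
      remaining <- remaining[!hit]
    }
    assign_u[remaining] <- "unannotated"
  }

  assignment <- assign_u[match(seqs, uniq)]
  counts_all <- table(factor(assignment,
                             levels = c(names(db), "unmapped",
                                        "unannotated")))
  counts <- stats::setNames(as.integer(counts_all[names(db)]), names(db))
  comp <- structure(list(
    total_reads = total,
    dropped_empty = dropped,
    unmapped_to_genome = as.integer(counts_all[["unmapped"]]),
    counts = counts,
    residual_unannotated = as.integer(counts_all[["unannotated"]]),
    max_mismatches = k
  ), class = "library_composition")

  list(composition = comp,
       assignments = data.frame(read_id = ids, category = assignment,
                                stringsAsFactors = FALSE))
}

#' Tabulate a library composition as percent shares
#'
#' One row per category in database order, plus `unmapped` and
#' `unannotated` rows; `percent` is 100 x count / total reads. An empty
#' library reports all percents as 0 and raises a warning (the returned
#' frame carries attribute `zero_library = TRUE`).
#'
#' @param comp A `library_composition` from [classify_reads()].
#' @return Data frame with columns `category`, `count`, `percent`.
#' @export
composition_report <- function(comp) {
  stopifnot(inherits(comp, "library_composition"))
  counts <- c(comp$counts,
              unmapped = comp$unmapped_to_genome,
              unannotated = comp$residual_unannotated)
  zero <- comp$total_reads == 0L
  if (zero) {
    warning("empty library: composition percents reported as 0")
    pct <- rep(0, length(counts))
  } else {
    pct <- 100 * as.numeric(counts) / comp$total_reads
  }
  out <- data.frame(category = names(counts), count = as.integer(counts),
                    percent = pct, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "zero_library") <- zero
  out
}

#' @export
print.library_composition <- function(x, ...) {
  cat("Library composition (", x$total_reads, " reads, k = ",
      x$max_mismatches, "; ", x$dropped_empty, " empty dropped)\n",
      sep = "")
  rep_ <- composition_report(x)
  for (i in seq_len(nrow(rep_))) {
    cat(sprintf("  %-12s %8d  %6.2f%%\n", rep_$category[i], rep_$count[i],
                rep_$percent[i]))
  }
  invisible(x)
}
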