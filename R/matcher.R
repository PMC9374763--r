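#' Mismatch-bounded ungapped matching of a read against reference sequences
#'
#' Places `read` as a substring of each reference (the fragment-in-parent
#' model: a tRF is a subsequence of its tRNA) at Hamming distance at most
#' `max_mismatches`, on the forward strand and, optionally, as its reverse
#' complement ('-' strand). `"all"` returns every placement; `"best"`
#' returns only the placements achieving the minimum mismatch count over
#' all placements, in deterministic tie order: reference input order, then
#' smaller offset, then '+' before '-'. An `N` in the read never matches a
#' reference base, so it is charged as a mismatch at that position.
#'
#' @param read DNA string (length >= 1).
#' @param refs Named character vector of N-free reference DNA strings.
#' @param max_mismatches Maximum Hamming distance (0, 1 or 2).
#' @param mode `"best"` or `"all"`.
#' @param search_reverse_complement Also evaluate the read's reverse
#'   complement ('-' strand hits).
#' @param read_id Id to carry into the result rows.
#' @return Data frame of hits: `read_id`, `ref_id`, `offset` (0-based
#'   start of the read within the reference), `strand`, `mismatches`.
#'   A read longer than every reference yields zero rows.
#' @examples
#' refs <- c(parent = "AAAAGCAGAGTGGCGTTTT")
#' find_matches("AGCAGAGTGGCG", refs, max_mismatches = 0)
#' @export
find_matches <- function(read, refs, max_mismatches = 1L,
                         mode = c("best", "all"),
                         search_reverse_complement = TRUE,
                         read_id = "read") {
  mode <- match.arg(mode)
  stopifnot(is.character(read), length(read) == 1L, nchar(read) >= 1L,
            max_mismatches %in% 0:2)
  refs <- validate_refs(refs)
  read <- toupper(read)
  hits <- hits_one_read_cpp(read, rc_dna(read), unname(refs),
                            as.integer(max_mismatches),
                            isTRUE(search_reverse_complement))
  hits <- as.data.frame(hits)
  out <- data.frame(
    read_id = rep(read_id, nrow(hits)),
    ref_id = names(refs)[hits$ref_idx],
    offset = hits$offset,
    strand = c("+", "-")[hits$strand + 1L],
    mismatches = hits$mismatches,
    stringsAsFactors = FALSE
  )
  if (mode == "best" && nrow(out) > 0L) {
    out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Count valid alignments of a read set against references
#'
#' Read-level counting: each read contributes at most one to
#' `total_matched_reads`. In `"best"` mode a read with tied best hits
#' across references increments only the first tied reference (reference
#' input order, then offset, then '+' before '-'). In `"all"` mode a read
#' increments every reference it places in, so per-reference counts can
#' sum to more than the total.
#'
#' @param reads Sequence record data frame (`id`, `seq`).
#' @param refs Named character vector of reference DNA strings.
#' @param max_mismatches Maximum Hamming distance (0, 1 or 2).
#' @param mode `"best"` or `"all"`.
#' @param search_reverse_complement Also evaluate reverse complements.
#' @return List with `counts` (named integer vector, one per reference),
#'   `total_matched_reads` and `n_reads`.
#' @export
count_valid_alignments <- function(reads, refs, max_mismatches = 1L,
                                   mode = c("best", "all"),
                                   search_reverse_complement = TRUE) {
  mode <- match.arg(mode)
  refs <- validate_refs(refs)
  seqs <- toupper(reads$seq)
  keep <- nzchar(seqs)
  seqs <- seqs[keep]
  counts <- stats::setNames(integer(length(refs)), names(refs))
  if (length(seqs) == 0L) {
    return(list(counts = counts, total_matched_reads = 0L, n_reads = 0L))
  }
  uniq <- unique(seqs)
  mult <- as.integer(table(factor(seqs, levels = uniq)))
  if (mode == "best") {
    best <- best_ref_cpp(uniq, rc_dna(uniq), unname(refs),
                         as.integer(max_mismatches),
                         isTRUE(search_reverse_complement))
    hit <- best$ref > 0L
    if (any(hit)) {
      per_ref <- tapply(mult[hit], factor(best$ref[hit],
                                          levels = seq_along(refs)), sum)
      per_ref[is.na(per_ref)] <- 0L
      counts[] <- as.integer(per_ref)
    }
    total <- sum(mult[hit])
  } else {
    total <- 0L
    for (i in seq_along(uniq)) {
      h <- hits_one_read_cpp(uniq[i], rc_dna(uniq[i]), unname(refs),
                             as.integer(max_mismatches),
                             isTRUE(search_reverse_complement))
      ridx <- unique(h$ref_idx)
      if (length(ridx) > 0L) {
        counts[ridx] <- counts[ridx] + mult[i]
        total <- total + mult[i]
      }
    }
  }
  list(counts = counts, total_matched_reads = as.integer(total),
       n_reads = length(seqs))
}

#' Export alignment hits as a 1-based TSV
#'
#' Internal coordinates are 0-based; reports are 1-based inclusive.
#'
#' @param hits Hit data frame from [find_matches()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hits_to_tsv <- function(hits, path) {
  out <- data.frame(read_id = hits$read_id, ref_id = hits$ref_id,
                    offset_1based = hits$offset + 1L, strand = hits$strand,
                    mismatches = hits$mismatches, stringsAsFactors = FALSE)
  write_table(out, path)
}

# References must be named, unique, non-empty, uppercase DNA without N.
validate_refs <- function(refs) {
  refs <- toupper(refs)
  if (is.null(names(refs)) || any(!nzchar(names(refs))) ||
      anyDuplicated(names(refs))) {
    stop("references must carry unique non-empty names")
  }
  if (any(grepl("[^ACGT]", refs))) {
    stop("reference sequences must be N-free DNA (ACGT only)")
  }
  refs
}
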