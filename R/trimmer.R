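#' Trim 3' adapter read-through from a single read
#'
#' Small-RNA inserts are shorter than the 50-cycle read, so sequencing
#' runs through the insert into the 3' adapter. The scan finds the
#' leftmost offset at which a prefix of the adapter, at least
#' `min_overlap` nt long (shorter only because the read ends), aligns
#' ungapped with a mismatch fraction at most `max_error_rate`; everything
#' from that offset on is removed. No acceptable offset is a valid
#' result, not an error: the read is returned untouched.
#'
#' @param read A single-row sequence record data frame, or a list/row with
#'   `id` and `seq`.
#' @param adapter Non-empty adapter DNA string.
#' @param min_overlap Minimum adapter prefix length considered.
#' @param max_error_rate Maximum mismatches/overlap-length fraction.
#' @return A list of class `trim_result`: `read_id`, `insert`,
#'   `adapter_found`, `adapter_start` (0-based offset, `NA` when not
#'   found) and `n_adapter_errors`.
#' @examples
#' r <- seq_records("r1", paste0("ACGTACGTACGTACGTACGTAC", default_adapter()))
#' trim_read_3prime(r, default_adapter())
#' @export
trim_read_3prime <- function(read, adapter, min_overlap = 3L,
                             max_error_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1L)
  id <- as.character(read$id)[1L]
  seq <- toupper(as.character(read$seq)[1L])
  scan <- trim_scan_cpp(seq, toupper(adapter), as.integer(min_overlap),
                        max_error_rate)
  found <- !is.na(scan$start[1L])
  structure(list(
    read_id = id,
    insert = if (found) substr(seq, 1L, scan$start[1L]) else seq,
    adapter_found = found,
    adapter_start = if (found) as.integer(scan$start[1L]) else NA_integer_,
    n_adapter_errors = if (found) as.integer(scan$errors[1L]) else NA_integer_
  ), class = "trim_result")
}

#' Partition a library into trimmed inserts and full-length candidates
#'
#' Reads in which the adapter is found are trimmed and become small-RNA
#' inserts (an adapter at offset 0 leaves a zero-length insert, which is
#' retained here and excluded from downstream matching). Adapter-free
#' reads whose original length falls inside `full_length_window` are
#' full-length transcript candidates; adapter-free reads outside the
#' window are tallied as discarded and routed to neither output.
#'
#' @param reads Sequence record data frame.
#' @param adapter Adapter DNA string.
#' @param min_overlap,max_error_rate Passed to the adapter scan, see
#'   [trim_read_3prime()].
#' @param full_length_window Length-2 integer vector `(min, max)` in nt.
#' @return A list of class `partition` with `trimmed` (sequence records of
#'   inserts, plus columns `adapter_start`, `n_adapter_errors`),
#'   `full_length` (untouched sequence records), and the conservation
#'   tallies `n_input`, `n_trimmed`, `n_full_length`, `n_discarded`.
#' @export
partition_library <- function(reads, adapter, min_overlap = 3L,
                              max_error_rate = 0.1,
                              full_length_window = c(50L, 51L)) {
  stopifnot(length(full_length_window) == 2L,
            full_length_window[1L] <= full_length_window[2L],
            nchar(adapter) >= 1L)
  seqs <- toupper(reads$seq)
  scan <- trim_scan_cpp(seqs, toupper(adapter), as.integer(min_overlap),
                        max_error_rate)
  found <- !is.na(scan$start)
  len <- nchar(seqs)
  full <- !found & len >= full_length_window[1L] & len <= full_length_window[2L]
  disc <- !found & !full

  trimmed <- reads[found, , drop = FALSE]
  st <- scan$start[found]
  trimmed$seq <- substr(seqs[found], 1L, st)
  if (!is.null(trimmed$qual)) {
    trimmed$qual <- ifelse(is.na(trimmed$qual), NA_character_,
                           substr(trimmed$qual, 1L, st))
  }
  trimmed$adapter_start <- as.integer(st)
  trimmed$n_adapter_errors <- as.integer(scan$errors[found])
  rownames(trimmed) <- NULL

  full_length <- reads[full, , drop = FALSE]
  rownames(full_length) <- NULL

  structure(list(
    trimmed = trimmed,
    full_length = full_length,
    n_input = length(seqs),
    n_trimmed = sum(found),
    n_full_length = sum(full),
    n_discarded = sum(disc)
  ), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Library partition: ", x$n_input, " reads -> ", x$n_trimmed,
      " trimmed, ", x$n_full_length, " full-length candidates, ",
      x$n_discarded, " discarded\n", sep = "")
  invisible(x)
}
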