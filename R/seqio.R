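#' Sequence record collections
#'
#' A collection of sequencing reads or reference sequences is represented
#' as a plain data frame with columns `id`, `seq` and `qual` (`NA` when no
#' quality is attached, e.g. for FASTA input). Sequences are uppercased on
#' construction; ids are kept verbatim. A record may use the DNA alphabet
#' (ACGTN) or the RNA alphabet (ACGUN) but never both T and U at once.
#'
#' @param id Character vector of non-empty record ids.
#' @param seq Character vector of sequences (IUPAC DNA or RNA; `N` allowed).
#' @param qual Optional character vector of Phred+33 quality strings, each
#'   the same length as its sequence, or `NA`.
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @examples
#' seq_records(c("r1", "r2"), c("ACGT", "acgu"))
#' @export
seq_records <- function(id, seq, qual = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  qual <- as.character(qual)
  if (length(qual) == 1L) qual <- rep(qual, length(seq))
  stopifnot(length(id) == length(seq), length(qual) == length(seq))
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("record ids must be non-empty strings")
  }
  bad <- grepl("[^ACGTUN]", seq)
  if (any(bad)) {
    stop("invalid sequence characters in record(s): ",
         paste(utils::head(id[bad], 5L), collapse = ", "))
  }
  mixed <- grepl("T", seq, fixed = TRUE) & grepl("U", seq, fixed = TRUE)
  if (any(mixed)) {
    stop("record(s) mix T and U in one sequence: ",
         paste(utils::head(id[mixed], 5L), collapse = ", "))
  }
  qlen_bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(qlen_bad)) {
    stop("quality length differs from sequence length for record(s): ",
         paste(utils::head(id[qlen_bad], 5L), collapse = ", "))
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record FASTQ (Sanger/Phred+33). Records are returned
#' in file order; the leading `@` and `+` are stripped; sequences are
#' uppercased.
#'
#' @param path Path to an existing FASTQ file.
#' @return A sequence record data frame (see [seq_records()]).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(seq_records(character(), character()))
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record: file has ", n,
         " lines, not a multiple of 4 (last complete record ends at line ",
         4L * (n %/% 4L), ")")
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    bad <- idx[substr(hdr, 1L, 1L) != "@"][1L]
    stop("malformed FASTQ: line ", bad, " does not start with '@'")
  }
  plus <- lines[idx + 2L]
  if (any(substr(plus, 1L, 1L) != "+")) {
    bad <- (idx + 2L)[substr(plus, 1L, 1L) != "+"][1L]
    stop("malformed FASTQ: line ", bad, " does not start with '+'")
  }
  seq <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  if (any(nchar(qual) != nchar(seq))) {
    bad <- idx[nchar(qual) != nchar(seq)][1L]
    stop("malformed FASTQ: quality length differs from sequence length ",
         "in the record starting at line ", bad)
  }
  seq_records(sub("^@", "", hdr), seq, qual)
}

#' Write a FASTQ file
#'
#' @param records Sequence record data frame. Records without quality get a
#'   constant `'I'` quality string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  fill <- is.na(qual)
  if (any(fill)) qual[fill] <- strrep("I", nchar(records$seq[fill]))
  out <- character(4L * nrow(records))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", records$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- records$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a multi-FASTA file
#'
#' Wrapped sequence lines are concatenated; ids are taken up to the first
#' whitespace; sequences are uppercased.
#'
#' @param path Path to an existing FASTA file.
#' @return A sequence record data frame with `qual = NA`.
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(seq_records(character(), character()))
  if (substr(first, 1L, 1L) != ">") {
    stop("malformed FASTA: sequence line before any '>' header (line 1)")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set))
}

#' Write a multi-FASTA file
#'
#' @param records Sequence record data frame.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write records as a tab-separated table
#'
#' Header row plus one line per record, tab-delimited, columns in
#' declaration order, UTF-8 with LF endings. Accepts a data frame or a
#' list of identically named lists (heterogeneous field sets are a schema
#' error).
#'
#' @param rows Data frame, or list of named lists sharing one field set.
#' @param path Output path.
#' @param format Only `"tsv"` is supported.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = "tsv") {
  format <- match.arg(format, "tsv")
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("rows must be a data frame or list of records")
    fields <- lapply(rows, names)
    if (length(rows) > 0L) {
      ok <- vapply(fields, identical, logical(1L), y = fields[[1L]])
      if (!all(ok)) {
        stop("schema error: records do not share one field set (record ",
             which(!ok)[1L], " differs)")
      }
    }
    rows <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#'
#' All values are returned as character strings, so a write/read
#' round-trip reproduces the table as printed.
#'
#' @param path Path to a TSV file with a header row.
#' @return A character data frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", colClasses = "character",
             check.names = FALSE, stringsAsFactors = FALSE)
}
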