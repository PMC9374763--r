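#' Reverse complement of DNA or RNA sequences
#'
#' Standard Watson-Crick complement, reversed. The alphabet of each input
#' is preserved: RNA in (any U, no T) gives RNA out; everything else is
#' treated as DNA. `N` complements to `N`.
#'
#' @param seq Character vector of sequences (uppercased internally).
#' @return Character vector of reverse complements, same alphabet.
#' @examples
#' reverse_complement("AGCAGAGUGG") # "CCACUCUGCU"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTUN]", seq))) stop("invalid sequence alphabet")
  is_rna <- grepl("U", seq, fixed = TRUE) & !grepl("T", seq, fixed = TRUE)
  comp <- ifelse(is_rna,
                 chartr("ACGUN", "UGCAN", seq),
                 chartr("ACGTN", "TGCAN", seq))
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Fast internal reverse complement for large DNA read vectors ('N' allowed).
rc_dna <- function(seq) {
  if (length(seq) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Find contiguous complementary duplex sites
#'
#' Scans a small RNA (the query) against a target sequence for all maximal
#' contiguous, perfectly complementary antiparallel stretches of at least
#' `min_length` bases -- the simplest model of a small-RNA binding site.
#' "Maximal" means the pairing can be extended in neither direction.
#' Comparisons internally map U to T, so RNA and DNA inputs mix freely;
#' reported `target_site` strings keep the caller's target alphabet.
#'
#' @param small_rna Query sequence (RNA or DNA string).
#' @param target Target sequence (e.g. a 3'UTR or reporter top strand).
#' @param min_length Minimum duplex length in nt to report.
#' @param allow_gu Also accept G:U wobble pairs.
#' @return Data frame sorted by length (descending) then target position,
#'   with 1-based inclusive coordinates: `query_start`, `query_end`,
#'   `target_start`, `target_end`, `length`, `target_site`.
#' @examples
#' sites <- find_duplex_sites(
#'   trimet_sequences()[["trf31_rna"]],
#'   trimet_sequences()[["reporter_wt1"]]
#' )
#' sites[1, ]
#' @export
find_duplex_sites <- function(small_rna, target, min_length = 8L,
                              allow_gu = FALSE) {
  stopifnot(nchar(small_rna) > 0L, nchar(target) > 0L)
  q <- strsplit(chartr("U", "T", toupper(small_rna)), "")[[1L]]
  t_fwd <- strsplit(chartr("U", "T", toupper(target)), "")[[1L]]
  n <- length(q)
  m <- length(t_fwd)
  tr <- rev(t_fwd) # tr[j] is target position m - j + 1
  pair <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "C" & y == "G") | (x == "G" & y == "C")
    if (allow_gu) wc | (x == "G" & y == "T") | (x == "T" & y == "G") else wc
  }
  # run[i, j]: length of the consecutive paired diagonal ending at (q[i], tr[j])
  run <- matrix(0L, n + 1L, m + 1L)
  P <- outer(q, tr, pair)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (P[i, j]) run[i + 1L, j + 1L] <- run[i, j] + 1L
    }
  }
  hits <- which(run >= min_length, arr.ind = TRUE)
  out <- data.frame(query_start = integer(), query_end = integer(),
                    target_start = integer(), target_end = integer(),
                    length = integer(), target_site = character(),
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    i <- hits[, 1L] - 1L
    j <- hits[, 2L] - 1L
    L <- run[hits]
    # right-maximal: the diagonal stops at (i, j)
    keep <- i == n | j == m
    ext <- !keep
    if (any(ext)) keep[ext] <- !P[cbind(i[ext] + 1L, j[ext] + 1L)]
    i <- i[keep]; j <- j[keep]; L <- L[keep]
    out <- data.frame(
      query_start = i - L + 1L,
      query_end = i,
      target_start = m - j + 1L,
      target_end = m - j + L,
      length = L,
      stringsAsFactors = FALSE
    )
    out$target_site <- substring(toupper(target), out$target_start,
                                 out$target_end)
    out <- out[order(-out$length, out$target_start, out$query_start), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Derive and validate a luciferase reporter insert from a cloning oligo pair
#'
#' The reporter inserts are synthesized as two phosphorylated oligos that
#' anneal into a duplex with an XbaI-compatible `CTAG` 5' overhang on the
#' top strand and an EcoRI-compatible `AATT` 5' overhang on the bottom
#' strand. This checks both overhangs and the annealing (after removing the
#' 4-nt overhangs the strands must be exact reverse complements) and
#' returns the top-strand insert.
#'
#' @param oligo_top Top-strand oligo (5'->3', DNA).
#' @param oligo_bottom Bottom-strand oligo (5'->3', DNA).
#' @param name Optional insert name carried through to the result.
#' @return A list of class `reporter_insert` with elements `name`,
#'   `top_strand` (insert between the cloning sites), `overhang_5`
#'   (`"CTAG"`) and `overhang_3` (`"AATT"`).
#' @examples
#' oligos <- trimet_sequences()
#' derive_reporter_inserts(oligos[["reporter_wt1"]], oligos[["reporter_wt2"]])
#' @export
derive_reporter_inserts <- function(oligo_top, oligo_bottom, name = "insert") {
  oligo_top <- toupper(oligo_top)
  oligo_bottom <- toupper(oligo_bottom)
  stopifnot(nchar(oligo_top) >= 10L, nchar(oligo_bottom) >= 10L)
  if (substr(oligo_top, 1L, 4L) != "CTAG") {
    stop("top oligo does not carry the XbaI 'CTAG' 5' overhang")
  }
  if (substr(oligo_bottom, 1L, 4L) != "AATT") {
    stop("bottom oligo does not carry the EcoRI 'AATT' 5' overhang")
  }
  core_top <- substr(oligo_top, 5L, nchar(oligo_top))
  core_bottom <- substr(oligo_bottom, 5L, nchar(oligo_bottom))
  expect <- reverse_complement(core_bottom)
  if (nchar(expect) != nchar(core_top)) {
    stop("oligos are incompatible: annealed strand lengths differ (",
         nchar(core_top), " vs ", nchar(expect), " nt after overhangs)")
  }
  same <- strsplit(core_top, "")[[1L]] == strsplit(expect, "")[[1L]]
  if (!all(same)) {
    stop("oligos are incompatible: first mismatching duplex position ",
         which(!same)[1L], " (top strand, after the overhang)")
  }
  structure(list(name = name, top_strand = core_top,
                 overhang_5 = "CTAG", overhang_3 = "AATT"),
            class = "reporter_insert")
}

#' @export
print.reporter_insert <- function(x, ...) {
  cat("Reporter insert '", x$name, "' (", nchar(x$top_strand), " nt)\n",
      "  5' overhang: ", x$overhang_5, "   3' partner overhang: ",
      x$overhang_3, "\n  top strand: ", x$top_strand, "\n", sep = "")
  invisible(x)
}

#' Check the provenance of a synthesized oligo against its parent sequence
#'
#' Assay oligos are typically a stretch of their parent sequence plus a
#' synthesis decoration: a 3' poly(A) tail (poly(A)-tailing qPCR primers)
#' or a 3' UU/dTdT overhang (siRNA strands), or nothing. This strips each
#' permitted decoration in turn, looks the remaining core up in the parent
#' (after mapping U to T on both sides), and reports the best (longest
#' core) interpretation.
#'
#' @param oligo Oligo sequence (RNA or DNA).
#' @param parent Parent sequence the oligo was designed from.
#' @param allowed_decorations Subset of `c("none", "UU_overhang",
#'   "polyA_tail")` to consider.
#' @return A list with `decoration`, `core` (normalized to DNA),
#'   `decoration_seq`, `parent_start`, `parent_end` (1-based inclusive)
#'   and `matched_length`. Errors if no permitted interpretation places
#'   the core inside the parent.
#' @examples
#' oligos <- trimet_sequences()
#' check_oligo_provenance(oligos[["timetf_sp"]], oligos[["trf31_dna"]],
#'                        allowed_decorations = "polyA_tail")
#' @export
check_oligo_provenance <- function(oligo, parent,
                                   allowed_decorations = c("none",
                                                           "UU_overhang",
                                                           "polyA_tail")) {
  allowed_decorations <- match.arg(allowed_decorations, several.ok = TRUE)
  o <- chartr("U", "T", toupper(oligo))
  p <- chartr("U", "T", toupper(parent))
  if (grepl("[^ACGTN]", o) || grepl("[^ACGTN]", p)) {
    stop("invalid sequence alphabet")
  }
  candidates <- list()
  for (dec in allowed_decorations) {
    core <- switch(dec,
      none = o,
      UU_overhang = if (endsWith(o, "TT")) substr(o, 1L, nchar(o) - 2L),
      polyA_tail = if (endsWith(o, "A")) sub("A+$", "", o)
    )
    if (is.null(core) || !nzchar(core)) next
    at <- regexpr(core, p, fixed = TRUE)
    if (at > 0L) {
      candidates[[dec]] <- list(
        decoration = dec,
        core = core,
        decoration_seq = substr(o, nchar(core) + 1L, nchar(o)),
        parent_start = as.integer(at),
        parent_end = as.integer(at) + nchar(core) - 1L,
        matched_length = nchar(core)
      )
    }
  }
  if (length(candidates) == 0L) {
    stop("oligo has no permitted suffix/substring relationship ",
         "with the parent sequence")
  }
  lens <- vapply(candidates, `[[`, integer(1L), "matched_length")
  candidates[[which.max(lens)]]
}
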