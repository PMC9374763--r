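# Independent reference implementations used as oracles. These stay in
# plain vectorized R, on a different code path from the package internals.

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# All-offsets Hamming scan, emitting hits in the matcher's documented tie
# order (reference input order, offset, '+' before '-').
oracle_hits <- function(read, refs, k, both = TRUE) {
  rl <- nchar(read)
  rch <- strsplit(read, "")[[1L]]
  rcch <- strsplit(oracle_rc(read), "")[[1L]]
  rows <- list()
  for (ri in seq_along(refs)) {
    refch <- strsplit(refs[[ri]], "")[[1L]]
    L <- length(refch)
    if (rl > L || rl == 0L) next
    for (off in 0:(L - rl)) {
      win <- refch[(off + 1L):(off + rl)]
      mm <- sum(rch != win)
      if (mm <= k) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = names(refs)[ri], offset = off, strand = "+",
          mismatches = mm, stringsAsFactors = FALSE)
      }
      if (both) {
        mm2 <- sum(rcch != win)
        if (mm2 <= k) {
          rows[[length(rows) + 1L]] <- data.frame(
            ref_id = names(refs)[ri], offset = off, strand = "-",
            mismatches = mm2, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(ref_id = character(), offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Leftmost acceptable adapter offset, per the documented trimming rule.
oracle_trim <- function(seq, adapter, min_overlap = 3L,
                        max_error_rate = 0.1) {
  rl <- nchar(seq)
  alen <- nchar(adapter)
  sch <- strsplit(seq, "")[[1L]]
  ach <- strsplit(adapter, "")[[1L]]
  for (p in 0:(rl - min_overlap)) {
    L <- min(alen, rl - p)
    if (L < min_overlap) break
    mm <- sum(sch[(p + 1L):(p + L)] != ach[1:L])
    if (mm / L <= max_error_rate + 1e-12) {
      return(list(start = p, errors = mm))
    }
  }
  list(start = NA_integer_, errors = NA_integer_)
}

# Brute-force enumeration of all maximal perfectly complementary
# antiparallel stretches >= min_length between query and target.
oracle_duplex <- function(query, target, min_length = 8L) {
  q <- chartr("U", "T", toupper(query))
  t_ <- chartr("U", "T", toupper(target))
  n <- nchar(q)
  m <- nchar(t_)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  qch <- strsplit(q, "")[[1L]]
  tch <- strsplit(t_, "")[[1L]]
  pair <- function(i, j) !is.na(comp[qch[i]]) && comp[qch[i]] == tch[j]
  rows <- list()
  for (qs in 1:n) for (ts in 1:m) {
    # stretch starting at query qs pairing target position ts downward
    L <- 0L
    while (qs + L <= n && ts - L >= 1L && pair(qs + L, ts - L)) L <- L + 1L
    if (L < min_length) next
    # maximal: not extendable left (query) / right (target)
    if (qs > 1L && ts < m && pair(qs - 1L, ts + 1L)) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_start = qs, query_end = qs + L - 1L,
      target_start = ts - L + 1L, target_end = ts, length = L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(query_start = integer(), query_end = integer(),
                      target_start = integer(), target_end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, out$target_start, out$query_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

tiny_db <- function() {
  category_db(list(
    miRNA = c(mir1 = "ACGTACGTACGTACGTACGTAC", mir2 = "TTGGCCAATTGGCCAATTGGCC"),
    tRNA = c(trna1 = paste0("GGG", "ACGTACGTACGTACGTACGTAC", "CCCTTTAAACCCGGGTTTAAA"),
             trna2 = "CATCATCATCATCATCATCATCATCATCATCAT")
  ))
}
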