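oligos <- trimet_sequences()

test_that("reverse complement preserves alphabet and is an involution", {
  expect_equal(reverse_complement(oligos[["fish_probe"]]),
               "GCCCATAACCCAGAGGTCGATGGATCGAAACC")
  expect_equal(reverse_complement("A"), "T")
  expect_equal(reverse_complement("AU"), "AU") # RNA in, RNA out
  expect_equal(reverse_complement("ACGUN"), "NACGU")
  set.seed(59)
  for (i in 1:25) {
    x <- random_dna_str(sample(5:60, 1))
    expect_equal(reverse_complement(reverse_complement(x)), x)
    # cross-check against Biostrings on the DNA alphabet
    expect_equal(reverse_complement(x),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(x))))
  }
  expect_error(reverse_complement("ACGX"), "alphabet")
})

test_that("the fragment pairs the wild-type reporter at a maximal 10-bp site", {
  sites <- find_duplex_sites(oligos[["trf31_rna"]], oligos[["reporter_wt1"]])
  expect_gte(nrow(sites), 1L)
  top <- sites[1, ]
  expect_equal(top$length, 10L)
  expect_equal(top$query_start, 1L)
  expect_equal(top$query_end, 10L)
  expect_equal(top$target_site, "CCACTCTGCT")
  # complementarity invariant, re-verified through reverse_complement
  expect_equal(reverse_complement(chartr("T", "U", top$target_site)),
               substr(oligos[["trf31_rna"]], top$query_start, top$query_end))

  # the deletion mutant and the scrambled control have no site >= 8
  expect_equal(nrow(find_duplex_sites(oligos[["trf31_rna"]],
                                      oligos[["reporter_mt1"]])), 0L)
  expect_equal(nrow(find_duplex_sites(oligos[["scr_rna"]],
                                      oligos[["reporter_wt1"]])), 0L)

  # a query against its own reverse complement pairs end to end
  q <- "AGCAGAGUGGCG"
  self <- find_duplex_sites(q, reverse_complement(q), min_length = 8)
  expect_equal(nrow(self), 1L)
  expect_equal(self$length, nchar(q))
})

test_that("duplex scanning equals the brute-force enumeration on random pairs", {
  set.seed(61)
  for (i in 1:30) {
    q <- random_dna_str(sample(12:40, 1))
    t_ <- if (runif(1) < 0.6) {
      # embed a complementary stretch so sites exist
      site <- reverse_complement(substr(q, 3, 3 + sample(7:12, 1)))
      paste0(random_dna_str(sample(5:30, 1)), site,
             random_dna_str(sample(5:30, 1)))
    } else {
      random_dna_str(sample(20:80, 1))
    }
    min_len <- sample(6:9, 1)
    got <- find_duplex_sites(q, t_, min_length = min_len)
    want <- oracle_duplex(q, t_, min_length = min_len)
    expect_equal(got[c("query_start", "query_end", "target_start",
                       "target_end", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("G:U wobble pairing extends sites only when enabled", {
  # query GGGGGG pairs target TTTTTT only under wobble rules
  expect_equal(nrow(find_duplex_sites("GGGGGG", "TTTTTT", min_length = 6)),
               0L)
  gu <- find_duplex_sites("GGGGGG", "TTTTTT", min_length = 6,
                          allow_gu = TRUE)
  expect_equal(nrow(gu), 1L)
  expect_equal(gu$length, 6L)
})

test_that("printed reporter oligo pairs anneal and differ by the 9-nt deletion", {
  wt <- derive_reporter_inserts(oligos[["reporter_wt1"]],
                                oligos[["reporter_wt2"]], name = "WT")
  mt <- derive_reporter_inserts(oligos[["reporter_mt1"]],
                                oligos[["reporter_mt2"]], name = "MT")
  expect_s3_class(wt, "reporter_insert")
  expect_equal(wt$overhang_5, "CTAG")
  expect_equal(wt$overhang_3, "AATT")

  # WT - MT is a single 9-nt deletion of the binding site core
  w <- wt$top_strand
  m <- mt$top_strand
  expect_equal(nchar(w) - nchar(m), 9L)
  i <- 1L
  while (substr(w, i, i) == substr(m, i, i)) i <- i + 1L
  expect_equal(substr(w, i, i + 8L), "CCACTCTGC")
  expect_equal(substr(w, i + 9L, nchar(w)), substr(m, i, nchar(m)))

  # mixed pair cannot anneal
  expect_error(derive_reporter_inserts(oligos[["reporter_wt1"]],
                                       oligos[["reporter_mt2"]]),
               "incompatible")
  # corrupted base is reported by duplex position
  bad <- oligos[["reporter_wt2"]]
  substr(bad, 10, 10) <- "C"
  expect_error(derive_reporter_inserts(oligos[["reporter_wt1"]], bad),
               "position")
})

test_that("printed assay oligos trace back to their parents exactly", {
  trf_dna <- oligos[["trf31_dna"]]
  sp <- check_oligo_provenance(oligos[["timetf_sp"]], trf_dna)
  expect_equal(sp$decoration, "polyA_tail")
  expect_equal(sp$parent_start, 19L)
  expect_equal(sp$parent_end, 31L)
  expect_equal(sp$core, "AAGCGTGCTGGGC")

  si2 <- check_oligo_provenance(oligos[["sirna2_sense"]], trf_dna)
  expect_equal(si2$decoration, "UU_overhang")
  expect_equal(si2$parent_start, 3L)
  expect_equal(si2$parent_end, 21L)

  unir <- check_oligo_provenance(oligos[["rtq_unir"]],
                                 oligos[["rtq_primer"]])
  expect_equal(unir$decoration, "none")
  expect_equal(unir$parent_start, 1L)
  expect_equal(unir$parent_end, 23L)
  expect_equal(unir$matched_length, 23L)

  expect_error(check_oligo_provenance("GGGGCCCCGGGG", trf_dna),
               "no permitted")
})
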