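test_that("reference bundles are deterministic and carry the tRNA-iMet-like reference", {
  b1 <- build_reference_bundle(seed = 1)
  b2 <- build_reference_bundle(seed = 1)
  expect_identical(b1, b2)

  oligos <- trimet_sequences()
  # printed fragment (31) + rc(printed probe) (32) + fixed 10-nt tail
  expect_equal(nchar(b1$trna_imet_like), 73L)
  expect_identical(substr(b1$trna_imet_like, 1, 31), oligos[["trf31_dna"]])
  expect_true(grepl(reverse_complement(oligos[["fish_probe"]]),
                    b1$trna_imet_like, fixed = TRUE))
  expect_identical(b1$categories[["tRNA"]][["tRNA_iMet_like"]],
                   b1$trna_imet_like)

  # every category sequence occurs in the genome
  for (cat in names(b1$categories)) {
    for (s in b1$categories[[cat]]) {
      expect_true(grepl(s, b1$genome, fixed = TRUE))
    }
  }
})

test_that("a zero-count category is empty but present", {
  n <- default_n_per_category()
  n[["miRNA"]] <- 0L
  b <- build_reference_bundle(seed = 3, n_per_category = n)
  expect_true("miRNA" %in% names(b$categories))
  expect_length(b$categories[["miRNA"]], 0L)
})

test_that("simulated libraries respect composition, adapter layout and ground truth", {
  b <- build_reference_bundle(seed = 1)
  comp <- default_composition() * (1 - 0.01)
  lib <- simulate_library(b, comp, trf_fraction = 0.01, n_reads = 1000,
                          seed = 5)
  expect_equal(nrow(lib$truth$reads), 1000L)
  expect_equal(nrow(lib$reads), 1000L)
  expect_true(all(nchar(lib$reads$seq) == 50L))

  # realized fragment count within the Binomial(1000, 0.01) 99.9% interval
  n_trf <- sum(lib$truth$reads$is_trf)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 1000, 0.01)
  expect_gte(n_trf, bounds[1])
  expect_lte(n_trf, bounds[2])

  # every short-insert read carries the adapter's 3-nt prefix at the boundary
  tr <- lib$truth$reads
  short <- tr$insert_len < 50L
  boundary <- substr(lib$reads$seq[short], tr$insert_len[short] + 1L,
                     tr$insert_len[short] + 3L)
  expect_true(all(boundary == substr(default_adapter(), 1, 3)))

  # fragment reads: 31-nt insert + first 19 adapter bases fills 50 cycles
  pure <- simulate_library(b, c(miRNA = 0), trf_fraction = 1, n_reads = 5,
                           seed = 9)
  expect_true(all(pure$reads$seq ==
    paste0(trimet_sequences()[["trf31_dna"]],
           substr(default_adapter(), 1, 19))))

  # full-length tRNA inserts leave no adapter in the read
  fl <- simulate_library(b, c(tRNA = 1), trf_fraction = 0, n_reads = 30,
                         seed = 10, full_length_fraction = 1)
  expect_true(all(fl$truth$reads$insert_len >= 50L))
  part <- partition_library(fl$reads, default_adapter())
  expect_equal(part$n_full_length, 30L)

  expect_error(simulate_library(b, c(miRNA = -0.5, tRNA = 1.5), 0, 10),
               "non-negative")
  expect_error(simulate_library(b, c(miRNA = 0.5), 0.1, 10), "sum to 1")
})

test_that("ground-truth category shares converge to the requested composition", {
  b <- build_reference_bundle(seed = 1)
  comp <- default_composition()
  lib <- simulate_library(b, comp, trf_fraction = 0, n_reads = 100000,
                          seed = 21)
  counts <- table(factor(lib$truth$reads$category, levels = names(comp)))
  # joint multinomial agreement: eleven simultaneous 3-sigma bounds would
  # reject ~3% of healthy seeds, so the convergence claim is tested with
  # the chi-squared goodness-of-fit statistic instead
  gof <- suppressWarnings(stats::chisq.test(as.integer(counts),
                                            p = unname(comp)))
  expect_gt(gof$p.value, 0.001)
  # and the worst single category sits within 4 sigma
  z <- (as.integer(counts) / 100000 - comp) /
    sqrt(comp * (1 - comp) / 100000)
  expect_lt(max(abs(z)), 4)
})

test_that("dose series hold composition constant and validate input", {
  b <- build_reference_bundle(seed = 1)
  expect_error(simulate_dose_series(b, c(0, 1), c(0.01), 100),
               "same length")
  expect_error(simulate_dose_series(b, c(0, 1), c(0.02, 0.01), 100),
               "non-decreasing")

  one <- simulate_dose_series(b, 0.5, 0.01, 100, seed = 2)
  expect_length(one, 1L)

  series <- simulate_dose_series(b, c(0, 0.5, 1), c(0.005, 0.02, 0.05),
                                 2000, seed = 2)
  intended <- vapply(series, function(s) s$truth$intended_trf_fraction,
                     numeric(1L))
  expect_identical(intended, c(0.005, 0.02, 0.05))
  # identical seeds reproduce the series
  series2 <- simulate_dose_series(b, c(0, 0.5, 1), c(0.005, 0.02, 0.05),
                                  2000, seed = 2)
  expect_identical(series, series2)
})

test_that("simulated meta-analysis study sets recover the mean log odds ratio", {
  s <- simulate_meta_studies(k = 20, log_or_mean = 0.7, tau = 0,
                             control_risk = 0.3, group_sizes = 500,
                             seed = 31)
  expect_equal(nrow(s), 20L)
  est <- study_odds_ratio(s$a, s$b, s$c, s$d)
  se_mean <- sqrt(sum(est$se_log_or^2)) / 20
  expect_lt(abs(mean(est$log_or) - 0.7), 3 * se_mean)

  expect_equal(nrow(simulate_meta_studies(1, 0, 0, 0.2, 50, seed = 1)), 1L)
  expect_identical(simulate_meta_studies(5, 0.3, 0.1, 0.2, 100, seed = 7),
                   simulate_meta_studies(5, 0.3, 0.1, 0.2, 100, seed = 7))
  expect_error(simulate_meta_studies(3, 0, 0, 1.2, 50), "strictly inside")
  expect_error(simulate_meta_studies(3, 0, 0, 0.3, 5), "at least 10")
})
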