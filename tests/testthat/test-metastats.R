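test_that("study odds ratios follow the 2x2 formula with Haldane correction", {
  est <- study_odds_ratio(20, 80, 10, 90)
  expect_equal(est$or, 2.25)
  expect_equal(est$se_log_or, sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90))
  expect_equal(est$ci_low, exp(log(2.25) - 1.96 * est$se_log_or))
  expect_true(est$ci_low <= est$or && est$or <= est$ci_high)

  # a.d == b.c gives OR 1
  expect_equal(study_odds_ratio(12, 24, 6, 12)$or, 1)

  # zero cell: computed on (0.5, 10.5, 5.5, 5.5)
  z <- study_odds_ratio(0, 10, 5, 5)
  expect_true(z$corrected)
  expect_equal(z$or, (0.5 * 5.5) / (10.5 * 5.5))
  expect_equal(z$se_log_or, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5))

  expect_error(study_odds_ratio(0, 0, 5, 5), "degenerate")
  expect_error(study_odds_ratio(-1, 5, 5, 5), "non-negative")
})

test_that("heterogeneity statistics match a spreadsheet-style computation", {
  # identical studies carry no heterogeneity
  same <- data.frame(a = c(20, 20, 20), b = c(80, 80, 80),
                     c = c(10, 10, 10), d = c(90, 90, 90))
  het <- heterogeneity(same)
  expect_equal(het$Q, 0)
  expect_equal(het$I2, 0)
  expect_equal(het$tau2, 0)

  # single study by definition
  one <- heterogeneity(data.frame(a = 5, b = 5, c = 5, d = 5))
  expect_equal(one$df, 0L)
  expect_equal(one$I2, 0)

  # two hand-specified studies, worked through the formulas step by step
  two <- data.frame(a = c(30, 10), b = c(70, 90), c = c(15, 30),
                    d = c(85, 70))
  y1 <- log((30 * 85) / (70 * 15)); v1 <- 1 / 30 + 1 / 70 + 1 / 15 + 1 / 85
  y2 <- log((10 * 70) / (90 * 30)); v2 <- 1 / 10 + 1 / 90 + 1 / 30 + 1 / 70
  w1 <- 1 / v1; w2 <- 1 / v2
  yhat <- (w1 * y1 + w2 * y2) / (w1 + w2)
  Q <- w1 * (y1 - yhat)^2 + w2 * (y2 - yhat)^2
  C <- (w1 + w2) - (w1^2 + w2^2) / (w1 + w2)
  het2 <- heterogeneity(two)
  expect_equal(het2$Q, Q)
  expect_equal(het2$df, 1L)
  expect_equal(het2$I2, max(0, (Q - 1) / Q) * 100)
  expect_equal(het2$tau2, max(0, (Q - 1) / C))
})

test_that("fixed-effect pooling reduces to the study for degenerate inputs", {
  s1 <- data.frame(a = 20, b = 80, c = 10, d = 90)
  for (m in c("MH", "IV")) {
    res <- pool_fixed(s1, method = m)
    expect_equal(res$pooled$or, 2.25)
    expect_equal(res$model_used, "fixed")
    expect_equal(res$tau2, 0)
  }
  # k copies of one table pool to that table's OR
  s5 <- s1[rep(1, 5), ]
  expect_equal(pool_fixed(s5, "MH")$pooled$or, 2.25)
  expect_equal(pool_fixed(s5, "IV")$pooled$or, 2.25)
})

test_that("Mantel-Haenszel pooling matches the independent formula", {
  tabs <- data.frame(a = c(25, 12, 40), b = c(75, 88, 60),
                     c = c(18, 20, 25), d = c(82, 80, 75))
  n <- with(tabs, a + b + c + d)
  or_mh <- sum(tabs$a * tabs$d / n) / sum(tabs$b * tabs$c / n)
  res <- pool_fixed(tabs, method = "MH")
  expect_equal(res$pooled$or, or_mh)
  # normalized weights sum to one; CI brackets the estimate
  expect_equal(sum(res$studies$weight), 1)
  expect_true(res$pooled$ci_low <= res$pooled$or &&
                res$pooled$or <= res$pooled$ci_high)
  # permuting study order changes nothing pooled
  perm <- pool_fixed(tabs[c(3, 1, 2), ], method = "MH")
  expect_equal(perm$pooled, res$pooled)
  expect_equal(perm$Q, res$Q)
})

test_that("random-effects pooling collapses to inverse-variance when tau2 = 0", {
  same <- data.frame(a = c(20, 20), b = c(80, 80), c = c(10, 10),
                     d = c(90, 90))
  rnd <- pool_random(same)
  fix <- pool_fixed(same, method = "IV")
  expect_equal(rnd$tau2, 0)
  expect_equal(rnd$pooled, fix$pooled)
  one <- pool_random(data.frame(a = 20, b = 80, c = 10, d = 90))
  expect_equal(one$pooled$or, 2.25)
})

test_that("the I2 threshold switch is strict", {
  # identical studies (I2 = 0) pool fixed
  same <- data.frame(a = c(20, 20), b = c(80, 80), c = c(10, 10),
                     d = c(90, 90))
  expect_equal(select_and_pool(same)$model_used, "fixed")

  # a heterogeneous pair: random above, fixed at the exact threshold
  hetero <- data.frame(a = c(60, 10), b = c(40, 90), c = c(20, 40),
                       d = c(80, 60))
  i2 <- heterogeneity(hetero)$I2
  expect_gt(i2, 50)
  expect_equal(select_and_pool(hetero)$model_used, "random")
  expect_equal(select_and_pool(hetero, i2_threshold = i2)$model_used,
               "fixed") # I2 equal to the threshold is not "greater"
  expect_equal(select_and_pool(hetero, i2_threshold = i2 - 1)$model_used,
               "random")
})

test_that("Spearman rho handles ties like the rank-Pearson formula", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearman_rho(1:5, rev(c(2, 4, 6, 7, 9)))$rho, -1)

  # ordinal staining scores with ties: against an independent rank
  # computation and the stats::cor estimate
  x <- c(0, 1, 2, 2, 3)
  y <- c(0, 1, 1, 2, 3)
  got <- spearman_rho(x, y)
  rx <- rank(x); ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, manual)
  expect_equal(got$rho, unname(cor(x, y, method = "spearman")))
  tt <- manual * sqrt(3 / (1 - manual^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 3))

  # n = 3 reports p = 1; constant input has no defined rank correlation
  expect_equal(spearman_rho(1:3, c(5, 7, 8))$p, 1)
  expect_true(is.na(spearman_rho(c(1, 1, 1, 1), 1:4)$rho))
})

test_that("Student's t matches stats::t.test and handles degenerate groups", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  got <- students_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, unname(ref$parameter))

  wg <- students_t(c(1, 2, 3, 9), c(2, 3, 4, 5), equal_var = FALSE)
  wref <- t.test(c(1, 2, 3, 9), c(2, 3, 4, 5), var.equal = FALSE)
  expect_equal(wg$t, unname(wref$statistic))
  expect_equal(wg$p, wref$p.value)

  # identical groups: t = 0, p = 1
  same <- students_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # |t| grows and p shrinks monotonically with a pure mean shift
  shifts <- c(0.5, 1, 2, 4)
  stats_ <- lapply(shifts, function(s) students_t(x, x + s))
  tvals <- abs(vapply(stats_, `[[`, numeric(1), "t"))
  pvals <- vapply(stats_, `[[`, numeric(1), "p")
  expect_true(all(diff(tvals) > 0))
  expect_true(all(diff(pvals) < 0))
})

test_that("study tables round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  s <- simulate_meta_studies(4, 0.5, 0.2, 0.3, 200, seed = 67)
  write_table(s[c("study_id", "a", "b", "c", "d")], f)
  back <- read_studies(f)
  expect_equal(back$a, s$a)
  expect_equal(back$d, s$d)
  res <- select_and_pool(back)
  expect_s3_class(res, "meta_result")
  fd <- forest_data(res)
  expect_equal(nrow(fd), 5L)
  expect_true(fd$pooled[5])
})
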