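#' Per-study odds ratio with 95% confidence interval
#'
#' For a 2x2 case/control exposure table the odds ratio is
#' `(a*d) / (b*c)` with log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and Wald 95% CI
#' `exp(log OR +/- 1.96 * se)`. If any cell of a study is zero, 0.5 is
#' added to all four cells of that study first (Haldane correction).
#' Vectorized over studies.
#'
#' @param a,b,c,d Non-negative counts: exposed cases, unexposed cases,
#'   exposed controls, unexposed controls.
#' @return Data frame: `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`,
#'   `corrected` (whether the 0.5 correction was applied).
#' @examples
#' study_odds_ratio(20, 80, 10, 90) # OR 2.25
#' @export
study_odds_ratio <- function(a, b, c, d) {
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a))
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if (any(a + b == 0 | c + d == 0)) {
    stop("degenerate study: a case or control margin is zero")
  }
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * corrected
  b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected
  d <- d + 0.5 * corrected
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(or = exp(log_or),
             ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se),
             log_or = log_or, se_log_or = se, corrected = corrected)
}

# Normalize study input to a data frame with study_id, a, b, c, d.
as_studies <- function(studies) {
  stopifnot(is.data.frame(studies),
            all(c("a", "b", "c", "d") %in% names(studies)),
            nrow(studies) >= 1L)
  if (is.null(studies$study_id)) {
    studies$study_id <- sprintf("study%02d", seq_len(nrow(studies)))
  }
  studies
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Heterogeneity of per-study log odds ratios around the
#' inverse-variance fixed-effect pool: `Q = sum w_i (y_i - y_hat)^2`
#' with `w_i = 1/se_i^2`, `df = k - 1`,
#' `I2 = max(0, (Q - df)/Q) * 100` (0 when Q is 0), and the
#' method-of-moments `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))`.
#' A single study returns all zeros.
#'
#' @param studies Data frame with columns `a`, `b`, `c`, `d` (and
#'   optionally `study_id`).
#' @return List: `Q`, `df`, `I2`, `tau2`.
#' @export
heterogeneity <- function(studies) {
  studies <- as_studies(studies)
  est <- study_odds_ratio(studies$a, studies$b, studies$c, studies$d)
  k <- nrow(studies)
  if (k == 1L) return(list(Q = 0, df = 0L, I2 = 0, tau2 = 0))
  w <- 1 / est$se_log_or^2
  yhat <- sum(w * est$log_or) / sum(w)
  Q <- sum(w * (est$log_or - yhat)^2)
  df <- k - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (C > 0) max(0, (Q - df) / C) else 0
  list(Q = Q, df = df, I2 = I2, tau2 = tau2)
}

meta_result <- function(studies, est, weights, pooled_log_or, pooled_se,
                        model_used, method, het, tau2_reported) {
  per_study <- cbind(studies[c("study_id", "a", "b", "c", "d")], est)
  per_study$weight <- weights / sum(weights)
  rownames(per_study) <- NULL
  structure(list(
    studies = per_study,
    pooled = list(or = exp(pooled_log_or),
                  ci_low = exp(pooled_log_or - 1.96 * pooled_se),
                  ci_high = exp(pooled_log_or + 1.96 * pooled_se),
                  log_or = pooled_log_or, se_log_or = pooled_se),
    model_used = model_used,
    method = method,
    Q = het$Q, df = het$df, I2 = het$I2, tau2 = tau2_reported
  ), class = "meta_result")
}

#' Fixed-effect pooling of study odds ratios
#'
#' `"MH"` (default) pools on the odds-ratio scale with Mantel-Haenszel
#' weights, `OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, and takes the
#' CI from the Robins-Breslow-Greenland variance of the log pooled OR.
#' `"IV"` pools per-study log odds ratios with inverse-variance weights
#' `w_i = 1/se_i^2`. Studies with a zero cell receive the Haldane 0.5
#' correction before pooling under either method. The fixed model assumes
#' no between-study variance, so `tau2` is reported as 0.
#'
#' @param studies Data frame with columns `a`, `b`, `c`, `d` (and
#'   optionally `study_id`).
#' @param method `"MH"` or `"IV"`.
#' @return A `meta_result`: per-study estimates with normalized weights,
#'   pooled OR with 95% CI, `model_used = "fixed"`, and the
#'   heterogeneity statistics `Q`, `df`, `I2`, `tau2`.
#' @export
pool_fixed <- function(studies, method = c("MH", "IV")) {
  method <- match.arg(method)
  studies <- as_studies(studies)
  est <- study_odds_ratio(studies$a, studies$b, studies$c, studies$d)
  het <- heterogeneity(studies)
  corr <- 0.5 * est$corrected
  a <- studies$a + corr; b <- studies$b + corr
  c <- studies$c + corr; d <- studies$d + corr
  n <- a + b + c + d
  if (method == "MH") {
    R <- a * d / n; S <- b * c / n
    P <- (a + d) / n; Q <- (b + c) / n
    pooled_log_or <- log(sum(R) / sum(S))
    var_rbg <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
    meta_result(studies, est, weights = S, pooled_log_or,
                sqrt(var_rbg), "fixed", "MH", het, tau2_reported = 0)
  } else {
    w <- 1 / est$se_log_or^2
    pooled_log_or <- sum(w * est$log_or) / sum(w)
    meta_result(studies, est, weights = w, pooled_log_or,
                1 / sqrt(sum(w)), "fixed", "IV", het, tau2_reported = 0)
  }
}

#' DerSimonian-Laird random-effects pooling
#'
#' Random-effects weights `w_i* = 1 / (se_i^2 + tau2)` with the
#' method-of-moments `tau2`; pooled log OR is the `w*`-weighted mean and
#' its CI uses `1.96 / sqrt(sum w*)`. With `tau2 = 0` this reduces
#' exactly to inverse-variance fixed pooling.
#'
#' @param studies Data frame with columns `a`, `b`, `c`, `d` (and
#'   optionally `study_id`).
#' @return A `meta_result` with `model_used = "random"`.
#' @export
pool_random <- function(studies) {
  studies <- as_studies(studies)
  est <- study_odds_ratio(studies$a, studies$b, studies$c, studies$d)
  het <- heterogeneity(studies)
  w <- 1 / (est$se_log_or^2 + het$tau2)
  pooled_log_or <- sum(w * est$log_or) / sum(w)
  meta_result(studies, est, weights = w, pooled_log_or,
              1 / sqrt(sum(w)), "random", "DL", het,
              tau2_reported = het$tau2)
}

#' Heterogeneity-driven model selection and pooling
#'
#' Computes I-squared and applies the selection rule used for the
#' published forest plots: a random-effects model when heterogeneity is
#' high (I-squared strictly greater than the threshold, 50% by default),
#' otherwise a fixed-effect model. I-squared exactly at the threshold
#' pools fixed.
#'
#' @param studies Data frame with columns `a`, `b`, `c`, `d` (and
#'   optionally `study_id`).
#' @param i2_threshold Percent threshold for switching to random effects.
#' @param fixed_method Fixed-effect estimator, `"MH"` or `"IV"`.
#' @return A `meta_result` with `model_used` recording the choice.
#' @export
select_and_pool <- function(studies, i2_threshold = 50,
                            fixed_method = c("MH", "IV")) {
  fixed_method <- match.arg(fixed_method)
  het <- heterogeneity(as_studies(studies))
  if (het$I2 > i2_threshold) {
    pool_random(studies)
  } else {
    pool_fixed(studies, method = fixed_method)
  }
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Meta-analysis (", nrow(x$studies), " studies, ", x$model_used,
      "-effect ", x$method, ")\n", sep = "")
  for (i in seq_len(nrow(x$studies))) {
    s <- x$studies[i, ]
    cat(sprintf("  %-10s OR %6.3f [%6.3f, %6.3f]  w = %5.1f%%\n",
                s$study_id, s$or, s$ci_low, s$ci_high, 100 * s$weight))
  }
  cat(sprintf("  pooled     OR %6.3f [%6.3f, %6.3f]\n", x$pooled$or,
              x$pooled$ci_low, x$pooled$ci_high))
  cat(sprintf("  Q = %.3f (df %d), I2 = %.1f%%, tau2 = %.4f\n",
              x$Q, x$df, x$I2, x$tau2))
  invisible(x)
}

#' Forest-plot data rows for a meta-analysis
#'
#' Per-study OR/CI/weight rows plus one pooled row -- sufficient to draw
#' a forest plot.
#'
#' @param x A `meta_result`.
#' @return Data frame: `study_id`, `or`, `ci_low`, `ci_high`, `weight`,
#'   `pooled` (logical marker for the summary row).
#' @export
forest_data <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  rows <- x$studies[c("study_id", "or", "ci_low", "ci_high", "weight")]
  rows$pooled <- FALSE
  pooled <- data.frame(study_id = "pooled", or = x$pooled$or,
                       ci_low = x$pooled$ci_low, ci_high = x$pooled$ci_high,
                       weight = 1, pooled = TRUE, stringsAsFactors = FALSE)
  out <- rbind(rows, pooled)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with tie-corrected t approximation
#'
#' Average ranks are assigned to ties; rho is the Pearson correlation of
#' the rank vectors. The two-sided p-value uses the t approximation with
#' n - 2 degrees of freedom for n >= 4 and is reported as 1 otherwise.
#' Suitable for ordinal staining scores (0-3 scales) where ties abound.
#'
#' @param x,y Numeric or ordinal vectors of equal length (n >= 2).
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  p <- if (n < 4L) {
    1
  } else if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-sample Student's t test
#'
#' Pooled-variance t with n1 + n2 - 2 degrees of freedom by default;
#' Welch's unequal-variance form when `equal_var = FALSE`. Two groups
#' with zero pooled variance return t = 0, p = 1 when their means agree
#' (identical groups) and an infinite t with p = 0 otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var Assume equal variances (classic Student's t).
#' @return List: `t`, `p`, `df`.
#' @export
students_t <- function(x, y, equal_var = TRUE) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (equal_var) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) {
      se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
      n1 + n2 - 2
    }
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = df))
  }
  tt <- (m1 - m2) / se
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

#' Read a study table for meta-analysis
#'
#' TSV with a header row and columns `study_id`, `a`, `b`, `c`, `d`
#' (optional `year`, `label` metadata are carried through).
#'
#' @param path Path to the TSV file.
#' @return Data frame of studies with integer cells.
#' @export
read_studies <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (col in c("a", "b", "c", "d")) {
    if (!col %in% names(df)) stop("missing study table column '", col, "'")
    df[[col]] <- as.integer(df[[col]])
  }
  as_studies(df)
}
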