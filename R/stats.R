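# The study's statistical toolkit: Pearson chi-square homogeneity test,
# one-way repeated-measures ANOVA with Bonferroni post hoc contrasts
# against the first follow-up, and Cohen's weighted kappa.

#' Pearson chi-square test on a contingency table
#'
#' Thin wrapper over [stats::chisq.test()] (no continuity correction) with
#' explicit degenerate-table handling: a table with a zero row or column
#' marginal has undefined expected counts and is rejected up front.
#'
#' @param table Matrix (or table) of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p`, and the `expected` counts.
#' @export
#' @examples
#' chi_square_test(rbind(c(10, 0), c(0, 10)))
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) abort_fmt("table must be at least 2 x 2")
  if (any(table < 0)) abort_fmt("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_fmt("degenerate table: zero row or column marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = ct$expected)
}

#' One-way repeated-measures ANOVA across follow-up intervals
#'
#' Within-subject ANOVA on one value per child at each of the 6-, 12- and
#' 18-month intervals, partitioning total variation into subject, time and
#' error sums of squares; `F = MS_time / MS_error` on `(t - 1, (t - 1)(n - 1))`
#' degrees of freedom. Post hoc, the later intervals are each compared with
#' the 6-month increment by a paired t test, Bonferroni-corrected for the
#' two comparisons (adjusted p = min(1, 2 * raw p)).
#'
#' Degenerate inputs are defined rather than NaN: zero error *and* zero time
#' variation (all children flat) gives `F = 0, p = 1`; zero error variation
#' with a real time effect gives `F = Inf, p = 0`.
#'
#' @param values Numeric matrix or data frame, one row per child, one
#'   column per interval in time order (default interpretation: 6, 12, 18
#'   months). Complete cases only; rows with any `NA` are an error — route
#'   incomplete children through imputation first.
#' @param months Interval labels for the columns (default `c(6, 12, 18)`).
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`: with the
#'   latter, the omnibus df are multiplied by the Greenhouse-Geisser epsilon
#'   estimated from the sample covariance of the columns.
#' @return List with `F`, `df_time`, `df_error`, `p`, `epsilon` (1 when no
#'   correction), `sphericity`, and `posthoc` — a tibble with one row per
#'   later interval: `months`, `vs_months`, `mean_diff`, `t`, `df`, `p_raw`,
#'   `p_adjusted`.
#' @export
#' @examples
#' x <- cbind(rnorm(20), rnorm(20, 0.5), rnorm(20, 1))
#' rm_anova(x)$posthoc
rm_anova <- function(values, months = c(6, 12, 18),
                     sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  x <- as.matrix(values)
  if (anyNA(x)) abort_fmt("`values` must be complete cases (impute first)")
  n <- nrow(x); t_lev <- ncol(x)
  if (n < 2) abort_fmt("insufficient data: need at least 2 children")
  if (t_lev < 2) abort_fmt("need at least 2 intervals")
  if (length(months) != t_lev) abort_fmt("`months` must label every column")

  grand <- mean(x)
  ss_subject <- t_lev * sum((rowMeans(x) - grand)^2)
  ss_time <- n * sum((colMeans(x) - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- max(ss_total - ss_subject - ss_time, 0)

  df_time <- t_lev - 1
  df_error <- (t_lev - 1) * (n - 1)
  tol <- 1e-12 * max(1, ss_total)

  eps <- 1
  if (sphericity == "greenhouse-geisser") {
    # epsilon from the double-centered covariance of the interval columns
    S <- stats::cov(x)
    C <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    tr <- sum(diag(C))
    eps <- if (sum(C^2) < tol) 1 else (tr^2) / ((t_lev - 1) * sum(C^2))
    eps <- min(max(eps, 1 / (t_lev - 1)), 1)
  }

  if (ss_error <= tol) {
    if (ss_time <= tol) {
      Fstat <- 0; p <- 1
    } else {
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- (ss_time / df_time) / (ss_error / df_error)
    p <- pf(Fstat, df_time * eps, df_error * eps, lower.tail = FALSE)
  }

  ref <- x[, 1]
  post <- lapply(seq_len(t_lev)[-1], function(j) {
    d <- x[, j] - ref
    sdd <- sd(d)
    if (sdd <= sqrt(tol)) {
      tval <- if (abs(mean(d)) <= sqrt(tol)) 0 else Inf * sign(mean(d))
      praw <- if (tval == 0) 1 else 0
    } else {
      tval <- mean(d) / (sdd / sqrt(n))
      praw <- 2 * pt(abs(tval), n - 1, lower.tail = FALSE)
    }
    tibble::tibble(months = months[j], vs_months = months[1],
                   mean_diff = mean(d), t = tval, df = n - 1,
                   p_raw = praw,
                   p_adjusted = min(1, (t_lev - 1) * praw))
  })

  list(F = Fstat, df_time = df_time, df_error = df_error, p = p,
       epsilon = eps, sphericity = sphericity,
       posthoc = dplyr::bind_rows(post))
}

#' Cohen's weighted kappa
#'
#' Chance-corrected agreement between two raters scoring the same units on
#' an ordinal scale, with linear (default) or quadratic disagreement
#' weights:
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}}}
#' where `O` is the observed joint proportion table, `E` the product of its
#' marginals, and `w_ij = |i - j| / (k - 1)` (linear) or its square
#' (quadratic). With two categories both weightings reduce to the
#' unweighted Cohen kappa.
#'
#' @param ratings_a,ratings_b Equal-length vectors of ordinal ratings. The
#'   category set and order is their sorted union unless `levels` is given.
#' @param weighting `"linear"` or `"quadratic"`.
#' @param levels Optional ordered category levels.
#' @return List with `kappa`, `weighting`, `n`, and the category `levels`.
#' @export
#' @examples
#' weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3))$kappa  # 1
weighted_kappa <- function(ratings_a, ratings_b,
                           weighting = c("linear", "quadratic"),
                           levels = NULL) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) == 0) abort_fmt("empty rating vectors")
  if (length(ratings_a) != length(ratings_b)) {
    abort_fmt("rating vectors differ in length (%d vs %d)",
              length(ratings_a), length(ratings_b))
  }
  levels <- levels %||% sort(unique(c(ratings_a, ratings_b)))
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  if (anyNA(a) || anyNA(b)) abort_fmt("ratings outside the category levels")

  k <- length(levels)
  O <- table(a, b) / length(a)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / max(k - 1, 1)
  w <- if (weighting == "linear") d else d^2

  denom <- sum(w * E)
  kappa <- if (denom == 0) 1 else 1 - sum(w * O) / denom
  list(kappa = kappa, weighting = weighting, n = length(ratings_a),
       levels = levels)
}
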