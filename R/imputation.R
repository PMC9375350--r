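# Stratified hot-deck multiple imputation of unobserved child-intervals,
# and Rubin's rules for pooling across completed datasets.
#
# Imputation operates on the per-child transition-count table (P, R, N per
# interval), not on raw surface states: the counts are sufficient for every
# downstream statistic, and inventing full surface trajectories for
# children who were never examined would add nothing but noise. For each
# missing child-interval a donor child is drawn uniformly at random from
# the same caries-risk stratum among children observed at that interval,
# and the donor's counts (hence increment) are copied. This is a simple,
# honest stand-in for a full model-based multiple imputation, and under
# missingness unrelated to the outcome it leaves stratum means unbiased.

#' Multiply impute missing child-intervals by stratified hot deck
#'
#' @param increments The per-child increment table from
#'   [child_increments()] (any subset of its intervals).
#' @param m Number of completed datasets (at least 2; default 20).
#' @param seed Integer RNG seed; the imputation is reproducible from it.
#' @return An `imputation_set`: list with `m`, `seed`, and `datasets` — a
#'   list of `m` completed increment tables in which every originally
#'   observed row is untouched and every originally missing row carries
#'   donor counts (`donor` column names the donor; `NA` for observed rows).
#' @export
impute_increments <- function(increments, m = 20, seed = 1L) {
  if (m < 2) abort_fmt("`m` must be at least 2")
  need <- c("child_id", "risk", "months", "observed", "P", "R", "N", "adjci")
  miss <- setdiff(need, names(increments))
  if (length(miss)) abort_fmt("increments table lacks column(s): %s",
                              paste(miss, collapse = ", "))

  holes <- which(!increments$observed)
  # donor pools per (risk, months)
  pools <- list()
  for (i in holes) {
    key <- paste(increments$risk[i], increments$months[i])
    if (is.null(pools[[key]])) {
      pools[[key]] <- which(increments$observed &
                              increments$risk == increments$risk[i] &
                              increments$months == increments$months[i])
    }
    if (length(pools[[key]]) == 0) {
      abort_fmt("irreducible missingness: no observed donor in stratum %s at %s months",
                increments$risk[i], increments$months[i])
    }
  }

  datasets <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(m), function(d) {
      out <- increments
      out$donor <- NA_character_
      for (i in holes) {
        pool <- pools[[paste(out$risk[i], out$months[i])]]
        j <- pool[sample.int(length(pool), 1L)]
        out$P[i] <- out$P[j]; out$R[i] <- out$R[j]; out$N[i] <- out$N[j]
        out$adjci[i] <- out$adjci[j]
        out$donor[i] <- out$child_id[j]
      }
      out
    })
  })
  structure(list(m = m, seed = as.integer(seed), datasets = datasets),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  n_imp <- sum(!is.na(x$datasets[[1]]$donor))
  cat(sprintf("<imputation_set> m = %d completed datasets (seed %d), %d imputed child-intervals each\n",
              x$m, x$seed, n_imp))
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines one scalar estimate (with its sampling variance) per completed
#' dataset: the pooled estimate is the mean of the per-dataset estimates,
#' the total variance is the within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance, and the degrees of
#' freedom follow Rubin's small-sample formula
#' `(m - 1) * (1 + W / ((1 + 1/m) B))^2` (infinite when the estimates agree
#' exactly across datasets).
#'
#' @param estimates Numeric vector of per-dataset estimates (length m >= 2).
#' @param variances Per-dataset sampling variances, same length.
#' @return List with `estimate`, `within_var`, `between_var`, `total_var`,
#'   `df`, `m`.
#' @export
#' @examples
#' pool_estimates(c(1, 2, 3), c(0, 0, 0))
pool_estimates <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) abort_fmt("`m` must be at least 2")
  if (length(variances) != m) abort_fmt("estimates and variances differ in length")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  list(estimate = qbar, within_var = W, between_var = B,
       total_var = total, df = df, m = m)
}
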