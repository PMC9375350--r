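# Child-level adjusted caries increment and the risk x follow-up tables.

#' Adjusted caries increment
#'
#' The child-level adjusted caries increment (modified Beck method):
#' \deqn{ADJCI = \frac{P \times N}{R + N}}
#' where `P`, `R`, `N` count the child's surfaces classified as progression,
#' regression, and neither over one baseline-to-follow-up interval. The
#' crude increment `P` is shrunk by the examiner reversal rate implied by
#' the regressions observed among non-progressing surfaces: with no
#' reversals (`R = 0`) the value is exactly `P`; with `P = 0` it is 0. In
#' the degenerate case `R + N = 0` (every surface progressed) the formula is
#' 0/0 and its natural limit `P` is returned.
#'
#' @param P,R,N Non-negative surface counts, or `P` may be a list with
#'   elements `P`, `R`, `N` as returned by [count_transitions()].
#' @return Numeric adjusted increment, on the surface-count scale.
#' @export
#' @examples
#' adjci(5, 0, 121)  # 5: no reversals, no adjustment
#' adjci(5, 1, 94)   # 5 * 94 / 95
adjci <- function(P, R = NULL, N = NULL) {
  if (is.list(P)) {
    R <- P$R; N <- P$N; P <- P$P
  }
  if (isTRUE(any(P < 0 | R < 0 | N < 0, na.rm = TRUE))) {
    abort_fmt("P, R, N must be non-negative")
  }
  ifelse(R + N == 0, as.numeric(P), P * N / (R + N))
}

#' Per-child transition counts and increments at every interval
#'
#' The long table that feeds the increment summaries, imputation and the
#' repeated-measures comparison: one row per child per follow-up interval,
#' with the transition counts and the adjusted increment where the interval
#' was observed (child attended baseline and the follow-up) and `NA`
#' otherwise.
#'
#' @param cohort A [caries_cohort()].
#' @param cutoff `"3-6"` or `"A-6"`.
#' @return Tibble with columns `child_id`, `risk`, `months` (6/12/18),
#'   `observed` (logical), `P`, `R`, `N`, `adjci`.
#' @export
child_increments <- function(cohort, cutoff) {
  cutoff <- match_cutoff(cutoff)
  out <- vector("list", 3L)
  for (k in 1:3) {
    audit <- transition_audit(cohort, k, cutoff)
    counts <- dplyr::summarise(
      dplyr::group_by(audit, .data$child_id),
      P = sum(.data$class == "PROGRESSION"),
      R = sum(.data$class == "REGRESSION"),
      N = sum(.data$class == "NEITHER"),
      .groups = "drop"
    )
    all_children <- cohort$children[c("child_id", "risk")]
    row <- dplyr::left_join(all_children, counts, by = "child_id")
    row$months <- visit_months(k)
    row$observed <- !is.na(row$P)
    out[[k]] <- row
  }
  res <- dplyr::bind_rows(out)
  res$adjci <- ifelse(res$observed, adjci(res$P, res$R, res$N), NA_real_)
  dplyr::arrange(
    res[c("child_id", "risk", "months", "observed", "P", "R", "N", "adjci")],
    .data$child_id, .data$months
  )
}

#' Mean increment per risk stratum at one follow-up
#'
#' Summarises child-level adjusted increments into the familiar
#' mean-plus-SD cells, one per risk stratum plus a pooled row over all
#' risks. With `data = "observed"` only children examined at both baseline
#' and the follow-up contribute; with `data = "imputed"` missing
#' child-intervals are first completed by stratified hot-deck multiple
#' imputation ([impute_increments()]) and the per-dataset stratum means are
#' pooled by Rubin's rules (the reported SD is then the average complete-
#' data SD). The mode used is recorded in the `data` column.
#'
#' @param cohort A [caries_cohort()].
#' @param cutoff `"3-6"` or `"A-6"`.
#' @param months Follow-up interval: 6, 12 or 18.
#' @param data `"observed"` (default) or `"imputed"`.
#' @param m,seed Number of imputations and RNG seed, used only when
#'   `data = "imputed"`.
#' @return Tibble with columns `cutoff`, `risk` (`LOW`/`MEDIUM`/`HIGH`/
#'   `ALL`), `months`, `n`, `mean`, `sd`, `data`; `n = 0` rows carry `NA`
#'   mean and sd (an empty stratum, never silently zero).
#' @export
increment_table <- function(cohort, cutoff, months, data = c("observed", "imputed"),
                            m = 20, seed = 1L) {
  cutoff <- match_cutoff(cutoff)
  data <- match.arg(data)
  months <- as.integer(months)
  if (!months %in% c(6L, 12L, 18L)) abort_fmt("`months` must be 6, 12 or 18")

  inc <- child_increments(cohort, cutoff)
  inc <- dplyr::filter(inc, .data$months == !!months)

  cell <- function(values, risk) {
    values <- values[!is.na(values)]
    n <- length(values)
    tibble::tibble(cutoff = cutoff, risk = risk, months = months, n = n,
                   mean = if (n) mean(values) else NA_real_,
                   sd = if (n >= 2) sd(values) else if (n) 0 else NA_real_,
                   data = data)
  }

  if (data == "observed") {
    rows <- lapply(risk_levels(), function(r) {
      cell(inc$adjci[inc$risk == r], r)
    })
    rows[[4]] <- cell(inc$adjci, "ALL")
    return(dplyr::bind_rows(rows))
  }

  imp <- impute_increments(inc, m = m, seed = seed)
  rows <- lapply(c(risk_levels(), "ALL"), function(r) {
    per_ds <- vapply(imp$datasets, function(d) {
      v <- if (r == "ALL") d$adjci else d$adjci[d$risk == r]
      c(mean(v), var(v) / length(v), sd(v), length(v))
    }, numeric(4))
    pooled <- pool_estimates(per_ds[1, ], per_ds[2, ])
    tibble::tibble(cutoff = cutoff, risk = r, months = months,
                   n = as.integer(per_ds[4, 1]),
                   mean = pooled$estimate, sd = mean(per_ds[3, ]),
                   data = data)
  })
  dplyr::bind_rows(rows)
}
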