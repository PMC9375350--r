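# Translate the pattern of significant increments into risk-stratified
# recall-interval recommendations.
#
# The rule: within one (risk stratum, cutoff) cell, the recommended recall
# is the earliest follow-up interval whose increment evidence is
# significant at alpha; if no interval is significant over the 18-month
# horizon, the recall can be extended to the horizon itself. The 6-month
# entry has no earlier increment to be compared against, so its evidence is
# a one-sample t test of the 6-month increments against zero (early
# progression); the 12- and 18-month entries are the Bonferroni-adjusted
# paired comparisons against the 6-month increment from the
# repeated-measures analysis.

#' Recall recommendation for one risk stratum and cutoff
#'
#' @param p_values Named numeric vector of adjusted p-values with entries
#'   `"6"`, `"12"`, `"18"` (one per follow-up interval).
#' @param risk,cutoff Labels carried into the result.
#' @param alpha Significance level (default 0.05; significance is p < alpha).
#' @return Tibble row: `risk`, `cutoff`, `months` (recommended recall, in
#'   `{6, 12, 18}`), `trigger` (the earliest significant interval, `NA` when
#'   none), and the three p-values as `p6`, `p12`, `p18`.
#' @export
#' @examples
#' recommend_recall(c(`6` = 0.01, `12` = 0.01, `18` = 0.01), "HIGH", "3-6")
#' recommend_recall(c(`6` = 1, `12` = 1, `18` = 1), "LOW", "3-6")
recommend_recall <- function(p_values, risk = NA_character_,
                             cutoff = NA_character_, alpha = 0.05) {
  need <- c("6", "12", "18")
  if (!all(need %in% names(p_values)) || anyNA(p_values[need])) {
    abort_fmt("incomplete evidence: need p-values named 6, 12, 18")
  }
  p <- as.numeric(p_values[need])
  sig <- p < alpha
  trigger <- if (any(sig)) c(6L, 12L, 18L)[which(sig)[1]] else NA_integer_
  tibble::tibble(
    risk = risk, cutoff = if (is.na(cutoff)) cutoff else match_cutoff(cutoff),
    months = if (is.na(trigger)) 18L else trigger,
    trigger = trigger, p6 = p[1], p12 = p[2], p18 = p[3]
  )
}

#' Recall recommendation table over all risk strata and cutoffs
#'
#' Applies [recommend_recall()] to each cell of a significance pattern. An
#' `overrides` argument allows an explicit, audited departure from the
#' evidence-driven rule for named cells (e.g. shortening a stratum's recall
#' on external grounds); overridden cells are flagged in the `overridden`
#' column and keep their evidence columns for audit.
#'
#' @param evidence Data frame with columns `risk`, `cutoff`, `p6`, `p12`,
#'   `p18` — one row per (risk, cutoff) cell, p-values already adjusted
#'   (see [significance_table()]).
#' @param alpha Significance level (default 0.05).
#' @param overrides Optional data frame with columns `risk`, `cutoff`,
#'   `months` forcing the recommendation for specific cells.
#' @return Tibble with one row per cell: `risk`, `cutoff`, `months`,
#'   `trigger`, `p6`, `p12`, `p18`, `overridden`.
#' @export
recall_table <- function(evidence, alpha = 0.05, overrides = NULL) {
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    recommend_recall(
      c(`6` = evidence$p6[i], `12` = evidence$p12[i], `18` = evidence$p18[i]),
      risk = evidence$risk[i], cutoff = evidence$cutoff[i], alpha = alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  out$overridden <- FALSE
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- out$risk == toupper(overrides$risk[i]) &
        out$cutoff == match_cutoff(overrides$cutoff[i])
      out$months[hit] <- as.integer(overrides$months[i])
      out$overridden[hit] <- TRUE
    }
  }
  out
}

#' Significance pattern computed from a cohort
#'
#' Builds the evidence table [recall_table()] consumes, for both cutoffs and
#' every risk stratum: `p6` is the (raw) one-sample t p-value of the
#' stratum's 6-month adjusted increments against zero; `p12` and `p18` are
#' the Bonferroni-adjusted paired comparisons of the 12- and 18-month
#' increments against the 6-month increment from [rm_anova()] on
#' complete-case children (or on imputed-complete data when
#' `data = "imputed"`, in which case each completed dataset is analysed and
#' the median p over datasets is reported).
#'
#' @param cohort A [caries_cohort()].
#' @param data `"complete"` (complete cases across all three intervals) or
#'   `"imputed"`.
#' @param m,seed Imputation settings when `data = "imputed"`.
#' @return Tibble with columns `risk`, `cutoff`, `n`, `p6`, `p12`, `p18`.
#' @export
significance_table <- function(cohort, data = c("complete", "imputed"),
                               m = 20, seed = 1L) {
  data <- match.arg(data)
  rows <- list()
  for (cutoff in cutoffs()) {
    inc <- child_increments(cohort, cutoff)
    sets <- if (data == "complete") {
      list(dplyr::filter(
        dplyr::group_by(inc, .data$child_id),
        all(.data$observed)
      ) |> dplyr::ungroup())
    } else {
      impute_increments(inc, m = m, seed = seed)$datasets
    }
    for (r in risk_levels()) {
      per_set <- vapply(sets, function(d) {
        d <- d[d$risk == r, ]
        wide <- tidyr::pivot_wider(d[c("child_id", "months", "adjci")],
                                   names_from = "months", values_from = "adjci")
        x <- as.matrix(wide[c("6", "12", "18")])
        x <- x[stats::complete.cases(x), , drop = FALSE]
        if (nrow(x) < 2) abort_fmt("insufficient data in stratum %s", r)
        v6 <- x[, 1]
        p6 <- if (sd(v6) == 0) {
          if (mean(v6) == 0) 1 else 0
        } else {
          stats::t.test(v6, mu = 0)$p.value
        }
        fit <- rm_anova(x)
        c(nrow(x), p6, fit$posthoc$p_adjusted)
      }, numeric(4))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        risk = r, cutoff = cutoff, n = as.integer(per_set[1, 1]),
        p6 = stats::median(per_set[2, ]),
        p12 = stats::median(per_set[3, ]),
        p18 = stats::median(per_set[4, ])
      )
    }
  }
  dplyr::bind_rows(rows)
}
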