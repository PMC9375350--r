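# Report-style tables: response rates, surface-state distributions,
# risk-by-demographics with chi-square, increment comparison, and
# recommendations — plus a one-call pipeline that writes them all.
#
# Every percentage printed in an artifact is recomputed from the count and
# denominator shown beside it (round-half-up; 1 decimal for rate-style
# tables, 2 for surface-share tables), so the tables are self-consistent by
# construction.

new_table_artifact <- function(kind, rows, metadata = list()) {
  structure(list(kind = kind, rows = rows, metadata = metadata),
            class = "table_artifact")
}

#' @export
print.table_artifact <- function(x, ...) {
  cat(sprintf("<table_artifact:%s>\n", x$kind))
  print(x$rows, n = 25)
  invisible(x)
}

#' Response, absence and dropout rates per visit
#'
#' Attendees, absentees and (cumulative) dropouts at each visit, per risk
#' stratum and in total, with the response rate attendees / enrolled x 100.
#'
#' @param cohort A [caries_cohort()].
#' @return A `table_artifact` of kind `RESPONSE_RATES` whose rows have
#'   `visit`, `risk`, `enrolled`, `attendees`, `absentees`, `dropouts`,
#'   `response_rate_pct`.
#' @export
table_response_rates <- function(cohort) {
  ch <- cohort$children
  rows <- list()
  for (k in 0:3) {
    st <- ch[[paste0("att", k)]]
    for (r in c(risk_levels(), "ALL")) {
      in_r <- if (r == "ALL") rep(TRUE, nrow(ch)) else ch$risk == r
      enrolled <- sum(in_r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        visit = k, risk = r, enrolled = enrolled,
        attendees = sum(st[in_r] == "ATTENDED"),
        absentees = sum(st[in_r] == "ABSENT"),
        dropouts = sum(st[in_r] == "DROPPED"),
        response_rate_pct = pct(sum(st[in_r] == "ATTENDED"), enrolled,
                                digits = 0)
      )
    }
  }
  new_table_artifact("RESPONSE_RATES", dplyr::bind_rows(rows))
}

#' Distribution of surface states at one visit
#'
#' Counts and percentages of observed surfaces in each modified ICDAS
#' column (sound, A, 3, 4, 5, 6, plus the restorative and terminal states)
#' among all surfaces observed at the visit.
#'
#' @param cohort A [caries_cohort()].
#' @param visit Visit index 0-3.
#' @return A `table_artifact` of kind `SURFACE_DISTRIBUTION` whose rows
#'   have `visit`, `condition`, `count`, `percent` (2 decimals, half-up)
#'   and a `TOTAL` row.
#' @export
table_surface_distribution <- function(cohort, visit) {
  visit <- as.integer(visit)
  ob <- dplyr::filter(cohort$observations, .data$visit == !!visit)
  total <- nrow(ob)
  counts <- vapply(surface_conditions(),
                   function(s) sum(ob$condition == s), integer(1),
                   USE.NAMES = FALSE)
  rows <- tibble::tibble(
    visit = visit,
    condition = c(surface_conditions(), "TOTAL"),
    count = c(counts, total),
    percent = c(pct(counts, total, digits = 2),
                if (total > 0) 100 else NA_real_)
  )
  new_table_artifact("SURFACE_DISTRIBUTION", rows)
}

#' Risk strata against sociodemographic characteristics
#'
#' For each characteristic (sex, residence, school type) the risk-level
#' counts with within-row percentages and a chi-square homogeneity p-value,
#' plus the overall risk distribution. Row percentages use largest-remainder
#' rounding so each row sums to exactly 100 (the distribution-row convention
#' of clinical survey tables). Characteristics whose table is degenerate (a
#' zero marginal, e.g. a single-stratum cohort) are flagged and carry no
#' p-value.
#'
#' @param cohort A [caries_cohort()].
#' @return A `table_artifact` of kind `RISK_BY_DEMOGRAPHICS` whose rows
#'   have `characteristic`, `level`, per-risk `n` and `pct` columns, and
#'   `p_value` (repeated within a characteristic; `NA` if degenerate).
#' @export
table_risk_by_demographics <- function(cohort) {
  ch <- cohort$children
  rows <- list()

  all_n <- vapply(risk_levels(), function(r) sum(ch$risk == r), integer(1))
  all_pct <- pct_lr(all_n)
  rows[[1]] <- tibble::tibble(
    characteristic = "all", level = "ALL",
    low_n = all_n[["LOW"]], low_pct = all_pct[1],
    medium_n = all_n[["MEDIUM"]], medium_pct = all_pct[2],
    high_n = all_n[["HIGH"]], high_pct = all_pct[3],
    p_value = NA_real_, degenerate = FALSE
  )

  for (char in c("sex", "residence", "school_type")) {
    levels <- sort(unique(ch[[char]]))
    tab <- t(vapply(levels, function(l) {
      vapply(risk_levels(), function(r) {
        sum(ch[[char]] == l & ch$risk == r)
      }, integer(1))
    }, integer(3)))
    degenerate <- nrow(tab) < 2 || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0)
    p <- if (degenerate) NA_real_ else chi_square_test(tab)$p
    for (i in seq_along(levels)) {
      row_pct <- pct_lr(tab[i, ])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        characteristic = char, level = levels[i],
        low_n = tab[i, 1], low_pct = row_pct[1],
        medium_n = tab[i, 2], medium_pct = row_pct[2],
        high_n = tab[i, 3], high_pct = row_pct[3],
        p_value = p, degenerate = degenerate
      )
    }
  }
  new_table_artifact("RISK_BY_DEMOGRAPHICS", dplyr::bind_rows(rows))
}

#' Increment comparison table over all strata, intervals and cutoffs
#'
#' The mean-increment table: for each cutoff and risk stratum (plus
#' pooled), mean and SD of the child-level adjusted increment at 6, 12 and
#' 18 months, with the post hoc p-values of the 12- and 18-month
#' comparisons against 6 months from the repeated-measures analysis.
#'
#' @param cohort A [caries_cohort()].
#' @param data `"observed"`/`"complete"` pair or `"imputed"`: mode for the
#'   cell summaries and the significance analysis.
#' @param m,seed Imputation settings.
#' @return A `table_artifact` of kind `INCREMENT_COMPARISON`.
#' @export
table_increment_comparison <- function(cohort, data = c("observed", "imputed"),
                                       m = 20, seed = 1L) {
  data <- match.arg(data)
  cells <- dplyr::bind_rows(lapply(cutoffs(), function(co) {
    dplyr::bind_rows(lapply(c(6L, 12L, 18L), function(mo) {
      increment_table(cohort, co, mo, data = data, m = m, seed = seed)
    }))
  }))
  sig <- significance_table(
    cohort, data = if (data == "observed") "complete" else "imputed",
    m = m, seed = seed
  )
  wide <- tidyr::pivot_wider(cells, names_from = "months",
                             values_from = c("n", "mean", "sd"))
  out <- dplyr::left_join(wide, sig[c("risk", "cutoff", "p12", "p18")],
                          by = c("risk", "cutoff"))
  new_table_artifact("INCREMENT_COMPARISON", out,
                     metadata = list(data = data, m = m, seed = seed))
}

#' Recommendation table artifact
#'
#' @param cohort A [caries_cohort()].
#' @param alpha Significance level.
#' @param data,m,seed Passed to [significance_table()].
#' @param overrides Optional override table (see [recall_table()]).
#' @return A `table_artifact` of kind `RECOMMENDATIONS`.
#' @export
table_recommendations <- function(cohort, alpha = 0.05,
                                  data = c("complete", "imputed"),
                                  m = 20, seed = 1L, overrides = NULL) {
  data <- match.arg(data)
  ev <- significance_table(cohort, data = data, m = m, seed = seed)
  new_table_artifact("RECOMMENDATIONS",
                     recall_table(ev, alpha = alpha, overrides = overrides),
                     metadata = list(alpha = alpha, data = data))
}

#' Run the full pipeline and write all artifacts
#'
#' Simulate (or read) a cohort, validate it, classify transitions, compute
#' increments, impute if any child-interval is unobserved, run the
#' statistics and the recall rules, and write every table as CSV plus a
#' machine-readable JSON manifest. Stages run in order and any failure
#' removes partial outputs.
#'
#' @param config Either a list or a path to a YAML file. Recognised fields:
#'   `exams`/`children` (paths; read a cohort) or `simulate: true` with
#'   optional generator overrides `n_per_risk`, `surfaces_per_child`,
#'   `frailty_sd`; `seed` (default 1), `alpha` (default 0.05), `m` (default
#'   20), `data` (`"observed"` or `"imputed"`; default `"imputed"` when any
#'   interval is unobserved, else `"observed"`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  m <- config$m %||% 20

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$exams)) {
      read_cohort(config$exams, config$children)
    } else {
      cfg <- default_config()
      for (f in intersect(names(config), c("surfaces_per_child", "frailty_sd"))) {
        cfg[[f]] <- config[[f]]
      }
      if (!is.null(config$n_per_risk)) {
        cfg$n_per_risk <- setNames(as.integer(config$n_per_risk), risk_levels())
      }
      simulate_cohort(cfg, seed)$cohort
    }
  })
  stage("validate", {
    v <- validate_cohort(cohort)
    if (nrow(v)) abort_fmt("%d invariant violation(s)", nrow(v))
  })

  any_missing <- stage("classify", {
    inc <- child_increments(cohort, "3-6")
    any(!inc$observed)
  })
  data_mode <- config$data %||% if (any_missing) "imputed" else "observed"

  emit <- function(artifact, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(artifact$rows, path)
    written <<- c(written, path)
    path
  }

  arts <- list(
    response_rates = emit(stage("tables", table_response_rates(cohort)),
                          "response_rates.csv"),
    surface_distribution = emit(
      stage("tables", {
        d <- dplyr::bind_rows(lapply(0:3, function(k) {
          table_surface_distribution(cohort, k)$rows
        }))
        new_table_artifact("SURFACE_DISTRIBUTION", d)
      }), "surface_distribution.csv"),
    risk_by_demographics = emit(
      stage("tables", table_risk_by_demographics(cohort)),
      "risk_by_demographics.csv"),
    increment_comparison = emit(
      stage("increment", table_increment_comparison(
        cohort, data = if (data_mode == "imputed") "imputed" else "observed",
        m = m, seed = seed)),
      "increment_comparison.csv"),
    recommendations = emit(
      stage("recommend", table_recommendations(
        cohort, alpha = alpha,
        data = if (data_mode == "imputed") "imputed" else "complete",
        m = m, seed = seed)),
      "recommendations.csv")
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("cariesrecall")),
    seed = seed, alpha = alpha, m = m, data = data_mode,
    imputation_used = isTRUE(any_missing) && data_mode == "imputed",
    n_children = nrow(cohort$children),
    n_observations = nrow(cohort$observations),
    artifacts = lapply(arts, basename)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  invisible(manifest)
}
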