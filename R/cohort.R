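# The cohort container: child metadata plus long-format surface observations.

#' Construct a caries cohort
#'
#' Bundles per-child metadata and the long-format surface examination table
#' into a single validated object, the container every downstream stage
#' (transition classification, increments, imputation, reporting) consumes.
#'
#' @param children Data frame with columns `child_id`, `risk`
#'   (LOW/MEDIUM/HIGH), `sex` (MALE/FEMALE), `residence` (URBAN/RURAL),
#'   `school_type` (PUBLIC/PRIVATE) and attendance flags `att0`..`att3`
#'   (ATTENDED/ABSENT/DROPPED), one row per child.
#' @param observations Data frame with columns `child_id`, `visit` (0-3),
#'   `tooth` (FDI two-digit permanent-tooth number, third molars excluded),
#'   `surface` (MESIAL/OCCLUSAL/DISTAL/BUCCAL/LINGUAL) and `condition`
#'   (see [surface_conditions()]), one row per surface per attended visit.
#' @param validate Check the invariants and fail on the first violations
#'   (default `TRUE`). Set `FALSE` only when deliberately building an
#'   invalid cohort to inspect with [validate_cohort()].
#' @return An object of class `caries_cohort`: a list with tibbles
#'   `children` and `observations`, enum fields normalised to upper case.
#' @seealso [read_cohort()], [validate_cohort()], [simulate_cohort()]
#' @export
#' @examples
#' coh <- caries_cohort(
#'   children = data.frame(
#'     child_id = "c1", risk = "LOW", sex = "FEMALE", residence = "URBAN",
#'     school_type = "PUBLIC", att0 = "ATTENDED", att1 = "ATTENDED",
#'     att2 = "ATTENDED", att3 = "ATTENDED"
#'   ),
#'   observations = data.frame(
#'     child_id = "c1", visit = 0L, tooth = 16L,
#'     surface = "OCCLUSAL", condition = "SOUND"
#'   )
#' )
#' coh
caries_cohort <- function(children, observations, validate = TRUE) {
  children <- tibble::as_tibble(children)
  observations <- tibble::as_tibble(observations)

  need_ch <- c("child_id", "risk", "sex", "residence", "school_type",
               paste0("att", 0:3))
  need_ob <- c("child_id", "visit", "tooth", "surface", "condition")
  miss <- setdiff(need_ch, names(children))
  if (length(miss)) abort_fmt("children table lacks column(s): %s",
                              paste(miss, collapse = ", "))
  miss <- setdiff(need_ob, names(observations))
  if (length(miss)) abort_fmt("observations table lacks column(s): %s",
                              paste(miss, collapse = ", "))

  children <- dplyr::mutate(
    children,
    child_id = as.character(.data$child_id),
    dplyr::across(dplyr::all_of(c("risk", "sex", "residence", "school_type",
                                  paste0("att", 0:3))),
                  ~ toupper(as.character(.x)))
  )
  observations <- dplyr::mutate(
    observations,
    child_id = as.character(.data$child_id),
    visit = as.integer(.data$visit),
    tooth = as.integer(.data$tooth),
    surface = toupper(as.character(.data$surface)),
    condition = toupper(as.character(.data$condition))
  )

  out <- structure(
    list(children = children[need_ch],
         observations = observations[need_ob]),
    class = "caries_cohort"
  )
  if (validate) {
    v <- validate_cohort(out)
    if (nrow(v)) {
      abort_fmt("invalid cohort: %d violation(s); first: %s (run validate_cohort() for all)",
                nrow(v), v$rule[1])
    }
  }
  out
}

#' @export
print.caries_cohort <- function(x, ...) {
  att <- as.matrix(x$children[paste0("att", 0:3)])
  cat(sprintf("<caries_cohort> %d children, %d surface observations\n",
              nrow(x$children), nrow(x$observations)))
  cat("  risk: ",
      paste(sprintf("%s=%d", tolower(risk_levels()),
                    tabulate(factor(x$children$risk, risk_levels()),
                             nbins = 3L)),
            collapse = ", "), "\n", sep = "")
  cat("  attendees per visit: ",
      paste(colSums(att == "ATTENDED"), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Check every cohort invariant
#'
#' Violations are returned as data, one row each, rather than raised: an
#' empty result means the cohort satisfies every structural rule (valid
#' enum tokens, permanent-dentition tooth numbers, unique surface keys,
#' observations only at attended visits, dropout absorbing, missing-surface
#' absorbing, no orphan observations).
#'
#' @param cohort A `caries_cohort` (possibly built with `validate = FALSE`).
#' @return Tibble with columns `child_id`, `visit`, `tooth`, `surface`,
#'   `rule`, `detail`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  ch <- cohort$children
  ob <- cohort$observations
  v <- list()
  bad <- function(child_id, visit, tooth, surface, rule, detail) {
    tibble::tibble(child_id = as.character(child_id),
                   visit = as.integer(visit), tooth = as.integer(tooth),
                   surface = as.character(surface), rule = rule,
                   detail = detail)
  }

  if (anyDuplicated(ch$child_id)) {
    dup <- unique(ch$child_id[duplicated(ch$child_id)])
    v[[length(v) + 1L]] <- bad(dup, NA, NA, NA, "duplicate_child",
                               "child_id occurs more than once")
  }
  enum_check <- function(col, valid, rule) {
    ok <- ch[[col]] %in% valid
    if (all(ok)) return()
    v[[length(v) + 1L]] <<- bad(ch$child_id[!ok], NA, NA, NA, rule,
                                sprintf("%s = %s", col, ch[[col]][!ok]))
  }
  enum_check("risk", risk_levels(), "bad_risk")
  enum_check("sex", c("MALE", "FEMALE"), "bad_sex")
  enum_check("residence", c("URBAN", "RURAL"), "bad_residence")
  enum_check("school_type", c("PUBLIC", "PRIVATE"), "bad_school_type")
  for (k in 0:3) enum_check(paste0("att", k), attendance_states(),
                            "bad_attendance")

  # dropout is absorbing across visits
  att <- as.matrix(ch[paste0("att", 0:3)])
  if (nrow(ch)) {
    for (k in 1:3) {
      relapse <- att[, k] == "DROPPED" & att[, k + 1L] != "DROPPED"
      if (any(relapse)) {
        v[[length(v) + 1L]] <- bad(ch$child_id[relapse], k, NA, NA,
                                   "dropout_not_absorbing",
                                   sprintf("DROPPED at visit %d but %s at visit %d",
                                           k - 1L, att[relapse, k + 1L], k))
      }
    }
  }

  ok <- ob$condition %in% surface_conditions()
  if (!all(ok)) {
    b <- ob[!ok, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "bad_condition",
                               sprintf("condition = %s", b$condition))
  }
  ok <- ob$tooth %in% permanent_teeth()
  if (!all(ok)) {
    b <- ob[!ok, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "bad_tooth",
                               "not a permanent tooth 11-17/21-27/31-37/41-47")
  }
  ok <- ob$surface %in% tooth_surfaces()
  if (!all(ok)) {
    b <- ob[!ok, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "bad_surface", sprintf("surface = %s", b$surface))
  }
  ok <- ob$visit %in% visit_indices()
  if (!all(ok)) {
    b <- ob[!ok, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "bad_visit", "visit index outside 0-3")
  }

  key <- paste(ob$child_id, ob$visit, ob$tooth, ob$surface)
  if (anyDuplicated(key)) {
    b <- ob[duplicated(key), ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "duplicate_surface",
                               "same (child, visit, tooth, surface) twice")
  }

  orphan <- !ob$child_id %in% ch$child_id
  if (any(orphan)) {
    b <- ob[orphan, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "orphan_observation",
                               "child_id not in children table")
  }

  # observations only at attended visits
  att_long <- tidyr::pivot_longer(ch[c("child_id", paste0("att", 0:3))],
                                  dplyr::starts_with("att"),
                                  names_to = "visit", values_to = "status")
  att_long$visit <- as.integer(sub("att", "", att_long$visit))
  j <- dplyr::left_join(ob, att_long, by = c("child_id", "visit"))
  not_att <- !is.na(j$status) & j$status != "ATTENDED"
  if (any(not_att)) {
    b <- j[not_att, ]
    v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                               "observation_while_away",
                               sprintf("child %s at visit %d", b$status, b$visit))
  }

  # MISSING is absorbing per surface
  if (nrow(ob)) {
    ob_s <- dplyr::arrange(ob, .data$child_id, .data$tooth, .data$surface,
                           .data$visit)
    grp <- paste(ob_s$child_id, ob_s$tooth, ob_s$surface)
    prev_missing <- c(FALSE, ob_s$condition[-nrow(ob_s)] == "MISSING") &
      c(FALSE, grp[-length(grp)] == grp[-1L])
    # propagate: once missing seen in group, all later rows flagged
    seen <- stats::ave(ob_s$condition == "MISSING", grp,
                       FUN = function(z) cumsum(z) > 0)
    resurrect <- seen & ob_s$condition != "MISSING"
    if (any(resurrect)) {
      b <- ob_s[resurrect, ]
      v[[length(v) + 1L]] <- bad(b$child_id, b$visit, b$tooth, b$surface,
                                 "missing_not_absorbing",
                                 sprintf("surface %s after MISSING", b$condition))
    }
  }

  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(child_id = character(), visit = integer(),
                   tooth = integer(), surface = character(),
                   rule = character(), detail = character())
}

# Attendance status of each child at one visit, as a named character vector.
attendance_at <- function(cohort, visit) {
  stats::setNames(cohort$children[[paste0("att", visit)]],
                  cohort$children$child_id)
}

# child_ids attending every visit in `visits`.
attending_all <- function(cohort, visits) {
  ok <- rep(TRUE, nrow(cohort$children))
  for (k in visits) ok <- ok & cohort$children[[paste0("att", k)]] == "ATTENDED"
  cohort$children$child_id[ok]
}
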