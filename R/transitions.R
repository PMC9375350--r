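# Surface-level transition classification between baseline and a follow-up.
#
# Each surface's pair of collapsed states (baseline, follow-up) is assigned
# exactly one of PROGRESSION / REGRESSION / NEITHER. The mapping is total
# over the 8 x 8 collapsed-state pairs and is held in a lookup matrix so the
# classifier is a table lookup, trivially vectorised and enumerable in tests.

#' Collapse a surface condition under a diagnostic cutoff
#'
#' Both cutoffs merge the four severity codes 3-6 into one cavitated state
#' `CAV`. Under `"3-6"` only cavitated lesions count as decay, so the merged
#' non-cavitated code A folds into `SOUND` (and a filling with non-cavitated
#' decay folds into a sound filling); under `"A-6"` code A remains a decayed
#' state `NONCAV`.
#'
#' @param condition Character vector of conditions ([surface_conditions()]).
#' @param cutoff `"3-6"` or `"A-6"`.
#' @return Character vector of collapsed states ([collapsed_states()]).
#' @export
#' @examples
#' collapse_state("NONCAV_A", "3-6")  # SOUND
#' collapse_state("NONCAV_A", "A-6")  # NONCAV
collapse_state <- function(condition, cutoff) {
  cutoff <- match_cutoff(cutoff)
  condition <- toupper(condition)
  bad <- !condition %in% surface_conditions()
  if (any(bad)) abort_fmt("unknown condition: %s", condition[bad][1])
  map <- c(SOUND = "SOUND", NONCAV_A = "NONCAV",
           CAV3 = "CAV", CAV4 = "CAV", CAV5 = "CAV", CAV6 = "CAV",
           FILLED_SOUND = "FILLED_SOUND", FILLED_NONCAV = "FILLED_NONCAV",
           FILLED_CAV = "FILLED_CAV", MISSING = "MISSING", CROWNED = "CROWNED")
  if (cutoff == "3-6") {
    map[["NONCAV_A"]] <- "SOUND"
    map[["FILLED_NONCAV"]] <- "FILLED_SOUND"
  }
  unname(map[condition])
}

# 8x8 lookup, rows = baseline state, cols = follow-up state.
# P = progression, R = regression, N = neither.
#
# Progression: new decay (sound -> noncav/cav, noncav -> cav), new treatment
# or loss of a previously unrestored surface (sound/noncav -> filled,
# missing, crowned), and worsening of a filling with non-cavitated decay.
# Regression: return to sound from decay or from any filled state, and the
# cavitated-filling -> non-cavitated-filling step.
# Neither: no change; anything out of MISSING or CROWNED (terminal states);
# and any move out of CAV or FILLED_CAV other than the listed regressions.
transition_lookup <- local({
  s <- c("SOUND", "NONCAV", "CAV", "FILLED_SOUND", "FILLED_NONCAV",
         "FILLED_CAV", "MISSING", "CROWNED")
  m <- matrix("NEITHER", 8, 8, dimnames = list(before = s, after = s))
  m["SOUND", c("NONCAV", "CAV", "FILLED_SOUND", "FILLED_NONCAV",
               "FILLED_CAV", "MISSING", "CROWNED")] <- "PROGRESSION"
  m["NONCAV", c("CAV", "FILLED_SOUND", "FILLED_NONCAV", "FILLED_CAV",
                "MISSING", "CROWNED")] <- "PROGRESSION"
  m["NONCAV", "SOUND"] <- "REGRESSION"
  m["CAV", "SOUND"] <- "REGRESSION"
  m["FILLED_SOUND", "SOUND"] <- "REGRESSION"
  m["FILLED_NONCAV", c("CAV", "FILLED_CAV")] <- "PROGRESSION"
  m["FILLED_NONCAV", "SOUND"] <- "REGRESSION"
  m["FILLED_CAV", c("SOUND", "FILLED_NONCAV")] <- "REGRESSION"
  m
})

#' Classify one surface transition
#'
#' Assigns `PROGRESSION`, `REGRESSION` or `NEITHER` to an ordered pair of
#' collapsed states (baseline, follow-up). The mapping is total: every one
#' of the 64 ordered pairs has exactly one class. Biologically implausible
#' reversals are deliberately not filtered — the adjusted-increment formula
#' uses observed reversals to estimate the examiner reversal rate.
#'
#' @param before,after Collapsed states ([collapsed_states()]), same length.
#' @return Character vector in `{"PROGRESSION", "REGRESSION", "NEITHER"}`.
#' @export
#' @examples
#' classify_transition("SOUND", "NONCAV")   # PROGRESSION
#' classify_transition("CAV", "SOUND")      # REGRESSION
#' classify_transition("MISSING", "MISSING") # NEITHER
classify_transition <- function(before, after) {
  before <- toupper(before); after <- toupper(after)
  bad <- !before %in% collapsed_states() | !after %in% collapsed_states()
  if (any(bad)) {
    abort_fmt("not a collapsed state: %s -> %s", before[bad][1], after[bad][1])
  }
  transition_lookup[cbind(before, after)]
}

#' Audit table of all classified transitions at one follow-up
#'
#' For every child attending both baseline and the follow-up visit, pairs
#' each surface's baseline and follow-up observation, collapses both under
#' the cutoff and classifies the change. Surfaces first seen at the
#' follow-up (newly erupted) are classified against an implied `SOUND`
#' baseline; surfaces observed at baseline but not at the follow-up are not
#' classified.
#'
#' @param cohort A [caries_cohort()].
#' @param follow_up_visit Follow-up visit index (1-3).
#' @param cutoff `"3-6"` or `"A-6"`.
#' @return Tibble with one row per classified surface: `child_id`, `visit`,
#'   `tooth`, `surface`, `before`, `after` (collapsed states), `class`,
#'   `cutoff`.
#' @export
transition_audit <- function(cohort, follow_up_visit, cutoff) {
  cutoff <- match_cutoff(cutoff)
  follow_up_visit <- as.integer(follow_up_visit)
  if (!follow_up_visit %in% 1:3) {
    abort_fmt("`follow_up_visit` must be 1, 2 or 3")
  }
  ids <- attending_all(cohort, c(0L, follow_up_visit))
  ob <- cohort$observations
  base <- dplyr::filter(ob, .data$visit == 0L, .data$child_id %in% ids)
  fup <- dplyr::filter(ob, .data$visit == follow_up_visit,
                       .data$child_id %in% ids)
  paired <- dplyr::full_join(
    dplyr::select(base, "child_id", "tooth", "surface", base_cond = "condition"),
    dplyr::select(fup, "child_id", "tooth", "surface", fup_cond = "condition"),
    by = c("child_id", "tooth", "surface")
  )
  # erupted between visits: implied sound baseline; unobserved at follow-up:
  # dropped from the audit.
  paired$base_cond[is.na(paired$base_cond)] <- "SOUND"
  paired <- paired[!is.na(paired$fup_cond), ]

  before <- collapse_state(paired$base_cond, cutoff)
  after <- collapse_state(paired$fup_cond, cutoff)
  tibble::tibble(
    child_id = paired$child_id,
    visit = follow_up_visit,
    tooth = paired$tooth,
    surface = paired$surface,
    before = before,
    after = after,
    class = classify_transition(before, after),
    cutoff = cutoff
  )
}

#' Count progressed / regressed / unchanged surfaces for one child
#'
#' The three operands of the adjusted caries increment: for one child and
#' one baseline-to-follow-up interval, the number of surfaces whose
#' transition classified as progression (`P`), regression (`R`), and
#' neither (`N`). Every classified surface lands in exactly one bucket, so
#' `P + R + N` equals the number of surfaces observed at both visits
#' (erupted surfaces included with implied sound baseline, surfaces missing
#' at baseline included as unchanging).
#'
#' @param cohort A [caries_cohort()].
#' @param child_id A single child identifier.
#' @inheritParams transition_audit
#' @return List with elements `P`, `R`, `N` (non-negative integers) and
#'   `audit` (the child's rows of [transition_audit()]).
#' @export
count_transitions <- function(cohort, child_id, follow_up_visit, cutoff) {
  child_id <- as.character(child_id)
  if (!child_id %in% cohort$children$child_id) {
    abort_fmt("unknown child: %s", child_id)
  }
  st0 <- attendance_at(cohort, 0L)[child_id]
  stk <- attendance_at(cohort, follow_up_visit)[child_id]
  if (st0 != "ATTENDED" || stk != "ATTENDED") {
    abort_fmt("unobserved interval: child %s is %s at baseline and %s at visit %d",
              child_id, st0, stk, follow_up_visit)
  }
  audit <- dplyr::filter(transition_audit(cohort, follow_up_visit, cutoff),
                         .data$child_id == !!child_id)
  list(P = sum(audit$class == "PROGRESSION"),
       R = sum(audit$class == "REGRESSION"),
       N = sum(audit$class == "NEITHER"),
       audit = audit)
}
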