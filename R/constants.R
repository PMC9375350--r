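# Domain vocabularies. All tokens are upper-case on disk and in memory;
# readers accept any case.

#' Surface condition codes
#'
#' The eleven surface states recognised on a modified ICDAS II surface
#' record. `NONCAV_A` is the merged code for ICDAS 1 and 2 (initial,
#' non-cavitated enamel change, scored without compressed-air drying);
#' `CAV3`..`CAV6` are ICDAS codes 3-6 (cavitated, from localised enamel
#' breakdown to extensive cavity with visible dentine). The `FILLED_*`
#' states carry the restorative status together with any decay associated
#' with the filling; `MISSING` and `CROWNED` are terminal states.
#'
#' @return Character vector of the valid condition tokens.
#' @export
#' @examples
#' surface_conditions()
surface_conditions <- function() {
  c("SOUND", "NONCAV_A", "CAV3", "CAV4", "CAV5", "CAV6",
    "FILLED_SOUND", "FILLED_NONCAV", "FILLED_CAV", "MISSING", "CROWNED")
}

#' Collapsed surface states
#'
#' The eight-state alphabet that transition classification operates on after
#' a diagnostic cutoff has been applied (see [collapse_state()]): the four
#' severity codes collapse to a single `CAV` state, and under the cavitated
#' 3-6 cutoff the non-cavitated code folds into `SOUND`.
#'
#' @return Character vector of the eight collapsed state tokens.
#' @export
collapsed_states <- function() {
  c("SOUND", "NONCAV", "CAV", "FILLED_SOUND", "FILLED_NONCAV", "FILLED_CAV",
    "MISSING", "CROWNED")
}

#' Diagnostic cutoffs
#'
#' `"3-6"` counts only cavitated lesions (ICDAS codes 3-6) as decay, so code
#' A surfaces are treated as sound; `"A-6"` counts cavitated plus
#' non-cavitated lesions, so code A is decayed.
#'
#' @return Character vector `c("3-6", "A-6")`.
#' @export
cutoffs <- function() c("3-6", "A-6")

#' @rdname cutoffs
#' @param cutoff Candidate cutoff label.
#' @return `match_cutoff()` returns the normalised label or errors.
#' @export
match_cutoff <- function(cutoff) {
  cutoff <- toupper(as.character(cutoff))
  cutoff[cutoff %in% c("3_6", "36", "CAV", "CAV_3_6")] <- "3-6"
  cutoff[cutoff %in% c("A_6", "A6", "ALL", "ALL_A_6")] <- "A-6"
  if (length(cutoff) != 1L || !cutoff %in% cutoffs()) {
    stop("`cutoff` must be one of \"3-6\", \"A-6\"", call. = FALSE)
  }
  cutoff
}

# 28 permanent teeth, FDI two-digit notation, third molars excluded.
permanent_teeth <- function() {
  as.integer(outer(c(10L, 20L, 30L, 40L), 1:7, `+`))
}

tooth_surfaces <- function() {
  c("MESIAL", "OCCLUSAL", "DISTAL", "BUCCAL", "LINGUAL")
}

risk_levels <- function() c("LOW", "MEDIUM", "HIGH")

attendance_states <- function() c("ATTENDED", "ABSENT", "DROPPED")

visit_indices <- function() 0:3

#' Months elapsed at each visit
#'
#' Visits are indexed 0-3 at a fixed six-month spacing, so visit `k` falls
#' `6 * k` months after baseline.
#'
#' @param visit Integer visit index (0-3).
#' @return Integer months from baseline.
#' @export
#' @examples
#' visit_months(0:3)
visit_months <- function(visit) 6L * as.integer(visit)

months_to_visit <- function(months) {
  months <- as.integer(months)
  if (any(months %% 6L != 0L) || any(months < 0L) || any(months > 18L)) {
    stop("`months` must be in {0, 6, 12, 18}", call. = FALSE)
  }
  months %/% 6L
}
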