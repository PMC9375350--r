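# Plain-CSV readers and writers for the two cohort files.
#
# exams file   : child_id,visit,tooth,surface,condition
# children file: child_id,risk,sex,residence,school_type,att0,att1,att2,att3
#
# Tooth numbers use FDI two-digit notation (quadrant digit + tooth digit,
# e.g. 16 = upper-right first molar); third molars are excluded. Enum tokens
# are case-insensitive on input and written upper-case.

#' Read a cohort from its two CSV files
#'
#' @param exams_path Path to the long-format surface examination CSV with
#'   header `child_id,visit,tooth,surface,condition`.
#' @param children_path Path to the child metadata CSV with header
#'   `child_id,risk,sex,residence,school_type,att0,att1,att2,att3`.
#' @return A validated [caries_cohort()].
#' @export
read_cohort <- function(exams_path, children_path) {
  for (p in c(exams_path, children_path)) {
    if (!file.exists(p)) abort_fmt("file not found: %s", p)
  }
  ob <- readr::read_csv(exams_path, show_col_types = FALSE,
                        col_types = readr::cols(
                          child_id = readr::col_character(),
                          visit = readr::col_integer(),
                          tooth = readr::col_integer(),
                          surface = readr::col_character(),
                          condition = readr::col_character()))
  ch <- readr::read_csv(children_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))

  bad <- !toupper(ob$condition) %in% surface_conditions()
  if (any(bad)) {
    abort_fmt("unknown condition token %s in %s (row %d)",
              ob$condition[which(bad)[1]], exams_path, which(bad)[1])
  }
  caries_cohort(ch, ob)
}

#' Write a cohort to its two CSV files
#'
#' Rows are emitted in deterministic order (child_id, visit, tooth, surface)
#' so that identical cohorts serialise byte-identically; the files round-trip
#' through [read_cohort()].
#'
#' @param cohort A [caries_cohort()].
#' @inheritParams read_cohort
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, exams_path, children_path) {
  ob <- dplyr::arrange(cohort$observations, .data$child_id, .data$visit,
                       .data$tooth, .data$surface)
  ch <- dplyr::arrange(cohort$children, .data$child_id)
  readr::write_csv(ob, exams_path)
  readr::write_csv(ch, children_path)
  invisible(c(exams = exams_path, children = children_path))
}
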