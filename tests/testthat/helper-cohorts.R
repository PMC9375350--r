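# Builders for small in-code fixtures.

# A child row with full attendance unless overridden.
child_row <- function(child_id, risk = "LOW", sex = "FEMALE",
                      residence = "URBAN", school_type = "PUBLIC",
                      att = rep("ATTENDED", 4)) {
  tibble::tibble(child_id = child_id, risk = risk, sex = sex,
                 residence = residence, school_type = school_type,
                 att0 = att[1], att1 = att[2], att2 = att[3], att3 = att[4])
}

# First `n` surface slots in canonical (tooth, surface) order.
surface_slots <- function(n) {
  teeth <- as.integer(outer(c(10L, 20L, 30L, 40L), 1:7, `+`))
  g <- expand.grid(surface = c("MESIAL", "OCCLUSAL", "DISTAL", "BUCCAL", "LINGUAL"),
                   tooth = sort(teeth), stringsAsFactors = FALSE)
  head(g[c("tooth", "surface")], n)
}

# One child observed at baseline and follow-ups with given per-visit
# condition vectors (each of length n_surf).
one_child_cohort <- function(conditions_by_visit, risk = "LOW",
                             child_id = "c1", validate = TRUE) {
  n_surf <- length(conditions_by_visit[[1]])
  slots <- surface_slots(n_surf)
  obs <- dplyr::bind_rows(lapply(seq_along(conditions_by_visit), function(i) {
    tibble::tibble(child_id = child_id, visit = as.integer(names(conditions_by_visit)[i]),
                   tooth = slots$tooth, surface = slots$surface,
                   condition = conditions_by_visit[[i]])
  }))
  visits_attended <- as.integer(names(conditions_by_visit))
  att <- ifelse(0:3 %in% visits_attended, "ATTENDED", "ABSENT")
  caries_cohort(child_row(child_id, risk = risk, att = att), obs,
                validate = validate)
}

# Cohort of `n` fully-sound children, full attendance, 6 surfaces each.
sound_cohort <- function(n, risk = "LOW") {
  slots <- surface_slots(6)
  children <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    child_row(sprintf("s%03d", i), risk = risk)
  }))
  obs <- tidyr::expand_grid(child_id = children$child_id, visit = 0:3,
                            slots)
  obs$condition <- "SOUND"
  caries_cohort(children, obs)
}

# Cohort whose children table realises exact per-risk counts and
# demographics; no observations needed for demographic tables.
demographic_cohort <- function(counts) {
  # counts: list of tibbles with columns risk, sex, residence, school_type, n
  rows <- list()
  i <- 0L
  for (j in seq_len(nrow(counts))) {
    for (k in seq_len(counts$n[j])) {
      i <- i + 1L
      rows[[i]] <- child_row(sprintf("d%04d", i), risk = counts$risk[j],
                             sex = counts$sex[j],
                             residence = counts$residence[j],
                             school_type = counts$school_type[j])
    }
  }
  caries_cohort(dplyr::bind_rows(rows),
                tibble::tibble(child_id = character(), visit = integer(),
                               tooth = integer(), surface = character(),
                               condition = character()))
}

# Cohort with a prescribed surface-state count vector at one visit.
# `state_counts` is a named integer vector over surface conditions.
distribution_cohort <- function(state_counts, visit = 0L) {
  total <- sum(state_counts)
  n_children <- ceiling(total / 140)
  slots <- surface_slots(140)
  conds <- rep(names(state_counts), state_counts)
  child_ids <- sprintf("p%04d", rep(seq_len(n_children), each = 140)[seq_len(total)])
  idx <- (seq_len(total) - 1L) %% 140L + 1L
  att <- ifelse(0:3 == visit, "ATTENDED", "ABSENT")
  children <- dplyr::bind_rows(lapply(unique(child_ids), function(id) {
    child_row(id, att = att)
  }))
  obs <- tibble::tibble(child_id = child_ids, visit = as.integer(visit),
                        tooth = slots$tooth[idx], surface = slots$surface[idx],
                        condition = conds)
  caries_cohort(children, obs)
}

# tiny config for fast end-to-end runs
small_config <- function(n = c(LOW = 12L, MEDIUM = 12L, HIGH = 12L),
                         surfaces = 30L) {
  cfg <- default_config()
  cfg$n_per_risk <- n
  cfg$surfaces_per_child <- surfaces
  cfg
}
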