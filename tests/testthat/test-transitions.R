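# Brute-force re-derivation of the transition classes from the rule text,
# independent of the package's lookup matrix.
oracle_classify <- function(before, after) {
  prog <- list(
    c("SOUND", "NONCAV"), c("SOUND", "CAV"), c("NONCAV", "CAV"),
    c("SOUND", "MISSING"), c("SOUND", "CROWNED"),
    c("NONCAV", "MISSING"), c("NONCAV", "CROWNED"),
    c("FILLED_NONCAV", "CAV"), c("FILLED_NONCAV", "FILLED_CAV"),
    c("SOUND", "FILLED_SOUND"), c("SOUND", "FILLED_NONCAV"),
    c("SOUND", "FILLED_CAV"),
    c("NONCAV", "FILLED_SOUND"), c("NONCAV", "FILLED_NONCAV"),
    c("NONCAV", "FILLED_CAV")
  )
  regr <- list(
    c("NONCAV", "SOUND"), c("CAV", "SOUND"), c("FILLED_NONCAV", "SOUND"),
    c("FILLED_CAV", "SOUND"), c("FILLED_CAV", "FILLED_NONCAV"),
    c("FILLED_SOUND", "SOUND")
  )
  pair <- c(before, after)
  if (any(vapply(prog, identical, logical(1), pair))) return("PROGRESSION")
  if (any(vapply(regr, identical, logical(1), pair))) return("REGRESSION")
  "NEITHER"
}

test_that("collapsing respects each cutoff's treatment of code A", {
  expect_equal(collapse_state("NONCAV_A", "3-6"), "SOUND")
  expect_equal(collapse_state("NONCAV_A", "A-6"), "NONCAV")
  expect_equal(collapse_state("FILLED_NONCAV", "3-6"), "FILLED_SOUND")
  for (cav in c("CAV3", "CAV4", "CAV5", "CAV6")) {
    expect_equal(collapse_state(cav, "3-6"), "CAV")
    expect_equal(collapse_state(cav, "A-6"), "CAV")
  }
  for (co in cutoffs()) {
    expect_true(all(collapse_state(surface_conditions(), co) %in%
                      collapsed_states()))
  }
})

test_that("classification matches the rule list on all 64 state pairs (totality)", {
  s <- collapsed_states()
  for (b in s) for (a in s) {
    got <- classify_transition(b, a)
    expect_true(got %in% c("PROGRESSION", "REGRESSION", "NEITHER"))
    expect_equal(got, oracle_classify(b, a),
                 label = sprintf("%s -> %s: %s", b, a, got))
  }
  # spot checks straight from the transition taxonomy
  expect_equal(classify_transition("SOUND", "NONCAV"), "PROGRESSION")
  expect_equal(classify_transition("MISSING", "MISSING"), "NEITHER")
  expect_equal(classify_transition("MISSING", "CAV"), "NEITHER")
  expect_equal(classify_transition("CAV", "SOUND"), "REGRESSION")
  expect_equal(classify_transition("SOUND", "SOUND"), "NEITHER")
  expect_equal(classify_transition("CAV", "MISSING"), "NEITHER")
})

test_that("transition counts are exhaustive and match a re-count of the audit", {
  coh <- one_child_cohort(list(
    `0` = rep("SOUND", 10),
    `1` = c(rep("NONCAV_A", 3), rep("SOUND", 7))
  ))
  ct <- count_transitions(coh, "c1", 1, "A-6")
  expect_equal(ct[c("P", "R", "N")], list(P = 3, R = 0, N = 7))
  ct36 <- count_transitions(coh, "c1", 1, "3-6")
  expect_equal(ct36[c("P", "R", "N")], list(P = 0, R = 0, N = 10))

  # unchanged child
  coh2 <- one_child_cohort(list(`0` = rep("CAV3", 4), `1` = rep("CAV3", 4)))
  ct2 <- count_transitions(coh2, "c1", 1, "3-6")
  expect_equal(ct2[c("P", "R", "N")], list(P = 0, R = 0, N = 4))

  # brute-force re-count over the audit list
  sim <- simulate_cohort(small_config(), seed = 5)
  for (co in cutoffs()) {
    audit <- transition_audit(sim$cohort, 2, co)
    id <- audit$child_id[1]
    ct <- count_transitions(sim$cohort, id, 2, co)
    mine <- audit[audit$child_id == id, ]
    expect_equal(ct$P, sum(mine$class == "PROGRESSION"))
    expect_equal(ct$R, sum(mine$class == "REGRESSION"))
    expect_equal(ct$N, sum(mine$class == "NEITHER"))
    expect_equal(ct$P + ct$R + ct$N, nrow(mine))
  }
})

test_that("P + R + N is conserved for every child, interval and cutoff", {
  sim <- simulate_cohort(small_config(n = c(LOW = 8L, MEDIUM = 8L, HIGH = 8L),
                                      surfaces = 20L), seed = 9)
  for (co in cutoffs()) {
    inc <- child_increments(sim$cohort, co)
    obs <- inc[inc$observed, ]
    expect_true(all(obs$P + obs$R + obs$N == 20L))
  }
})

test_that("a child absent at either endpoint raises an unobserved-interval error", {
  coh <- one_child_cohort(list(`0` = rep("SOUND", 3), `2` = rep("SOUND", 3)))
  expect_error(count_transitions(coh, "c1", 1, "3-6"), "unobserved interval")
})

test_that("surfaces erupting between visits count against an implied sound baseline", {
  slots <- surface_slots(4)
  children <- child_row("c1")
  obs <- dplyr::bind_rows(
    tibble::tibble(child_id = "c1", visit = 0L, tooth = slots$tooth[1:2],
                   surface = slots$surface[1:2], condition = "SOUND"),
    tibble::tibble(child_id = "c1", visit = 1L, tooth = slots$tooth,
                   surface = slots$surface,
                   condition = c("SOUND", "SOUND", "SOUND", "CAV3"))
  )
  coh <- caries_cohort(children, obs)
  ct <- count_transitions(coh, "c1", 1, "3-6")
  # four surfaces classified: 2 carried, 2 erupted (one straight to decay)
  expect_equal(ct[c("P", "R", "N")], list(P = 1, R = 0, N = 3))
})

test_that("with only sound-to-A changes, progression is seen at A-6 and not at 3-6", {
  set.seed(21)
  n_surf <- 40
  base <- rep("SOUND", n_surf)
  fup <- ifelse(runif(n_surf) < 0.2, "NONCAV_A", "SOUND")
  coh <- one_child_cohort(list(`0` = base, `1` = fup))
  pa <- count_transitions(coh, "c1", 1, "A-6")$P
  p36 <- count_transitions(coh, "c1", 1, "3-6")$P
  expect_equal(p36, 0)
  expect_gte(pa, p36)
  expect_equal(pa, sum(fup == "NONCAV_A"))
})
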