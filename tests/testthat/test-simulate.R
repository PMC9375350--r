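test_that("the default configuration encodes the study-scale cohort", {
  cfg <- default_config()
  expect_equal(sum(cfg$n_per_risk), 226L)
  expect_equal(unname(cfg$n_per_risk), c(90L, 69L, 67L))
  expect_equal(cfg$surfaces_per_child, 126L)
  expect_equal(round(cfg$baseline_state_probs[["SOUND"]], 3), 0.975)
  expect_equal(round(100 * cfg$baseline_state_probs[["NONCAV_A"]], 2), 1.81)
  expect_equal(sum(cfg$baseline_state_probs), 1)
})

test_that("every risk kernel is row-stochastic with absorbing terminal states", {
  cfg <- default_config()
  for (r in c("LOW", "MEDIUM", "HIGH")) {
    K <- transition_kernel(cfg, r)
    expect_equal(unname(rowSums(K)), rep(1, 11), tolerance = 1e-12)
    expect_true(all(K >= 0))
    expect_equal(K["MISSING", "MISSING"], 1)
    expect_equal(K["CROWNED", "CROWNED"], 1)
  }
  # progression rates ordered high > medium > low
  for (p in c("sound_to_noncav", "sound_to_cav", "noncav_to_cav")) {
    expect_gt(cfg$progression$HIGH[[p]], cfg$progression$MEDIUM[[p]])
    expect_gt(cfg$progression$MEDIUM[[p]], cfg$progression$LOW[[p]])
  }
})

test_that("identical seed and config give identical cohorts", {
  cfg <- small_config()
  s1 <- simulate_cohort(cfg, seed = 42)
  s2 <- simulate_cohort(cfg, seed = 42)
  expect_identical(s1$cohort$children, s2$cohort$children)
  expect_identical(s1$cohort$observations, s2$cohort$observations)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(s1$cohort$observations, s3$cohort$observations))
})

test_that("an identity kernel freezes every surface and all increments are zero", {
  cfg <- small_config()
  cfg$progression <- lapply(cfg$progression, function(p) p * 0)
  cfg$shared_rates[] <- 0
  cfg$absence_prob <- rep(0, 4)
  cfg$dropout_prob <- rep(0, 4)
  sim <- simulate_cohort(cfg, seed = 6)
  base <- dplyr::filter(sim$cohort$observations, visit == 0)
  for (k in 1:3) {
    fup <- dplyr::filter(sim$cohort$observations, visit == k)
    expect_equal(fup$condition, base$condition)
  }
  inc <- child_increments(sim$cohort, "A-6")
  expect_true(all(inc$adjci == 0))
})

test_that("a certain sound-to-A kernel progresses every sound surface by visit 1", {
  cfg <- small_config(n = c(LOW = 5L, MEDIUM = 5L, HIGH = 5L), surfaces = 20L)
  cfg$baseline_state_probs[] <- 0
  cfg$baseline_state_probs[["SOUND"]] <- 1
  for (r in c("LOW", "MEDIUM", "HIGH")) {
    cfg$progression[[r]][["sound_to_noncav"]] <- 1
    cfg$progression[[r]][["sound_to_cav"]] <- 0
  }
  cfg$shared_rates[["noncav_to_sound"]] <- 0
  cfg$absence_prob <- rep(0, 4)
  cfg$dropout_prob <- rep(0, 4)
  sim <- simulate_cohort(cfg, seed = 8)
  inc <- child_increments(sim$cohort, "A-6")
  expect_true(all(inc$P[inc$months == 6] == 20L))
})

test_that("baseline state frequencies match the configured distribution at scale", {
  cfg <- small_config(n = c(LOW = 1000L, MEDIUM = 1000L, HIGH = 1000L),
                      surfaces = 126L)
  sim <- simulate_cohort(cfg, seed = 123)
  base <- dplyr::filter(sim$cohort$observations, visit == 0)
  n <- nrow(base)
  for (s in c("SOUND", "NONCAV_A", "CAV3")) {
    p <- cfg$baseline_state_probs[[s]]
    phat <- mean(base$condition == s)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("ground-truth expectations are internally consistent with the cohort", {
  cfg <- small_config(n = c(LOW = 30L, MEDIUM = 30L, HIGH = 30L), surfaces = 60L)
  cfg$absence_prob <- rep(0, 4)
  cfg$dropout_prob <- rep(0, 4)
  sim <- simulate_cohort(cfg, seed = 91)
  # realized ground-truth counts equal the pipeline's counts when everyone
  # attends every visit
  inc <- child_increments(sim$cohort, "3-6")
  gt <- dplyr::filter(sim$ground_truth$realized, cutoff == "3-6")
  j <- dplyr::inner_join(inc, gt, by = c("child_id", "months"),
                         suffix = c("", ".gt"))
  expect_equal(nrow(j), nrow(inc))
  expect_equal(j$P, j$P.gt)
  expect_equal(j$R, j$R.gt)
  expect_equal(j$N, j$N.gt)
  expect_equal(j$adjci, j$adjci.gt)
})

test_that("attrition at the default hazards lands near the published attendance", {
  sim <- simulate_cohort(default_config(), seed = 2024)
  att <- vapply(0:3, function(k) {
    sum(sim$cohort$children[[paste0("att", k)]] == "ATTENDED")
  }, integer(1))
  # expected attendees approx 220/172/172/181 of 226; allow generous MC slack
  expect_true(all(abs(att - c(220, 172, 172, 181)) < 25))
  dropped3 <- sum(sim$cohort$children$att3 == "DROPPED")
  expect_true(abs(dropped3 - 43) < 20)
})
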