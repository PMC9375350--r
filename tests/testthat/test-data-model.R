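test_that("a minimal valid exam file reads into a one-observation cohort", {
  exams <- withr::local_tempfile(fileext = ".csv")
  children <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,visit,tooth,surface,condition",
               "c1,0,16,OCCLUSAL,SOUND"), exams)
  writeLines(c("child_id,risk,sex,residence,school_type,att0,att1,att2,att3",
               "c1,low,female,urban,public,attended,absent,absent,absent"),
             children)
  coh <- read_cohort(exams, children)
  expect_s3_class(coh, "caries_cohort")
  expect_equal(nrow(coh$observations), 1L)
  expect_equal(coh$observations$condition, "SOUND")
  expect_equal(coh$children$risk, "LOW")  # case-insensitive parsing
})

test_that("third molars and unknown tokens are rejected with informative errors", {
  exams <- withr::local_tempfile(fileext = ".csv")
  children <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,risk,sex,residence,school_type,att0,att1,att2,att3",
               "c1,LOW,FEMALE,URBAN,PUBLIC,ATTENDED,ABSENT,ABSENT,ABSENT"),
             children)
  writeLines(c("child_id,visit,tooth,surface,condition",
               "c1,0,18,OCCLUSAL,SOUND"), exams)
  expect_error(read_cohort(exams, children), "violation")
  writeLines(c("child_id,visit,tooth,surface,condition",
               "c1,0,16,OCCLUSAL,WOBBLY"), exams)
  expect_error(read_cohort(exams, children), "WOBBLY.*row 1")
  # duplicate surface key
  writeLines(c("child_id,visit,tooth,surface,condition",
               "c1,0,16,OCCLUSAL,SOUND", "c1,0,16,OCCLUSAL,CAV3"), exams)
  expect_error(read_cohort(exams, children), "violation")
  # observation at an absent visit
  writeLines(c("child_id,visit,tooth,surface,condition",
               "c1,1,16,OCCLUSAL,SOUND"), exams)
  expect_error(read_cohort(exams, children), "violation")
})

test_that("write_cohort then read_cohort round-trips a simulated cohort", {
  sim <- simulate_cohort(small_config(), seed = 11)
  exams <- withr::local_tempfile(fileext = ".csv")
  children <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, exams, children)
  back <- read_cohort(exams, children)
  ord <- function(coh) {
    list(
      children = dplyr::arrange(coh$children, child_id),
      observations = dplyr::arrange(coh$observations, child_id, visit,
                                    tooth, surface)
    )
  }
  expect_equal(ord(back), ord(sim$cohort))
})

test_that("an empty cohort writes header-only files", {
  coh <- caries_cohort(
    child_row(character(0))[0, ],
    tibble::tibble(child_id = character(), visit = integer(),
                   tooth = integer(), surface = character(),
                   condition = character())
  )
  exams <- withr::local_tempfile(fileext = ".csv")
  children <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, exams, children)
  expect_equal(readLines(exams), "child_id,visit,tooth,surface,condition")
  expect_equal(readLines(children),
               "child_id,risk,sex,residence,school_type,att0,att1,att2,att3")
})

test_that("MISSING tokens serialise verbatim", {
  coh <- one_child_cohort(list(`0` = c("SOUND", "MISSING")))
  exams <- withr::local_tempfile(fileext = ".csv")
  children <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, exams, children)
  expect_true(any(grepl(",MISSING$", readLines(exams))))
})

test_that("validate_cohort reports absorbing-state violations as data", {
  coh <- one_child_cohort(list(`0` = "SOUND", `1` = "MISSING", `2` = "SOUND",
                               `3` = "SOUND"), validate = FALSE)
  v <- validate_cohort(coh)
  expect_true("missing_not_absorbing" %in% v$rule)

  ch <- child_row("c9", att = c("ATTENDED", "DROPPED", "ATTENDED", "ATTENDED"))
  coh3 <- caries_cohort(ch, coh$observations[0, ], validate = FALSE)
  v3 <- validate_cohort(coh3)
  expect_true("dropout_not_absorbing" %in% v3$rule)

  expect_equal(nrow(validate_cohort(sound_cohort(3))), 0L)
})

test_that("randomly corrupted cohorts never pass validation (soundness)", {
  sim <- simulate_cohort(small_config(), seed = 3)
  coh <- sim$cohort
  corruptions <- list(
    function(c0) { c0$observations$tooth[1] <- 18L; c0 },
    function(c0) { c0$observations$condition[1] <- "BROKEN"; c0 },
    function(c0) { c0$observations <- dplyr::bind_rows(c0$observations,
                                                       c0$observations[1, ]); c0 },
    function(c0) { c0$observations$child_id[1] <- "ghost"; c0 },
    function(c0) { c0$children$att1[1] <- "DROPPED"; c0$children$att2[1] <- "ATTENDED"; c0 },
    function(c0) { c0$children$risk[1] <- "EXTREME"; c0 },
    function(c0) { c0$observations$surface[1] <- "PALATAL?"; c0 },
    function(c0) { c0$observations$visit[1] <- 7L; c0 }
  )
  for (corrupt in corruptions) {
    bad <- corrupt(coh)
    bad <- caries_cohort(bad$children, bad$observations, validate = FALSE)
    expect_gt(nrow(validate_cohort(bad)), 0)
  }
})
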