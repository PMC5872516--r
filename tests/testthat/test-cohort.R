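test_that("baseline SCr prefers the 48-hour pre-admission window", {
  b <- compute_baseline(times = c(-30 / 24, 2 / 24), values = c(1.1, 0.9),
                        admission = 0)
  expect_equal(b$value, 1.1)
  expect_equal(b$source, "pre-admission-window")

  b <- compute_baseline(times = 1 / 24, values = 0.8, admission = 0)
  expect_equal(b$value, 0.8)
  expect_equal(b$source, "first-inpatient")

  # a pre-admission value outside the 48-h window is ignored
  b <- compute_baseline(times = c(-60 / 24, 5 / 24), values = c(1.4, 1.0),
                        admission = 0)
  expect_equal(b$value, 1.0)
  expect_equal(b$source, "first-inpatient")

  expect_error(compute_baseline(numeric(0), numeric(0), 0), "empty")
  expect_error(compute_baseline(c(1, 1), c(1, 1), 0), "increasing")
})

test_that("KDIGO staging follows the SCr criteria with half-open ratio bands", {
  expect_equal(stage_aki(1, 3.1, 1.0)$stage, 3L)       # ratio 3.1 >= 3
  expect_equal(stage_aki(1, 1.25, 1.0)$stage, 0L)      # increase 0.25, ratio 1.25
  expect_equal(stage_aki(1, 1.15, 0.8)$stage, 1L)      # increase 0.35 > 0.3
  expect_equal(stage_aki(1, 2.0, 1.0)$stage, 2L)       # ratio exactly 2.0
  expect_equal(stage_aki(1, 4.1, 3.0)$stage, 3L)       # absolute > 4.0 mg/dL
  expect_equal(stage_aki(1, 1.5, 1.0)$stage, 1L)       # ratio exactly 1.5
  expect_equal(stage_aki(1, 2.99, 1.0)$stage, 2L)      # just under stage 3

  s <- stage_aki(c(1, 2, 3), c(1.2, 2.5, 3.4), 1.0)
  expect_equal(s$stage, 3L)
  expect_equal(s$onset_time, 3)                         # first stage-3 crossing
})

test_that("staging equals the brute-force oracle and is monotone", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_scr_series()
    base <- round(runif(1, 0.5, 2.0), 3)
    got <- stage_aki(s$times, s$values, base)
    want <- brute_stage(s$times, s$values, base)
    expect_identical(got$stage, want$stage)
    expect_identical(got$onset_time, want$onset_time)

    # raising one measurement never lowers the stage
    j <- sample(length(s$values), 1)
    bumped <- s$values
    bumped[j] <- bumped[j] + runif(1, 0, 3)
    expect_gte(stage_aki(s$times, bumped, base)$stage, got$stage)

    # unit coherence: umol/L input divided by 88.4 stages identically
    umol <- s$values * 88.4
    expect_identical(stage_aki(s$times, umol / 88.4, base)$stage, got$stage)
  }
})

test_that("exclusion rules fire with the documented reason codes", {
  enc <- data.frame(
    encounter_id = c("A", "B", "C", "D"),
    admission = 0, discharge = 5,
    egfr = c(90, 90, 45, 75),
    stringsAsFactors = FALSE
  )
  scr <- data.frame(
    encounter_id = c("A", "B", "B", "C", "C", "D", "D", "D"),
    time = c(1, 0.25, 1, 0.5, 2, 0.5, 1, 2),
    value = c(1.0, 1.4, 1.0, 1.0, 1.1, 0.9, 1.0, 1.1),
    stringsAsFactors = FALSE
  )
  ex <- apply_exclusions(enc, scr)
  expect_setequal(ex$retained$encounter_id, "D")
  reasons <- setNames(ex$exclusions$reason, ex$exclusions$encounter_id)
  expect_equal(reasons[["A"]], "insufficient_scr")
  expect_equal(reasons[["B"]], "abnormal_admission_scr")
  expect_equal(reasons[["C"]], "low_egfr")
})

test_that("abnormal SCr outside the 24-hour window does not exclude", {
  enc <- data.frame(encounter_id = "A", admission = 0, discharge = 6,
                    egfr = 80, stringsAsFactors = FALSE)
  scr <- data.frame(encounter_id = "A", time = c(0.5, 3), value = c(1.0, 2.5),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(apply_exclusions(enc, scr)$retained), 1L)
})

test_that("matching is exact on gender/race with nearest age in caliper", {
  cases <- data.frame(encounter_id = "c1", age = 60, gender = "F",
                      race = "white", stringsAsFactors = FALSE)
  controls <- data.frame(
    encounter_id = c("k1", "k2"), age = c(58, 70),
    gender = "F", race = "white", stringsAsFactors = FALSE
  )
  m <- match_controls(cases, controls, caliper = 15)
  expect_equal(m$pairs$control_id, "k1")
  expect_equal(m$pairs$age_diff, 2)

  # exact-match constraint unsatisfiable
  m2 <- match_controls(
    data.frame(encounter_id = "c1", age = 40, gender = "M", race = "asian",
               stringsAsFactors = FALSE),
    transform(controls, gender = "F")
  )
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched, "c1")

  expect_error(match_controls(cases, controls, caliper = 0), "caliper")
})

test_that("matching is invariant to control row order and breaks ties by id", {
  cases <- data.frame(encounter_id = c("c1", "c2"), age = c(60, 62),
                      gender = "F", race = "white", stringsAsFactors = FALSE)
  controls <- data.frame(encounter_id = c("k3", "k1", "k2"),
                         age = c(61, 61, 63), gender = "F", race = "white",
                         stringsAsFactors = FALSE)
  m1 <- match_controls(cases, controls)
  m2 <- match_controls(cases, controls[c(2, 3, 1), ])
  expect_identical(m1$pairs, m2$pairs)
  # c1's two gap-1 candidates resolve to the lower encounter id
  expect_equal(m1$pairs$control_id[m1$pairs$case_id == "c1"], "k1")
})

test_that("a compatible 179 + 179 cohort matches completely", {
  sim <- generate_cohort(synthetic_spec(seed = 42))
  built <- build_cohort(sim$encounters, sim$scr)
  expect_equal(nrow(built$pairs), 179L)
  expect_equal(nrow(built$cohort), 358L)
  expect_length(built$unmatched, 0L)
  expect_setequal(unique(built$cohort$stage), c(0L, 3L))
})
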