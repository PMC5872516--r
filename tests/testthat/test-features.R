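test_that("checkpoints sit 24 h before onset and transfer to controls", {
  expect_equal(checkpoint_time(0, 8, onset_time = 5), 4)
  # matched control inherits the case's offset against its own admission
  expect_equal(checkpoint_time(0, 10, onset_time = NA, case_offset = 4), 4)
  # capped at discharge
  expect_equal(checkpoint_time(0, 3, onset_time = NA, case_offset = 4), 3)
  expect_error(checkpoint_time(0, 3), "case_offset")
})

test_that("last value before a checkpoint is strict in time", {
  expect_equal(last_value_before(c(1, 3), c(98.6, 101.0), 4), 101.0)
  expect_true(is.na(last_value_before(c(5, 6), c(1, 2), 4)))
  expect_equal(last_value_before(c(3.999, 4.0), c(7, 9), 4.0), 7)
})

test_that("labs categorize against reference ranges with explicit unknowns", {
  expect_equal(categorize_lab(7.0, 4.0, 11.0), "present-normal")
  expect_equal(categorize_lab(15.2, 4.0, 11.0), "present-abnormal")
  expect_equal(categorize_lab(NA, 4.0, 11.0), "unknown")
  expect_error(categorize_lab(5, 11, 4), "range")
})

test_that("vital bins follow the printed categories under half-open tiling", {
  expect_equal(bin_vital("bmi", 26.0), "[25.0-29.9]")
  expect_equal(bin_vital("pulse", 50), "[50-65]")
  expect_equal(bin_vital("diastolic_bp", 99.5), "[90-99]")
  expect_equal(bin_vital("temperature", 99.5), "[99.5-104.0]")
  expect_equal(bin_vital("systolic_bp", NA), "Unknown")
  expect_error(bin_vital("heightt", 1), "unknown vital")

  # every finite value maps to exactly one non-Unknown bin
  for (v in names(vital_states())) {
    grid <- seq(-5, 220, by = 0.5)
    lab <- bin_vital(v, grid)
    expect_false(any(lab == "Unknown"))
    expect_true(all(lab %in% setdiff(vital_states(v), "Unknown")))
  }
})

test_that("binary encoding honors checkpoint and time-independence", {
  expect_equal(encode_binary(times = 2, checkpoint = 4), "yes")
  expect_equal(encode_binary(times = 5, checkpoint = 4), "no")
  expect_equal(encode_binary(times = 5, checkpoint = 4, time_dependent = FALSE), "yes")
  expect_equal(encode_binary(numeric(0), 4), "no")
})

test_that("assemble_matrix freezes features at the checkpoint", {
  tc <- tiny_cohort_tables()
  dict <- data.frame(
    name = c("med_a", "wbc", "pulse", "comorb_a"),
    category = c("medication", "lab", "vitals", "comorbidity"),
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    encounter_id = c("C1", "C1", "C1", "K1", "K1"),
    time = c(2, 1, 6, 3.5, 5),
    feature = c("med_a", "wbc", "wbc", "wbc", "comorb_a"),
    category = c("medication", "lab", "lab", "lab", "comorbidity"),
    value = c(1, 15.2, 7.0, 7.0, 1),
    stringsAsFactors = FALSE
  )
  fm <- assemble_matrix(tc$cohort, tc$encounters, events, dict)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm$data), c(2L, 7L))  # 3 demographics + 4 dictionary
  expect_equal(fm$y, c(1L, 0L))
  # case checkpoint = day 4: med at day 2 counts, wbc last value day 1 (15.2)
  expect_equal(as.character(fm$data["C1", "med_a"]), "yes")
  expect_equal(as.character(fm$data["C1", "wbc"]), "present-abnormal")
  # control checkpoint transfers to day 4: wbc at 3.5 visible, comorb at 5 is
  # time-independent so still yes, med absent
  expect_equal(as.character(fm$data["K1", "wbc"]), "present-normal")
  expect_equal(as.character(fm$data["K1", "comorb_a"]), "yes")
  expect_equal(as.character(fm$data["K1", "med_a"]), "no")
  # vitals without events resolve to Unknown; no NA cells anywhere
  expect_equal(as.character(fm$data$pulse), c("Unknown", "Unknown"))
  expect_false(anyNA(fm$data))
})

test_that("assemble_matrix is permutation-equivariant and handles empty cohorts", {
  sim <- generate_cohort(synthetic_spec(n_cases = 8, n_controls = 8,
                                        n_features = 30, seed = 9))
  built <- build_cohort(sim$encounters, sim$scr)
  fm1 <- assemble_matrix(built, sim$encounters, sim$events, sim$features)
  shuffled <- built$cohort[rev(seq_len(nrow(built$cohort))), ]
  fm2 <- assemble_matrix(shuffled, sim$encounters, sim$events, sim$features)
  ord <- match(fm1$encounter_id, fm2$encounter_id)
  for (nm in names(fm1$data)) {
    expect_identical(as.character(fm1$data[[nm]]),
                     as.character(fm2$data[[nm]][ord]))
  }
  # all state indices valid for their alphabets
  for (j in seq_along(fm1$data)) {
    expect_true(all(as.integer(fm1$data[[j]]) <= nlevels(fm1$data[[j]])))
  }
  empty <- assemble_matrix(built$cohort[0, ], sim$encounters, sim$events,
                           sim$features)
  expect_equal(nrow(empty$data), 0L)
})

test_that("duplicate feature names are rejected", {
  tc <- tiny_cohort_tables()
  dict <- data.frame(name = c("med_a", "med_a"),
                     category = c("medication", "medication"),
                     stringsAsFactors = FALSE)
  ev <- data.frame(encounter_id = character(0), time = numeric(0),
                   feature = character(0), category = character(0),
                   value = numeric(0), stringsAsFactors = FALSE)
  expect_error(assemble_matrix(tc$cohort, tc$encounters, ev, dict), "duplicate")
})
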