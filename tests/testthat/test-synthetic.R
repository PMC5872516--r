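test_that("spec validation reports the offending field", {
  expect_error(synthetic_spec(noise_flip_prob = 0.5), "noise_flip_prob")
  expect_error(synthetic_spec(n_features = 10), "n_features")
  expect_error(synthetic_spec(planted_causes = c(not_a_feature = 3)),
               "planted_causes")
  edges <- data.frame(from = c("med_010", "med_011"),
                      to = c("med_011", "med_010"), stringsAsFactors = FALSE)
  expect_error(synthetic_spec(confounder_edges = edges), "acyclic")
})

test_that("equal seeds give identical cohorts, different seeds differ", {
  s1 <- generate_cohort(synthetic_spec(n_cases = 15, n_controls = 15,
                                       n_features = 30, seed = 7))
  s2 <- generate_cohort(synthetic_spec(n_cases = 15, n_controls = 15,
                                       n_features = 30, seed = 7))
  expect_identical(s1$encounters, s2$encounters)
  expect_identical(s1$scr, s2$scr)
  expect_identical(s1$events, s2$events)
  s3 <- generate_cohort(synthetic_spec(n_cases = 15, n_controls = 15,
                                       n_features = 30, seed = 8))
  expect_false(identical(s1$scr, s3$scr))
})

test_that("an empty case arm yields an all-control cohort", {
  sim <- generate_cohort(synthetic_spec(n_cases = 0, n_controls = 10,
                                        n_features = 30, seed = 3))
  expect_equal(nrow(sim$encounters), 10L)
  expect_true(all(sim$truth$stage_intent$stage == 0L))
})

test_that("independent re-staging reproduces every intended stage", {
  sim <- generate_cohort(synthetic_spec(n_cases = 25, n_controls = 25,
                                        n_features = 30, seed = 11))
  built <- build_cohort(sim$encounters, sim$scr)
  got <- built$stages
  want <- sim$truth$stage_intent
  m <- merge(got, want, by = "encounter_id")
  expect_equal(nrow(m), 50L)                       # nothing excluded
  expect_true(all(m$stage.x == m$stage.y))
  # stage-3 onsets land on the intended day
  case <- m[m$stage.y == 3L, ]
  expect_equal(case$onset_time.x, case$onset_time.y)
})

test_that("network truth records the Markov blanket by construction", {
  # chain A -> y -> B
  net <- generate_discrete_network(
    synthetic_spec(n_features = 30, n_planted = 1, n_children = 1, seed = 2),
    n = 100
  )
  expect_length(net$mb, 2L)
  expect_true(all(net$causes %in% net$mb))

  # parents {A, B}, child C, spouse S => MB has 4 members
  net2 <- generate_discrete_network(
    synthetic_spec(n_features = 30, n_planted = 2, n_children = 1,
                   n_spouses = 1, seed = 2),
    n = 100
  )
  expect_length(net2$mb, 4L)
})

test_that("planted causes show positive marginal odds ratios", {
  net <- generate_discrete_network(synthetic_spec(n_planted = 4, seed = 1),
                                   n = 2000)
  for (cz in net$causes) {
    e <- net$x[[cz]] == "yes"
    a <- sum(e & net$y == 1); b <- sum(e & net$y == 0)
    c_ <- sum(!e & net$y == 1); d <- sum(!e & net$y == 0)
    expect_gt((a * d) / (b * c_), 1)               # 2x2 cross-ratio oracle
  }
})

test_that("unit effect multipliers leave no planted signal", {
  net <- generate_discrete_network(
    synthetic_spec(effect_multiplier = 1.0, seed = 13), n = 5000
  )
  for (cz in net$causes) {
    e <- net$x[[cz]] == "yes"
    r <- oracle_or(sum(e & net$y == 1), sum(e & net$y == 0),
                   sum(!e & net$y == 1), sum(!e & net$y == 0))
    expect_lt(abs(log(r$or)), 0.35)
  }
})

test_that("generated feature states are recoverable through the builder", {
  sim <- generate_cohort(synthetic_spec(n_cases = 20, n_controls = 20,
                                        n_features = 40, seed = 17))
  built <- build_cohort(sim$encounters, sim$scr)
  fm <- assemble_matrix(built, sim$encounters, sim$events, sim$features)
  truthX <- sim$truth$states[match(fm$encounter_id,
                                   sim$encounters$encounter_id), ]
  for (nm in sim$features$name) {
    expect_identical(as.integer(fm$data[[nm]]), unname(truthX[, nm]))
  }
})
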