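# Independent oracles, kept deliberately separate from the package's code
# paths: a literal per-measurement transcription of the KDIGO staging rules,
# and a direct transcription of the odds-ratio / CI formulas.

# Brute-force staging: evaluate every criterion on every measurement with an
# explicit if-chain, then take the maximum stage and the first onset.
brute_stage <- function(times, values, baseline) {
  per <- integer(length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    r <- v / baseline
    s <- 0L
    if ((v - baseline) > 0.3) s <- max(s, 1L)
    if (r >= 1.5 && r < 2.0) s <- max(s, 1L)
    if (r >= 2.0 && r < 3.0) s <- max(s, 2L)
    if (r >= 3.0) s <- max(s, 3L)
    if (v > 4.0) s <- max(s, 3L)
    per[i] <- s
  }
  stage <- max(c(0L, per))
  onset <- if (stage == 0L) NA_real_ else times[which(per == stage)[1L]]
  list(stage = stage, onset_time = onset)
}

# Direct formula transcription: OR = ad/bc, Wald CI on the log scale,
# Haldane +0.5 when any cell is empty.
oracle_or <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se))
}

# A random but valid SCr series (strictly increasing times, positive values).
random_scr_series <- function(n_meas = NULL) {
  n <- n_meas %||% sample(2:12, 1)
  list(
    times = sort(runif(n, 0, 10)),
    values = round(runif(n, 0.3, 6.0), 3)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny two-arm cohort tables for feature-builder tests.
tiny_cohort_tables <- function() {
  encounters <- data.frame(
    encounter_id = c("C1", "K1"),
    age = c(60, 61), gender = c("F", "F"), race = c("white", "white"),
    admission = 0, discharge = c(8, 10), egfr = c(90, 85),
    stringsAsFactors = FALSE
  )
  cohort <- data.frame(
    encounter_id = c("C1", "K1"), arm = c("case", "control"),
    stage = c(3L, 0L), onset_time = c(5, NA), pair_id = c(1L, 1L),
    stringsAsFactors = FALSE
  )
  list(encounters = encounters, cohort = cohort)
}
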