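#' Baseline serum creatinine for an encounter
#'
#' The baseline is the last SCr measurement inside the 48-hour window ending
#' at hospital admission; when no pre-admission measurement falls in that
#' window, the first measurement at or after admission is used instead.
#'
#' All timestamps in this package are numeric days (fractions allowed) on a
#' common axis; SCr values are mg/dL.
#'
#' @param times numeric vector of measurement timestamps (days), strictly
#'   increasing.
#' @param values numeric vector of SCr values (mg/dL), positive, parallel to
#'   `times`.
#' @param admission admission timestamp (days).
#' @return A list of class `baseline_scr` with elements `value` (mg/dL) and
#'   `source` (`"pre-admission-window"` or `"first-inpatient"`).
#' @examples
#' compute_baseline(times = c(-1.25, 0.1), values = c(1.1, 0.9), admission = 0)
#' @export
compute_baseline <- function(times, values, admission) {
  if (length(times) == 0L) stop("empty SCr series", call. = FALSE)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(values <= 0)) stop("SCr values must be positive", call. = FALSE)
  pre <- which(times >= admission - 2 & times < admission)
  if (length(pre) > 0L) {
    out <- list(value = values[pre[length(pre)]], source = "pre-admission-window")
  } else {
    post <- which(times >= admission)
    if (length(post) == 0L) {
      stop("no SCr measurement in the baseline window or after admission", call. = FALSE)
    }
    out <- list(value = values[post[1L]], source = "first-inpatient")
  }
  class(out) <- "baseline_scr"
  out
}

#' KDIGO stage of an encounter from inpatient serum creatinine
#'
#' Applies the KDIGO SCr criteria to every inpatient measurement and returns
#' the maximum stage reached, together with the first time that stage's
#' criterion holds. Criteria (thresholds canonical in mg/dL):
#' \describe{
#'   \item{Stage 1}{increase over baseline > 0.3 mg/dL, or ratio to baseline
#'     in \[1.5, 2.0)}
#'   \item{Stage 2}{ratio in \[2.0, 3.0)}
#'   \item{Stage 3}{ratio >= 3.0, or absolute SCr > 4.0 mg/dL}
#' }
#' The printed ratio bands ("1.5--1.9", "2.0--2.9") are implemented as
#' half-open intervals so the bands tile the line without gaps. Inputs in
#' umol/L should be divided by 88.4 before calling.
#'
#' @param times inpatient measurement timestamps (days).
#' @param values SCr values (mg/dL).
#' @param baseline a `baseline_scr` object or a positive number (mg/dL).
#' @return A list of class `aki_stage` with elements `stage` (0--3) and
#'   `onset_time` (timestamp of the first measurement satisfying the maximal
#'   stage's criterion; `NA` for stage 0).
#' @examples
#' stage_aki(times = 1:3, values = c(1.0, 2.1, 3.2), baseline = 1.0)
#' @export
stage_aki <- function(times, values, baseline) {
  b <- if (inherits(baseline, "baseline_scr")) baseline$value else baseline
  stopifnot(is.numeric(b), length(b) == 1L, b > 0)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  ratio <- values / b
  crit3 <- ratio >= 3.0 | values > 4.0
  crit2 <- ratio >= 2.0 & ratio < 3.0
  crit1 <- (values - b) > 0.3 | (ratio >= 1.5 & ratio < 2.0)
  stage <- if (any(crit3)) 3L else if (any(crit2)) 2L else if (any(crit1)) 1L else 0L
  onset <- switch(stage + 1L,
    NA_real_,
    times[which(crit1)[1L]],
    times[which(crit2)[1L]],
    times[which(crit3)[1L]]
  )
  structure(list(stage = stage, onset_time = onset), class = "aki_stage")
}

#' Apply cohort exclusion rules
#'
#' Removes encounters that cannot be staged or that show pre-existing kidney
#' dysfunction: fewer than two SCr measurements (`insufficient_scr`), eGFR
#' below 60 mL/min/1.73 m2 (`low_egfr`), or any SCr above 1.3 mg/dL within
#' 24 h of admission (`abnormal_admission_scr`). The first rule that fires is
#' the recorded reason.
#'
#' @param encounters data frame with columns `encounter_id`, `admission`,
#'   `discharge` (and optionally `egfr` if `egfr` is `NULL`).
#' @param scr data frame with columns `encounter_id`, `time`, `value`.
#' @param egfr optional data frame (`encounter_id`, `egfr`); falls back to an
#'   `egfr` column of `encounters`. Encounters without an eGFR value are not
#'   excluded on that rule.
#' @return list with `retained` (subset of `encounters`) and `exclusions`
#'   (data frame `encounter_id`, `reason`).
#' @export
apply_exclusions <- function(encounters, scr, egfr = NULL) {
  stopifnot(is.data.frame(encounters), is.data.frame(scr))
  ids <- encounters$encounter_id
  n_scr <- table(factor(scr$encounter_id, levels = ids))
  egfr_val <- rep(NA_real_, length(ids))
  if (is.null(egfr) && "egfr" %in% names(encounters)) {
    egfr_val <- encounters$egfr
  } else if (is.data.frame(egfr)) {
    egfr_val <- egfr$egfr[match(ids, egfr$encounter_id)]
  }
  adm <- encounters$admission[match(scr$encounter_id, ids)]
  early_abn <- scr$value > 1.3 & scr$time >= adm & scr$time <= adm + 1
  abn_ids <- unique(scr$encounter_id[early_abn])

  reason <- rep(NA_character_, length(ids))
  reason[as.vector(n_scr) < 2L] <- "insufficient_scr"
  low <- is.na(reason) & !is.na(egfr_val) & egfr_val < 60
  reason[low] <- "low_egfr"
  abn <- is.na(reason) & ids %in% abn_ids
  reason[abn] <- "abnormal_admission_scr"

  keep <- is.na(reason)
  list(
    retained = encounters[keep, , drop = FALSE],
    exclusions = data.frame(
      encounter_id = ids[!keep], reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Match stage-3 cases to stage-0 controls on demographics
#'
#' 1:1 matching with exact agreement on gender and race and nearest age within
#' a caliper. Matching is greedy, most-constrained case first (fewest eligible
#' controls); ties on age gap are broken by the lowest control encounter id,
#' ties on constraint by the lowest case encounter id, so the result does not
#' depend on row order.
#'
#' @param cases,controls data frames with columns `encounter_id`, `age`,
#'   `gender`, `race`.
#' @param caliper maximum allowed absolute age difference in years (> 0).
#' @return list with `pairs` (data frame `pair_id`, `case_id`, `control_id`,
#'   `age_diff`) and `unmatched` (case encounter ids without a pair).
#' @export
match_controls <- function(cases, controls, caliper = 5) {
  if (!is.numeric(caliper) || length(caliper) != 1L || caliper <= 0) {
    stop("caliper must be a positive number", call. = FALSE)
  }
  stopifnot(is.data.frame(cases), is.data.frame(controls))
  nc <- nrow(cases)
  if (nc == 0L) {
    return(list(pairs = data.frame(
      pair_id = integer(), case_id = character(),
      control_id = character(), age_diff = numeric(),
      stringsAsFactors = FALSE
    ), unmatched = character()))
  }
  elig <- lapply(seq_len(nc), function(i) {
    which(controls$gender == cases$gender[i] &
            controls$race == cases$race[i] &
            abs(controls$age - cases$age[i]) <= caliper)
  })
  ord <- order(vapply(elig, length, 1L), cases$encounter_id)
  used <- rep(FALSE, nrow(controls))
  out <- vector("list", nc)
  unmatched <- character()
  pair <- 0L
  for (i in ord) {
    cand <- elig[[i]][!used[elig[[i]]]]
    if (length(cand) == 0L) {
      unmatched <- c(unmatched, as.character(cases$encounter_id[i]))
      next
    }
    gap <- abs(controls$age[cand] - cases$age[i])
    best <- cand[order(gap, controls$encounter_id[cand])][1L]
    used[best] <- TRUE
    pair <- pair + 1L
    out[[pair]] <- data.frame(
      case_id = as.character(cases$encounter_id[i]),
      control_id = as.character(controls$encounter_id[best]),
      age_diff = abs(controls$age[best] - cases$age[i]),
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (pair > 0L) do.call(rbind, out[seq_len(pair)]) else
    data.frame(case_id = character(), control_id = character(),
               age_diff = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$case_id), , drop = FALSE]
  pairs <- cbind(pair_id = seq_len(nrow(pairs)), pairs)
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = sort(unmatched))
}

#' Build a matched stage-3 vs stage-0 cohort from raw tables
#'
#' Orchestrates exclusions, baseline determination, KDIGO staging and
#' demographic matching. Encounters staging 1 or 2 are set aside: the design
#' contrasts stage-3 cases with encounters that never met any AKI criterion.
#'
#' @param encounters data frame: `encounter_id`, `age`, `gender`, `race`,
#'   `admission`, `discharge` and optionally `egfr`.
#' @param scr data frame: `encounter_id`, `time`, `value` (mg/dL).
#' @param egfr optional eGFR table, see [apply_exclusions()].
#' @param caliper age caliper in years for [match_controls()].
#' @return list of class `aki_cohort`: `cohort` (data frame `encounter_id`,
#'   `arm`, `stage`, `onset_time`, `pair_id`), `pairs`, `unmatched`,
#'   `exclusions`, `stages` (all staged encounters).
#' @export
build_cohort <- function(encounters, scr, egfr = NULL, caliper = 5) {
  ex <- apply_exclusions(encounters, scr, egfr)
  enc <- ex$retained
  scr <- scr[order(scr$encounter_id, scr$time), , drop = FALSE]
  idx <- split(seq_len(nrow(scr)), scr$encounter_id)

  stage_one <- function(id, admission, discharge) {
    rows <- idx[[as.character(id)]]
    tt <- scr$time[rows]; vv <- scr$value[rows]
    base <- compute_baseline(tt, vv, admission)
    inp <- tt >= admission & tt <= discharge
    st <- stage_aki(tt[inp], vv[inp], base)
    c(stage = st$stage, onset = st$onset_time)
  }
  staged <- t(mapply(stage_one, enc$encounter_id, enc$admission, enc$discharge))
  stages <- data.frame(
    encounter_id = enc$encounter_id,
    stage = as.integer(staged[, "stage"]),
    onset_time = staged[, "onset"],
    stringsAsFactors = FALSE
  )
  cases <- enc[stages$stage == 3L, , drop = FALSE]
  controls <- enc[stages$stage == 0L, , drop = FALSE]
  m <- match_controls(cases, controls, caliper)
  p <- m$pairs
  cohort <- rbind(
    data.frame(encounter_id = p$case_id, arm = "case", pair_id = p$pair_id,
               stringsAsFactors = FALSE),
    data.frame(encounter_id = p$control_id, arm = "control", pair_id = p$pair_id,
               stringsAsFactors = FALSE)
  )
  cohort$stage <- stages$stage[match(cohort$encounter_id, stages$encounter_id)]
  cohort$onset_time <- stages$onset_time[match(cohort$encounter_id, stages$encounter_id)]
  cohort <- cohort[order(cohort$pair_id, cohort$arm), c(
    "encounter_id", "arm", "stage", "onset_time", "pair_id"
  )]
  rownames(cohort) <- NULL
  structure(
    list(cohort = cohort, pairs = m$pairs, unmatched = m$unmatched,
         exclusions = ex$exclusions, stages = stages),
    class = "aki_cohort"
  )
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat("Matched AKI cohort:", sum(x$cohort$arm == "case"), "stage-3 cases,",
      sum(x$cohort$arm == "control"), "matched controls\n")
  if (length(x$unmatched)) {
    cat("Unmatched cases:", length(x$unmatched), "\n")
  }
  if (nrow(x$exclusions)) {
    cat("Exclusions:\n")
    print(table(x$exclusions$reason))
  }
  invisible(x)
}
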