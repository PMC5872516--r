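# Discretization of vitals and labs, checkpoint logic, and categorical
# encodings used to build the feature matrix.

# Bin definitions for the five vital signs. Printed bin labels leave gaps at
# their boundaries (e.g. "[90-99]" then "> 100"); bins are implemented as a
# left-closed right-open tiling of the real line with breaks at each printed
# lower bound and at the "greater-than" threshold, so every finite value maps
# to exactly one bin.
.vital_bins <- list(
  bmi = list(
    breaks = c(18.5, 25.0, 30.0),
    labels = c("< 18.5", "[18.5-24.9]", "[25.0-29.9]", "> 30.0")
  ),
  diastolic_bp = list(
    breaks = c(80, 90, 100),
    labels = c("< 80", "[80-89]", "[90-99]", "> 100")
  ),
  systolic_bp = list(
    breaks = c(120, 140, 160),
    labels = c("< 120", "[120-139]", "[140-159]", "> 160")
  ),
  pulse = list(
    breaks = c(50, 66, 81, 100),
    labels = c("< 50", "[50-65]", "[66-80]", "[81-100]", "> 100")
  ),
  temperature = list(
    breaks = c(95.0, 97.7, 99.5, 104.0),
    labels = c("< 95.0", "[95.0-97.6]", "[97.7-99.5]", "[99.5-104.0]", "> 104.0")
  )
)

#' Vital-sign bin labels
#'
#' State alphabets for the five vital signs (the discretization bins plus
#' `"Unknown"`).
#'
#' @param name optional vital name; omit for the full list.
#' @return A character vector of state labels, or a named list of them.
#' @export
vital_states <- function(name = NULL) {
  all <- lapply(.vital_bins, function(b) c(b$labels, "Unknown"))
  if (is.null(name)) return(all)
  if (!name %in% names(all)) stop(sprintf("unknown vital '%s'", name), call. = FALSE)
  all[[name]]
}

#' Discretize a vital-sign value
#'
#' Maps a measured value of BMI, blood pressure, pulse or temperature to its
#' categorical bin; missing values map to `"Unknown"`.
#'
#' @param name one of `"bmi"`, `"diastolic_bp"`, `"systolic_bp"`, `"pulse"`,
#'   `"temperature"`.
#' @param value numeric vector of measurements (NA allowed).
#' @return character vector of bin labels.
#' @examples
#' bin_vital("bmi", c(26, 17.2, NA))
#' @export
bin_vital <- function(name, value) {
  if (!name %in% names(.vital_bins)) {
    stop(sprintf("unknown vital '%s'", name), call. = FALSE)
  }
  b <- .vital_bins[[name]]
  out <- rep("Unknown", length(value))
  ok <- !is.na(value)
  out[ok] <- b$labels[findInterval(value[ok], b$breaks) + 1L]
  out
}

#' Default laboratory reference ranges
#'
#' Conventional adult reference intervals for the fourteen laboratory tests
#' carried by the cohort design (albumin g/dL; ALT/AST/CK U/L; ammonia
#' umol/L; bilirubin/BUN/calcium/glucose mg/dL; CK-MB/troponin ng/mL; lipase
#' U/L; platelets 10^3/uL; WBC 10^3/uL). Override via the `ranges` argument
#' of [assemble_matrix()] for site-specific intervals.
#'
#' @return data frame with columns `name`, `low`, `high`.
#' @export
lab_reference_ranges <- function() {
  data.frame(
    name = c("albumin", "alt", "ast", "ammonia", "bilirubin", "bun", "calcium",
             "ckmb", "ck", "glucose", "lipase", "platelets", "troponin", "wbc"),
    low  = c(3.5,  7, 10, 15, 0.1,  7,  8.5, 0,  22,  70,  0, 150, 0,    4.0),
    high = c(5.0, 56, 40, 45, 1.2, 20, 10.5, 5, 198, 140, 160, 450, 0.04, 11.0),
    stringsAsFactors = FALSE
  )
}

#' Categorize a lab value against a reference range
#'
#' @param value numeric vector (NA = not measured).
#' @param low,high finite reference range bounds, `low < high`.
#' @return character vector over `{"present-normal", "present-abnormal",
#'   "unknown"}`.
#' @examples
#' categorize_lab(c(7.0, 15.2, NA), low = 4.0, high = 11.0)
#' @export
categorize_lab <- function(value, low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("reference range must satisfy finite low < high", call. = FALSE)
  }
  out <- rep("unknown", length(value))
  ok <- !is.na(value)
  out[ok] <- ifelse(value[ok] >= low & value[ok] <= high,
                    "present-normal", "present-abnormal")
  out
}

#' State labels for lab features
#' @return character vector of the three lab states.
#' @export
lab_states <- function() c("present-normal", "present-abnormal", "unknown")

#' Prediction checkpoint for an encounter
#'
#' Cases are frozen 24 hours before stage-3 onset. A matched control inherits
#' its case's checkpoint-to-admission offset, applied to the control's own
#' admission and capped at the control's discharge (controls have no onset of
#' their own). A checkpoint falling before admission is an error condition
#' handled upstream by dropping the encounter.
#'
#' @param admission,discharge encounter timestamps (days).
#' @param onset_time stage-3 onset for cases, `NA` for controls.
#' @param case_offset for controls: the matched case's checkpoint minus that
#'   case's admission (days).
#' @return checkpoint timestamp (days).
#' @export
checkpoint_time <- function(admission, discharge, onset_time = NA, case_offset = NA) {
  if (!is.na(onset_time)) {
    return(onset_time - 1)
  }
  if (is.na(case_offset)) stop("controls require case_offset", call. = FALSE)
  min(admission + case_offset, discharge)
}

#' Last recorded value strictly before a checkpoint
#'
#' @param times event timestamps.
#' @param values event values, parallel to `times`.
#' @param checkpoint timestamp.
#' @return the value of the latest event with `time < checkpoint`, or `NA` if
#'   none exists.
#' @export
last_value_before <- function(times, values, checkpoint) {
  keep <- which(times < checkpoint)
  if (length(keep) == 0L) return(NA)
  values[keep[which.max(times[keep])]]
}

#' Binary yes/no encoding of event presence
#'
#' Medication, history, comorbidity and admission-diagnosis features take
#' `"yes"` when at least one qualifying event exists at or before the
#' checkpoint; time-independent categories count events at any time.
#'
#' @param times event timestamps (may be empty).
#' @param checkpoint timestamp.
#' @param time_dependent if `FALSE`, events qualify regardless of time.
#' @return `"yes"` or `"no"`.
#' @export
encode_binary <- function(times, checkpoint, time_dependent = TRUE) {
  hit <- if (time_dependent) any(times <= checkpoint) else length(times) > 0L
  if (isTRUE(hit)) "yes" else "no"
}
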