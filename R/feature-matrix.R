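# The encounters x features categorical matrix and its constructor from raw
# event streams.

.time_dependent_categories <- c("vitals", "lab", "medication", "history")
.binary_categories <- c("medication", "history", "comorbidity", "admission_dx")

.age_bands <- sprintf("[%d-%d]", seq(10, 90, 10), seq(19, 99, 10))

age_band <- function(age) {
  d <- pmin(pmax(floor(age / 10) * 10, 10), 90)
  sprintf("[%d-%d]", d, d + 9)
}

#' Construct a feature matrix from categorized columns
#'
#' Lower-level constructor used both by [assemble_matrix()] and directly on
#' pre-categorized data (every column a factor whose levels are the feature's
#' full state alphabet; no `NA` cells - missingness must already be an
#' explicit state).
#'
#' @param data data frame of factors, one row per encounter.
#' @param y binary outcome vector (0/1), one per row; 1 = stage-3 case.
#' @param categories optional character vector of feature categories,
#'   recycled as `"unknown"` when absent.
#' @param time_dependent optional logical vector per feature.
#' @return An object of class `feature_matrix` with elements `data`, `y`,
#'   `features` (name, category, m, time_dependent, states).
#' @export
feature_matrix <- function(data, y, categories = NULL, time_dependent = NULL) {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(names(data))) stop("duplicate feature names", call. = FALSE)
  if (length(y) != nrow(data)) stop("y must have one value per row", call. = FALSE)
  y <- as.integer(y)
  if (nrow(data) > 0 && !all(y %in% c(0L, 1L))) {
    stop("y must be binary 0/1", call. = FALSE)
  }
  data[] <- lapply(data, function(col) if (is.factor(col)) col else factor(col))
  if (anyNA(data)) stop("feature cells must not be NA; encode missingness as a state", call. = FALSE)
  m <- vapply(data, nlevels, 1L)
  if (ncol(data) > 0 && any(m < 2L)) {
    stop(sprintf("feature '%s' has fewer than 2 states", names(data)[which(m < 2L)[1L]]),
         call. = FALSE)
  }
  feats <- data.frame(
    name = names(data),
    category = categories %||% rep("unknown", ncol(data)),
    m = as.integer(m),
    time_dependent = time_dependent %||% rep(NA, ncol(data)),
    states = vapply(data, function(col) paste(levels(col), collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  rownames(feats) <- NULL
  structure(list(data = data, y = y, features = feats), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$data), "encounters x", ncol(x$data), "features;",
      sum(x$y), "cases /", sum(x$y == 0L), "controls\n")
  tab <- table(x$features$category)
  cat("Categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' Assemble the categorical feature matrix for a matched cohort
#'
#' Freezes every time-dependent feature at the encounter's checkpoint (24 h
#' before stage-3 onset for cases; the matched case's offset, capped at
#' discharge, for controls), discretizes labs against reference ranges and
#' vitals against their bins, encodes event-presence features as yes/no, and
#' derives the three demographic features (decade age band, gender, race)
#' from the encounters table. Missing measurements become explicit
#' "unknown"/"Unknown" states so no cell is ever empty.
#'
#' @param cohort an `aki_cohort` object from [build_cohort()], or its
#'   `cohort` data frame.
#' @param encounters encounters table (`encounter_id`, `age`, `gender`,
#'   `race`, `admission`, `discharge`).
#' @param events long feature-event table (`encounter_id`, `time`, `feature`,
#'   `category`, `value`); `value` numeric for labs/vitals, ignored for
#'   binary categories.
#' @param features feature dictionary (`name`, `category`) declaring every
#'   non-demographic feature column, including ones with no events.
#' @param ranges lab reference ranges, see [lab_reference_ranges()].
#' @return A `feature_matrix`; encounters whose checkpoint would precede
#'   admission are dropped and listed in its `dropped` element.
#' @export
assemble_matrix <- function(cohort, encounters, events, features,
                            ranges = lab_reference_ranges()) {
  if (inherits(cohort, "aki_cohort")) cohort <- cohort$cohort
  stopifnot(is.data.frame(cohort), is.data.frame(events), is.data.frame(features))
  if (anyDuplicated(features$name)) stop("duplicate feature names", call. = FALSE)
  if (nrow(cohort) == 0L) {
    return(feature_matrix(data.frame(), integer(0)))
  }
  enc_i <- match(cohort$encounter_id, encounters$encounter_id)
  adm <- encounters$admission[enc_i]
  dis <- encounters$discharge[enc_i]

  # checkpoints: cases from onset, controls from the paired case's offset
  cp <- rep(NA_real_, nrow(cohort))
  is_case <- cohort$arm == "case"
  cp[is_case] <- cohort$onset_time[is_case] - 1
  off <- (cp[is_case] - adm[is_case])[match(cohort$pair_id[!is_case],
                                            cohort$pair_id[is_case])]
  cp[!is_case] <- pmin(adm[!is_case] + off, dis[!is_case])

  bad <- is.na(cp) | cp < adm
  dropped <- data.frame(
    encounter_id = cohort$encounter_id[bad],
    reason = rep("checkpoint_before_admission", sum(bad)),
    stringsAsFactors = FALSE
  )
  keep <- !bad
  cohort <- cohort[keep, , drop = FALSE]
  cp <- cp[keep]; enc_i <- enc_i[keep]
  ids <- cohort$encounter_id
  n <- length(ids)

  ev <- events[events$encounter_id %in% ids, , drop = FALSE]
  ev$row <- match(ev$encounter_id, ids)
  ev$cp <- cp[ev$row]

  cells <- list()
  categ <- character(0)
  tdep <- logical(0)
  add_col <- function(name, values, states, category, td) {
    cells[[name]] <<- factor(values, levels = states)
    categ <<- c(categ, category)
    tdep <<- c(tdep, td)
  }

  # demographics from the encounters table (time-independent)
  add_col("age_band", age_band(encounters$age[enc_i]), .age_bands, "demographics", FALSE)
  # alphabets pad the observed values with the canonical categories so a
  # single-gender cohort still yields a well-formed (>= 2 state) feature
  add_col("gender", as.character(encounters$gender[enc_i]),
          sort(union(as.character(encounters$gender), c("F", "M"))),
          "demographics", FALSE)
  add_col("race", as.character(encounters$race[enc_i]),
          sort(union(as.character(encounters$race),
                     c("white", "black", "asian", "hispanic", "other"))),
          "demographics", FALSE)

  for (k in seq_len(nrow(features))) {
    fname <- features$name[k]
    fcat <- features$category[k]
    td <- fcat %in% .time_dependent_categories
    fe <- ev[ev$feature == fname, , drop = FALSE]
    if (fcat %in% .binary_categories) {
      hit <- if (td) fe$row[fe$time <= fe$cp] else fe$row
      vals <- rep("no", n)
      vals[unique(hit)] <- "yes"
      add_col(fname, vals, c("no", "yes"), fcat, td)
    } else if (fcat == "lab") {
      ri <- match(fname, ranges$name)
      if (is.na(ri)) stop(sprintf("no reference range for lab '%s'", fname), call. = FALSE)
      raw <- rep(NA_real_, n)
      fe <- fe[fe$time < fe$cp, , drop = FALSE]
      if (nrow(fe)) {
        fe <- fe[order(fe$time), , drop = FALSE]
        last <- !duplicated(fe$row, fromLast = TRUE)
        raw[fe$row[last]] <- as.numeric(fe$value[last])
      }
      add_col(fname, categorize_lab(raw, ranges$low[ri], ranges$high[ri]),
              lab_states(), "lab", TRUE)
    } else if (fcat == "vitals") {
      raw <- rep(NA_real_, n)
      fe <- fe[fe$time < fe$cp, , drop = FALSE]
      if (nrow(fe)) {
        fe <- fe[order(fe$time), , drop = FALSE]
        last <- !duplicated(fe$row, fromLast = TRUE)
        raw[fe$row[last]] <- as.numeric(fe$value[last])
      }
      add_col(fname, bin_vital(fname, raw), vital_states(fname), "vitals", TRUE)
    } else {
      stop(sprintf("unknown feature category '%s'", fcat), call. = FALSE)
    }
  }

  data <- as.data.frame(cells, optional = TRUE, stringsAsFactors = FALSE)
  rownames(data) <- ids
  fm <- feature_matrix(data, as.integer(cohort$arm == "case"),
                       categories = categ, time_dependent = tdep)
  fm$encounter_id <- ids
  fm$checkpoint <- cp
  fm$dropped <- dropped
  fm
}
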