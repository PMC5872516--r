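# End-to-end orchestration. Every stage reads only files written by earlier
# stages into the run directory, so a run is auditable (and resumable) from
# its outputs alone.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

.read_csv <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE, ...)
}

#' Configuration for a pipeline run
#'
#' Exactly one of `synthetic` (a [synthetic_spec()]) or `inputs` (paths to
#' `encounters`, `scr`, `events`, `features` CSV files in the package's data
#' dictionary) must be provided.
#'
#' @param synthetic a `synthetic_spec`, or `NULL` when analysing real tables.
#' @param inputs named list of CSV paths, or `NULL` when simulating.
#' @param alpha shared significance level in (0, 1).
#' @param max_cond_size conditioning-set cap for structure learning.
#' @param max_set_size cause-set cap for direction learning.
#' @param caliper age caliper (years) for matching.
#' @param k_folds cross-validation folds.
#' @param models classifier names for the evaluation stage.
#' @param eval_all_features also evaluate the full feature set (the
#'   dimension-reduction comparison arm).
#' @param params classifier hyperparameter overrides, see [run_cv()].
#' @param seed master seed for every stochastic step.
#' @return An object of class `mcdsl_config`.
#' @export
mcdsl_config <- function(synthetic = NULL, inputs = NULL, alpha = 0.05,
                         max_cond_size = 3, max_set_size = 4, caliper = 5,
                         k_folds = 10, models = c("KNN", "DT", "BPNN", "RF", "EC"),
                         eval_all_features = TRUE, params = list(), seed = 1) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of 'synthetic' or 'inputs' must be provided", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    stop_field("synthetic", "must be a synthetic_spec")
  }
  if (!is.null(inputs)) {
    need <- c("encounters", "scr", "events", "features")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop_field("inputs", paste("missing:", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop_field("alpha", "must be in (0, 1)")
  if (!is_count(max_cond_size) || max_cond_size < 1) stop_field("max_cond_size", "must be >= 1")
  if (!is_count(max_set_size) || max_set_size < 1) stop_field("max_set_size", "must be >= 1")
  if (!is.numeric(caliper) || caliper <= 0) stop_field("caliper", "must be > 0")
  if (!is_count(k_folds) || k_folds < 2) stop_field("k_folds", "must be >= 2")
  structure(list(
    synthetic = synthetic, inputs = inputs, alpha = alpha,
    max_cond_size = as.integer(max_cond_size),
    max_set_size = as.integer(max_set_size), caliper = caliper,
    k_folds = as.integer(k_folds), models = models,
    eval_all_features = isTRUE(eval_all_features), params = params,
    seed = as.integer(seed)
  ), class = "mcdsl_config")
}

# ---- stage implementations -------------------------------------------------

stage_simulate <- function(config, dir) {
  if (is.null(config$synthetic)) {
    for (nm in c("encounters", "scr", "events", "features")) {
      file.copy(config$inputs[[nm]], file.path(dir, paste0(nm, ".csv")),
                overwrite = TRUE)
    }
    return(list(source = "input files"))
  }
  sim <- generate_cohort(config$synthetic)
  .write_csv(sim$encounters, file.path(dir, "encounters.csv"))
  .write_csv(sim$scr, file.path(dir, "scr.csv"))
  .write_csv(sim$events, file.path(dir, "events.csv"))
  .write_csv(sim$features, file.path(dir, "features.csv"))
  truth <- sim$truth
  jsonlite::write_json(list(
    planted = as.list(truth$planted),
    graph = truth$graph,
    markov_blanket = truth$markov_blanket
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_csv(truth$stage_intent, file.path(dir, "truth_stages.csv"))
  list(encounters = nrow(sim$encounters), scr_rows = nrow(sim$scr),
       event_rows = nrow(sim$events))
}

stage_cohort <- function(config, dir) {
  enc <- .read_csv(file.path(dir, "encounters.csv"))
  scr <- .read_csv(file.path(dir, "scr.csv"))
  built <- build_cohort(enc, scr, caliper = config$caliper)
  .write_csv(built$cohort, file.path(dir, "cohort.csv"))
  .write_csv(built$exclusions, file.path(dir, "exclusions.csv"))
  list(cases = sum(built$cohort$arm == "case"),
       controls = sum(built$cohort$arm == "control"),
       excluded = nrow(built$exclusions),
       unmatched = length(built$unmatched))
}

stage_features <- function(config, dir) {
  cohort <- .read_csv(file.path(dir, "cohort.csv"))
  enc <- .read_csv(file.path(dir, "encounters.csv"))
  events <- .read_csv(file.path(dir, "events.csv"))
  dict <- .read_csv(file.path(dir, "features.csv"))
  fm <- assemble_matrix(cohort, enc, events, dict)
  out <- data.frame(encounter_id = fm$encounter_id, y = fm$y,
                    lapply(fm$data, as.character),
                    stringsAsFactors = FALSE, check.names = FALSE)
  .write_csv(out, file.path(dir, "feature_matrix.csv"))
  .write_csv(fm$features, file.path(dir, "feature_dictionary.csv"))
  .write_csv(fm$dropped, file.path(dir, "feature_dropped.csv"))
  list(rows = nrow(fm$data), features = ncol(fm$data), cases = sum(fm$y))
}

# Rebuild the factor matrix from the stage-3 outputs.
.load_matrix <- function(dir) {
  raw <- .read_csv(file.path(dir, "feature_matrix.csv"),
                   colClasses = "character", check.names = FALSE)
  dict <- .read_csv(file.path(dir, "feature_dictionary.csv"))
  data <- raw[, dict$name, drop = FALSE]
  for (j in seq_len(ncol(data))) {
    data[[j]] <- factor(data[[j]], levels = strsplit(dict$states[j], "|",
                                                     fixed = TRUE)[[1L]])
  }
  fm <- feature_matrix(data, as.integer(raw$y), categories = dict$category,
                       time_dependent = dict$time_dependent)
  fm$encounter_id <- raw$encounter_id
  fm
}

stage_structure <- function(config, dir) {
  fm <- .load_matrix(dir)
  mb <- learn_markov_blanket(fm, alpha = config$alpha,
                             max_cond_size = config$max_cond_size)
  .write_csv(data.frame(member = mb$members, stringsAsFactors = FALSE),
             file.path(dir, "blanket.csv"))
  .write_csv(mb$trace, file.path(dir, "blanket_trace.csv"))
  list(blanket_size = length(mb$members), tests = nrow(mb$trace))
}

stage_direction <- function(config, dir) {
  fm <- .load_matrix(dir)
  members <- .read_csv(file.path(dir, "blanket.csv"))$member
  res <- discover_causes(fm, members, alpha = config$alpha,
                         max_set_size = config$max_set_size)
  .write_csv(data.frame(
    cause = if (length(res$causes)) res$causes else character(0),
    forward_p = rep(res$forward_p, length(res$causes)),
    backward_p = rep(res$backward_p, length(res$causes)),
    accepted = rep(res$accepted, length(res$causes)),
    stringsAsFactors = FALSE
  ), file.path(dir, "causes.csv"))
  .write_csv(res$search, file.path(dir, "direction_search.csv"))
  list(causes = length(res$causes), accepted = res$accepted,
       subsets = nrow(res$search))
}

stage_associate <- function(config, dir) {
  fm <- .load_matrix(dir)
  causes <- .read_csv(file.path(dir, "causes.csv"))$cause
  tab <- if (length(causes)) combination_table(fm, causes) else
    data.frame(combination = character(0))
  .write_csv(tab, file.path(dir, "or_table.csv"))
  list(combinations = nrow(tab))
}

stage_evaluate <- function(config, dir) {
  fm <- .load_matrix(dir)
  causes <- .read_csv(file.path(dir, "causes.csv"))$cause
  members <- .read_csv(file.path(dir, "blanket.csv"))$member
  subset_sel <- if (length(causes)) causes else members
  if (length(subset_sel) == 0L) {
    .write_csv(data.frame(subset = character(0)), file.path(dir, "metrics.csv"))
    return(list(evaluated = 0L))
  }
  subsets <- list(selected = subset_sel)
  if (config$eval_all_features) subsets$all_features <- names(fm$data)
  cmp <- compare_feature_sets(fm, subsets, models = config$models,
                              k_folds = config$k_folds, seed = config$seed,
                              params = config$params)
  .write_csv(cmp$table, file.path(dir, "metrics.csv"))
  list(evaluated = length(subsets) * length(config$models))
}

.pipeline_stages <- list(
  simulate = stage_simulate, cohort = stage_cohort, features = stage_features,
  structure = stage_structure, direction = stage_direction,
  associate = stage_associate, evaluate = stage_evaluate
)

#' Run the full discovery pipeline
#'
#' Executes simulate (or input ingestion), cohort construction, feature
#' assembly, structure learning, direction learning, odds-ratio association
#' and cross-validated evaluation, writing each stage's outputs as CSV into
#' `dir` plus a JSON run manifest. Any stage failure halts the run with the
#' stage name and cause. With a fixed seed every output file except the
#' manifest's timing block is byte-reproducible.
#'
#' @param config an [mcdsl_config()].
#' @param dir output directory (created if needed).
#' @param stages subset of stage names to run, in pipeline order; defaults to
#'   all.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, dir, stages = names(.pipeline_stages)) {
  stopifnot(inherits(config, "mcdsl_config"))
  stages <- match.arg(stages, names(.pipeline_stages), several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mcdsl")),
    seed = config$seed,
    alpha = config$alpha,
    stages = list(),
    timing = list()
  )
  for (nm in names(.pipeline_stages)) {
    if (!nm %in% stages) next
    t0 <- proc.time()[["elapsed"]]
    info <- tryCatch(
      .pipeline_stages[[nm]](config, dir),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
             call. = FALSE)
      }
    )
    manifest$stages[[nm]] <- info
    manifest$timing[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
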