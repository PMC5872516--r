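# Cross-validated predictive evaluation of feature subsets.

.cv_models <- c("KNN", "DT", "BPNN", "RF", "EC")

# Rank-based (Mann-Whitney) AUC; ties get mid-ranks.
.auc <- function(score, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fold_metrics <- function(prob, y, threshold = 0.5) {
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(auc = .auc(prob, y), precision = precision, recall = recall, f_score = f)
}

# Stratified fold ids: within each class, shuffle and deal round-robin.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    if (length(rows) < k) {
      stop("a fold would contain a single class: too few observations per class",
           call. = FALSE)
    }
    fold[rows[sample.int(length(rows))]] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

.one_hot <- function(data) {
  stats::model.matrix(~ . - 1, data = data)
}

#' Cross-validated evaluation of one classifier on one feature subset
#'
#' Stratified k-fold cross-validation of a classifier on the one-hot encoded
#' feature subset. Metrics (AUC, precision, recall, F-score; positive class =
#' stage-3, probability threshold 0.5) are averaged over folds and carry
#' normal-approximation 95% intervals `mean +- 1.96 sd / sqrt(k)`.
#'
#' Default hyperparameters (none is prescribed by the study design): KNN
#' k = 5; decision tree minimum leaf 5; random forest 500 trees over random
#' feature subspaces; backpropagation network with one hidden layer of 16
#' units; the ensemble soft-votes over the other four.
#'
#' @param data a `feature_matrix` or data frame of factors.
#' @param features character vector of feature columns to use.
#' @param model one of `"KNN"`, `"DT"`, `"BPNN"`, `"RF"`, `"EC"`.
#' @param y binary outcome (taken from `data` when it is a `feature_matrix`).
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed controlling fold assignment and every stochastic
#'   learner.
#' @param params named list of hyperparameter overrides (`knn_k`,
#'   `dt_min_leaf`, `rf_trees`, `bpnn_hidden`, `bpnn_epochs`).
#' @return An object of class `cv_report`: `model`, `features`, `folds`
#'   (per-fold metric data frame), `summary` (mean, ci_low, ci_high per
#'   metric), `seed`.
#' @export
run_cv <- function(data, features, model, y = NULL, k_folds = 10, seed = 1,
                   params = list()) {
  model <- match.arg(model, .cv_models)
  if (inherits(data, "feature_matrix")) {
    y <- data$y
    data <- data$data
  }
  if (length(features) == 0L) stop("empty feature subset", call. = FALSE)
  miss <- setdiff(features, names(data))
  if (length(miss)) stop(sprintf("unknown feature(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is_count(k_folds) || k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  y <- as.integer(y)
  X <- .one_hot(droplevels(data[, features, drop = FALSE]))
  set.seed(derive_seed(seed, 47))
  fold <- .stratified_folds(y, k_folds)
  per <- matrix(NA_real_, nrow = k_folds, ncol = 4L,
                dimnames = list(NULL, c("auc", "precision", "recall", "f_score")))
  for (f in seq_len(k_folds)) {
    test <- fold == f
    prob <- .classifier_prob(model, X[!test, , drop = FALSE], y[!test],
                             X[test, , drop = FALSE], params)
    per[f, ] <- .fold_metrics(prob, y[test])
  }
  mean_ <- colMeans(per)
  sd_ <- apply(per, 2L, stats::sd)
  ci <- 1.96 * sd_ / sqrt(k_folds)
  structure(list(
    model = model, features = features, seed = seed, k_folds = k_folds,
    folds = as.data.frame(cbind(fold = seq_len(k_folds), per)),
    summary = data.frame(
      metric = colnames(per), mean = unname(mean_),
      ci_low = unname(pmax(mean_ - ci, 0)), ci_high = unname(pmin(mean_ + ci, 1)),
      stringsAsFactors = FALSE
    )
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s on %d features, %d-fold stratified CV (seed %d)\n",
              x$model, length(x$features), x$k_folds, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f [%.3f, %.3f]\n", s$metric[i], s$mean[i],
                s$ci_low[i], s$ci_high[i]))
  }
  invisible(x)
}

#' Compare named feature subsets across classifiers
#'
#' Runs [run_cv()] for the full cross of feature subsets and models and
#' returns a long summary table (one row per subset, model and metric) with
#' the subset size alongside, mirroring a feature-selection comparison
#' layout.
#'
#' @param data a `feature_matrix` or data frame of factors.
#' @param subsets named list of character vectors of feature names (>= 1).
#' @param models character vector of classifier names.
#' @param y outcome (taken from a `feature_matrix`).
#' @inheritParams run_cv
#' @return list with `table` (summary data frame: `subset`, `n_features`,
#'   `model`, `metric`, `mean`, `ci_low`, `ci_high`) and `reports` (nested
#'   list of `cv_report`s).
#' @export
compare_feature_sets <- function(data, subsets, models = .cv_models, y = NULL,
                                 k_folds = 10, seed = 1, params = list()) {
  stopifnot(is.list(subsets), length(subsets) >= 1L, !is.null(names(subsets)))
  reports <- list()
  rows <- list()
  for (sn in names(subsets)) {
    for (mod in models) {
      rep_ <- run_cv(data, subsets[[sn]], mod, y = y, k_folds = k_folds,
                     seed = seed, params = params)
      reports[[sn]][[mod]] <- rep_
      s <- rep_$summary
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subset = sn, n_features = length(subsets[[sn]]),
                   model = mod, stringsAsFactors = FALSE), s)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, reports = reports)
}
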