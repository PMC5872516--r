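make_eval_data <- function(n, seed, signal = TRUE) {
  set.seed(seed)
  x1 <- factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes"))
  noise <- replicate(3, factor(sample(c("no", "yes"), n, TRUE),
                               levels = c("no", "yes")), simplify = FALSE)
  d <- data.frame(x1 = x1, n1 = noise[[1]], n2 = noise[[2]], n3 = noise[[3]])
  y <- if (signal) as.integer(x1 == "yes") else rbinom(n, 1, 0.5)
  list(d = d, y = y)
}

test_that("a perfectly separable outcome scores AUC 1 on every model", {
  dd <- make_eval_data(200, seed = 51, signal = TRUE)
  for (mod in c("KNN", "DT", "RF")) {
    rep_ <- run_cv(dd$d, names(dd$d), mod, y = dd$y, k_folds = 5, seed = 1,
                   params = list(rf_trees = 50))
    expect_equal(rep_$summary$mean[rep_$summary$metric == "auc"], 1)
  }
})

test_that("per-fold F-score is the harmonic mean of precision and recall", {
  dd <- make_eval_data(300, seed = 52, signal = TRUE)
  rep_ <- run_cv(dd$d, names(dd$d), "DT", y = dd$y, k_folds = 5, seed = 2)
  f <- rep_$folds
  harm <- ifelse(f$precision + f$recall == 0, 0,
                 2 * f$precision * f$recall / (f$precision + f$recall))
  expect_equal(f$f_score, harm)
  # all metrics bounded in [0, 1]
  expect_true(all(as.matrix(f[, -1]) >= 0 & as.matrix(f[, -1]) <= 1))
})

test_that("reports are reproducible under a fixed seed", {
  dd <- make_eval_data(200, seed = 53, signal = FALSE)
  r1 <- run_cv(dd$d, names(dd$d), "RF", y = dd$y, k_folds = 5, seed = 9,
               params = list(rf_trees = 30))
  r2 <- run_cv(dd$d, names(dd$d), "RF", y = dd$y, k_folds = 5, seed = 9,
               params = list(rf_trees = 30))
  expect_identical(r1$folds, r2$folds)
})

test_that("folds with a single class fail loudly", {
  dd <- make_eval_data(30, seed = 54, signal = FALSE)
  y_rare <- c(rep(1L, 3), rep(0L, 27))
  expect_error(run_cv(dd$d, names(dd$d), "DT", y = y_rare, k_folds = 10),
               "single class")
})

test_that("compare_feature_sets crosses subsets with models", {
  dd <- make_eval_data(200, seed = 55, signal = TRUE)
  cmp <- compare_feature_sets(
    dd$d, list(signal = "x1", noise = c("n1", "n2")),
    models = c("KNN", "DT"), y = dd$y, k_folds = 5, seed = 1
  )
  expect_equal(nrow(cmp$table), 2 * 2 * 4)    # subsets x models x metrics
  expect_setequal(unique(cmp$table$subset), c("signal", "noise"))
  auc <- subset(cmp$table, metric == "auc")
  expect_true(all(auc$mean[auc$subset == "signal"] >
                    auc$mean[auc$subset == "noise"]))
  # identical subset under the same seed reproduces identically
  cmp2 <- compare_feature_sets(dd$d, list(signal = "x1"), models = "DT",
                               y = dd$y, k_folds = 5, seed = 1)
  expect_identical(
    subset(cmp$table, subset == "signal" & model == "DT")$mean,
    subset(cmp2$table, subset == "signal")$mean
  )
})

test_that("the BPNN learns a separable rule", {
  dd <- make_eval_data(300, seed = 56, signal = TRUE)
  rep_ <- run_cv(dd$d, names(dd$d), "BPNN", y = dd$y, k_folds = 5, seed = 3,
                 params = list(bpnn_epochs = 200))
  expect_gt(rep_$summary$mean[rep_$summary$metric == "auc"], 0.95)
})
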