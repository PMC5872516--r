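# Internal classifiers for the cross-validated evaluation. The environment
# ships no tree / neural-network / random-forest package, so the decision
# tree (greedy Gini CART on the one-hot design), the bagged random forest
# over random feature subspaces, and the single-hidden-layer backpropagation
# network are small self-contained implementations; k-nearest-neighbour
# classification comes from FNN.

# ---- decision tree ---------------------------------------------------------

.gini <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 2 * (n1 / n) * (n0 / n) * n)
}

# Greedy binary CART on a numeric matrix (one-hot features are 0/1, so the
# candidate threshold per feature is the midpoint of adjacent observed
# values). Returns a nested list; leaves carry the positive-class rate.
.tree_fit <- function(X, y, min_leaf = 5, max_depth = 30L, depth = 0L) {
  n <- length(y)
  n1 <- sum(y)
  node_prob <- n1 / n
  if (depth >= max_depth || n < 2 * min_leaf || n1 == 0L || n1 == n) {
    return(list(leaf = TRUE, prob = node_prob))
  }
  parent_imp <- .gini(n1, n - n1)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj)
    xs <- xj[ord]; ys <- y[ord]
    cum1 <- cumsum(ys)
    cum <- seq_len(n)
    cut_ok <- which(xs[-n] < xs[-1L])
    cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    imp <- .gini(cum1[cut_ok], cum[cut_ok] - cum1[cut_ok]) +
      .gini(n1 - cum1[cut_ok], (n - cum[cut_ok]) - (n1 - cum1[cut_ok]))
    b <- which.min(imp)
    if (is.null(best) || imp[b] < best$imp) {
      best <- list(imp = imp[b], j = j,
                   thr = (xs[cut_ok[b]] + xs[cut_ok[b] + 1L]) / 2)
    }
  }
  if (is.null(best) || best$imp >= parent_imp - 1e-12) {
    return(list(leaf = TRUE, prob = node_prob))
  }
  left <- X[, best$j] <= best$thr
  list(
    leaf = FALSE, j = best$j, thr = best$thr,
    left = .tree_fit(X[left, , drop = FALSE], y[left], min_leaf, max_depth, depth + 1L),
    right = .tree_fit(X[!left, , drop = FALSE], y[!left], min_leaf, max_depth, depth + 1L)
  )
}

.tree_predict <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  walk <- function(node, rows) {
    if (!length(rows)) return(invisible())
    if (node$leaf) {
      out[rows] <<- node$prob
      return(invisible())
    }
    left <- X[rows, node$j] <= node$thr
    walk(node$left, rows[left])
    walk(node$right, rows[!left])
  }
  walk(tree, seq_len(n))
  out
}

# ---- random forest (bagging + random feature subspaces) --------------------

.forest_fit <- function(X, y, n_tree = 500L, min_leaf = 3) {
  mtry <- max(1L, ceiling(sqrt(ncol(X))))
  lapply(seq_len(n_tree), function(t) {
    rows <- sample.int(nrow(X), replace = TRUE)
    cols <- sort(sample.int(ncol(X), mtry))
    list(cols = cols,
         tree = .tree_fit(X[rows, cols, drop = FALSE], y[rows],
                          min_leaf = min_leaf))
  })
}

.forest_predict <- function(forest, X) {
  p <- rowMeans(vapply(forest, function(t) {
    .tree_predict(t$tree, X[, t$cols, drop = FALSE])
  }, numeric(nrow(X))))
  p
}

# ---- backpropagation neural network ----------------------------------------

# One hidden layer of logistic units, logistic output, full-batch gradient
# descent with momentum on the cross-entropy loss.
.bpnn_fit <- function(X, y, hidden = 16L, epochs = 300L, rate = 0.3,
                      momentum = 0.9, l2 = 1e-4) {
  p <- ncol(X)
  W1 <- matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden)
  b1 <- stats::runif(hidden, -0.5, 0.5)
  W2 <- matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1)
  b2 <- stats::runif(1, -0.5, 0.5)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  n <- nrow(X)
  sig <- function(z) 1 / (1 + exp(-z))
  for (e in seq_len(epochs)) {
    H <- sig(sweep(X %*% W1, 2L, b1, `+`))
    out <- as.vector(sig(H %*% W2 + b2))
    d_out <- (out - y) / n
    gW2 <- crossprod(H, d_out) + l2 * W2
    gb2 <- sum(d_out)
    d_h <- (d_out %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(X, d_h) + l2 * W1
    gb1 <- colSums(d_h)
    vW2 <- momentum * vW2 - rate * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - rate * gb2; b2 <- b2 + vb2
    vW1 <- momentum * vW1 - rate * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - rate * gb1; b1 <- b1 + vb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.bpnn_predict <- function(model, X) {
  sig <- function(z) 1 / (1 + exp(-z))
  H <- sig(sweep(X %*% model$W1, 2L, model$b1, `+`))
  as.vector(sig(H %*% model$W2 + model$b2))
}

# ---- dispatch --------------------------------------------------------------

# Fit one classifier on the training split and return held-out positive-class
# probabilities. `params` carries the documented hyperparameter defaults.
.classifier_prob <- function(model, X_train, y_train, X_test, params) {
  switch(model,
    KNN = {
      k <- params$knn_k %||% 5L
      pred <- FNN::knn(X_train, X_test, factor(y_train, levels = c(0, 1)),
                       k = k, prob = TRUE)
      vote <- attr(pred, "prob")
      ifelse(pred == "1", vote, 1 - vote)
    },
    DT = .tree_predict(.tree_fit(X_train, y_train,
                                 min_leaf = params$dt_min_leaf %||% 5), X_test),
    RF = .forest_predict(.forest_fit(X_train, y_train,
                                     n_tree = params$rf_trees %||% 500L),
                         X_test),
    BPNN = .bpnn_predict(.bpnn_fit(X_train, y_train,
                                   hidden = params$bpnn_hidden %||% 16L,
                                   epochs = params$bpnn_epochs %||% 300L),
                         X_test),
    EC = {
      comp <- c("KNN", "DT", "RF", "BPNN")
      probs <- vapply(comp, .classifier_prob, numeric(nrow(X_test)),
                      X_train = X_train, y_train = y_train, X_test = X_test,
                      params = params)
      rowMeans(probs)
    },
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}
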