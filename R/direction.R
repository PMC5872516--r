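# Phase 2: many-to-one causal direction learning. Candidate cause subsets are
# collapsed into a single converted feature whose states enumerate the joint
# component states, and the direction of the arrow between the converted
# feature and the outcome is decided by a discrete additive-noise model.

#' Convert several categorical features into one joint-state feature
#'
#' Mixed-radix enumeration of the component state tuples with the LAST
#' component varying fastest: with components of sizes m1, ..., mk the tuple
#' of all first states maps to index 1, advancing the last component by one
#' state advances the index by one, and the tuple of all last states maps to
#' the product of the sizes.
#'
#' @param data a `feature_matrix` or data frame of factors.
#' @param components character vector of component feature names (>= 1), in
#'   conversion order.
#' @return An object of class `converted_feature`: `index` (integer vector of
#'   joint-state indices, one per row), `m_bar` (total state count),
#'   `components`, `m` (per-component sizes), `states` (per-component
#'   alphabets).
#' @examples
#' d <- data.frame(a = factor(c("no", "yes")), b = factor(c("x", "y")))
#' convert_features(d, c("a", "b"))$index
#' @export
convert_features <- function(data, components) {
  if (inherits(data, "feature_matrix")) data <- data$data
  if (length(components) < 1L) stop("empty component list", call. = FALSE)
  miss <- setdiff(components, names(data))
  if (length(miss)) {
    stop(sprintf("unknown component feature(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  cols <- lapply(data[components], function(col) if (is.factor(col)) col else factor(col))
  m <- vapply(cols, nlevels, 1L)
  if (any(m < 2L)) stop("components must have at least 2 states", call. = FALSE)
  idx <- convert_index(do.call(cbind, lapply(cols, as.integer)), m)
  structure(list(
    index = idx, m_bar = prod(m), components = components, m = m,
    states = lapply(cols, levels)
  ), class = "converted_feature")
}

#' Joint-state index of component state tuples
#'
#' @param tuples integer matrix (or vector for a single tuple), one column
#'   per component, entries in 1..m_i.
#' @param m integer vector of component state counts.
#' @return integer vector of indices in 1..prod(m).
#' @seealso [convert_decode()] for the inverse.
#' @export
convert_index <- function(tuples, m) {
  if (is.null(dim(tuples))) tuples <- matrix(tuples, nrow = 1L)
  stopifnot(ncol(tuples) == length(m))
  if (any(tuples < 1L) || any(tuples > rep(m, each = nrow(tuples)))) {
    stop("tuple entries must lie in 1..m_i", call. = FALSE)
  }
  radix <- rev(cumprod(rev(c(m[-1L], 1))))  # weight of each position
  as.integer(1L + (tuples - 1L) %*% radix)
}

#' Decode a joint-state index back to its component tuple
#'
#' Exact inverse of [convert_index()].
#'
#' @param index integer vector of joint-state indices in 1..prod(m).
#' @param m integer vector of component state counts.
#' @return integer matrix with one row per index, one column per component.
#' @export
convert_decode <- function(index, m) {
  if (any(index < 1L) || any(index > prod(m))) {
    stop("index out of range", call. = FALSE)
  }
  k <- length(m)
  out <- matrix(0L, nrow = length(index), ncol = k)
  rem <- as.integer(index) - 1L
  for (j in rev(seq_len(k))) {
    out[, j] <- rem %% m[j] + 1L
    rem <- rem %/% m[j]
  }
  out
}

#' Fit a discrete additive-noise model x -> y
#'
#' Regresses the effect on the cause by the conditional mode (per cause
#' state), forms the cyclic residual `N = (y - f_hat(x)) mod m_y` on the
#' integer state scale, and scores the direction by a chi-square test of
#' independence between the residual and the cause: under a true
#' additive-noise mechanism the residual is independent of the cause, and
#' this fails in the anti-causal direction. Cause states with zero support
#' fall back to the global mode and are flagged.
#'
#' @param x integer state codes (or factor) of the cause; typically a
#'   `converted_feature` index.
#' @param y integer state codes (or factor) of the effect, ordered scale.
#' @param m_x,m_y state counts; inferred from the data when missing.
#' @return An object of class `anm_fit`: `f_hat` (modal effect state per
#'   cause state), `residuals` (0-based cyclic residuals), `independence_p`,
#'   `reliable`, `statistic`, `dof`, `zero_support`.
#' @export
fit_anm <- function(x, y, m_x = NULL, m_y = NULL) {
  if (inherits(x, "converted_feature")) { m_x <- m_x %||% x$m_bar; x <- x$index }
  if (is.factor(x)) { m_x <- m_x %||% nlevels(x); x <- as.integer(x) }
  if (is.factor(y)) { m_y <- m_y %||% nlevels(y); y <- as.integer(y) }
  x <- as.integer(x); y <- as.integer(y)
  if (min(y) == 0L) y <- y + 1L  # accept 0/1 outcomes
  m_x <- as.integer(m_x %||% max(x))
  m_y <- as.integer(m_y %||% max(y))
  n <- length(x)
  stopifnot(length(y) == n, n > 0L)

  counts <- matrix(tabulate((x - 1L) * m_y + y, nbins = m_x * m_y),
                   nrow = m_x, byrow = TRUE)
  support <- rowSums(counts) > 0
  global_mode <- which.max(tabulate(y, m_y))
  f_hat <- rep(global_mode, m_x)
  f_hat[support] <- apply(counts[support, , drop = FALSE], 1L, which.max)

  resid <- (y - f_hat[x]) %% m_y  # 0 .. m_y - 1
  if (length(unique(resid)) < 2L || length(unique(x)) < 2L) {
    # constant residual (e.g. a deterministic mechanism) is independent of
    # everything; a constant cause admits no test
    fit <- list(independence_p = 1, reliable = TRUE, statistic = 0, dof = 0L)
  } else {
    core <- .chi2_core(x, resid + 1L, m_x, m_y)
    if (is.null(core)) {
      fit <- list(independence_p = 1, reliable = FALSE, statistic = 0, dof = 0L)
    } else {
      fit <- list(
        independence_p = stats::pchisq(core$statistic, core$dof, lower.tail = FALSE),
        reliable = n >= 5 * core$dof,
        statistic = core$statistic, dof = core$dof
      )
    }
  }
  structure(c(list(f_hat = f_hat, residuals = resid, n = n, m_x = m_x,
                   m_y = m_y, zero_support = any(!support)), fit),
            class = "anm_fit")
}

#' @export
print.anm_fit <- function(x, ...) {
  cat(sprintf("discrete ANM fit: %d cause states -> %d effect states, n = %d\n",
              x$m_x, x$m_y, x$n))
  cat(sprintf("  residual _||_ cause: p = %.4g%s\n", x$independence_p,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' Identify the direct-cause subset of the Markov blanket
#'
#' Searches candidate subsets of the blanket in increasing cardinality (then
#' lexicographic) order. Each subset is collapsed by [convert_features()] and
#' both causal directions are fitted with [fit_anm()]: the forward model
#' (subset -> outcome) and the backward model (outcome -> converted subset).
#' A subset is admissible when the forward residual independence is NOT
#' rejected (`forward_p > alpha`) while the backward one IS
#' (`backward_p <= alpha`), both tests reliable. Subsets whose joint state
#' count breaks the reliability cap `n >= 5 * (m_bar - 1)` are skipped.
#'
#' The many-to-one structure is tenable only when the unique set of ALL
#' direct causes has been found, which is enforced as: the union of every
#' admissible subset must itself be admissible, and is then the accepted
#' cause set. (Strict subsets of the true cause set routinely pass the
#' forward test too, because omitting one cause perturbs the residual
#' distribution only mildly; scoring candidates by forward p-value alone
#' would therefore pick an arbitrary passing subset, whereas the union rule
#' returns the full set or, when the admissible family is inconsistent with
#' any single many-to-one structure, nothing.) When no subset qualifies the
#' result carries `accepted = FALSE` (a "both-pass" outcome is
#' unidentifiable, not silently resolved).
#'
#' @param x a `feature_matrix` or data frame of factors.
#' @param blanket a `markov_blanket` or character vector of member names.
#' @param y outcome (ignored when `x` is a `feature_matrix`).
#' @param alpha significance level shared with the structure phase.
#' @param max_set_size largest candidate cause-set size.
#' @return An object of class `causal_result`: `causes` (sorted names),
#'   `forward_p`, `backward_p`, `accepted`, and `search` (per-subset log).
#' @export
discover_causes <- function(x, blanket, y = NULL, alpha = 0.05, max_set_size = 4) {
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$data
  }
  members <- if (inherits(blanket, "markov_blanket")) blanket$members else blanket
  members <- sort(unique(as.character(members)))
  empty <- structure(list(
    causes = character(0), forward_p = NA_real_, backward_p = NA_real_,
    accepted = FALSE, alpha = alpha,
    search = data.frame(subset = character(), size = integer(),
                        m_bar = integer(), forward_p = numeric(),
                        backward_p = numeric(), status = character(),
                        stringsAsFactors = FALSE)
  ), class = "causal_result")
  if (length(members) == 0L) return(empty)

  yi <- as.integer(factor(y))
  n <- length(yi)
  m_y <- max(yi)
  log <- list()
  admissible <- list()

  sizes <- seq_len(min(length(members), max_set_size))
  for (k in sizes) {
    subsets <- utils::combn(members, k, simplify = FALSE)
    for (S in subsets) {
      cf <- convert_features(x, S)
      status <- "tested"
      fp <- bp <- NA_real_
      if (n < 5 * (cf$m_bar - 1L)) {
        status <- "skipped_mbar"
      } else {
        fwd <- fit_anm(cf$index, yi, m_x = cf$m_bar, m_y = m_y)
        bwd <- fit_anm(yi, cf$index, m_x = m_y, m_y = cf$m_bar)
        fp <- fwd$independence_p
        bp <- bwd$independence_p
        if (!fwd$reliable || !bwd$reliable) {
          status <- "unreliable"
        } else if (fp > alpha && bp <= alpha) {
          status <- "admissible"
          admissible[[length(admissible) + 1L]] <-
            list(S = S, fp = fp, bp = bp)
        }
      }
      log[[length(log) + 1L]] <- data.frame(
        subset = paste(S, collapse = "+"), size = k, m_bar = cf$m_bar,
        forward_p = fp, backward_p = bp, status = status,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- empty
  out$search <- do.call(rbind, log)
  if (length(admissible)) {
    un <- sort(unique(unlist(lapply(admissible, `[[`, "S"))))
    hit <- Filter(function(a) setequal(a$S, un), admissible)
    if (length(hit)) {
      out$causes <- un
      out$forward_p <- hit[[1L]]$fp
      out$backward_p <- hit[[1L]]$bp
      out$accepted <- TRUE
    }
  }
  out
}

#' @export
print.causal_result <- function(x, ...) {
  if (x$accepted) {
    cat("Accepted many-to-one causal structure {",
        paste(x$causes, collapse = ", "), "} -> outcome\n", sep = "")
    cat(sprintf("  forward residual independence p = %.4g (not rejected)\n",
                x$forward_p))
    cat(sprintf("  backward residual independence p = %.4g (rejected)\n",
                x$backward_p))
  } else {
    cat("No cause subset satisfied the direction criterion (accepted = FALSE)\n")
  }
  cat("  subsets examined:", nrow(x$search), "\n")
  invisible(x)
}
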