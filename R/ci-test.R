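# Chi-square (conditional) independence kernel shared by the structure- and
# direction-learning phases. Operates on integer state codes for speed; the
# exported surface accepts factors, integer codes, or column names of a
# feature_matrix / data frame.

# Pearson chi-square on two integer-coded variables. Rows/columns with zero
# margin are dropped before computing expectations and degrees of freedom.
# Returns NULL when fewer than 2 states remain on either side.
.chi2_core <- function(xi, yi, mx, my) {
  counts <- tabulate((xi - 1L) * my + yi, nbins = mx * my)
  O <- matrix(counts, nrow = mx, ncol = my, byrow = TRUE)
  O <- O[rowSums(O) > 0, , drop = FALSE]
  O <- O[, colSums(O) > 0, drop = FALSE]
  if (nrow(O) < 2L || ncol(O) < 2L) return(NULL)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  list(statistic = sum((O - E)^2 / E),
       dof = (nrow(O) - 1L) * (ncol(O) - 1L))
}

.resolve_column <- function(v, data) {
  if (is.character(v) && length(v) == 1L && !is.null(data)) {
    d <- if (inherits(data, "feature_matrix")) data$data else data
    if (!v %in% names(d)) stop(sprintf("no column '%s'", v), call. = FALSE)
    v <- d[[v]]
  }
  f <- if (is.factor(v)) v else factor(v)
  list(code = as.integer(f), m = nlevels(f))
}

.ci_result <- function(x, y, Z, statistic, dof, n, strata_used = 1L,
                       strata_skipped = 0L) {
  if (dof < 1L) {
    # fully degenerate stratification: nothing testable, never a rejection
    res <- list(statistic = 0, dof = 1L, p_value = 1, reliable = FALSE)
  } else {
    res <- list(
      statistic = statistic,
      dof = as.integer(dof),
      p_value = stats::pchisq(statistic, dof, lower.tail = FALSE),
      reliable = n >= 5 * dof
    )
  }
  structure(c(list(x = x, y = y, Z = Z, n = n), res,
              list(strata_used = strata_used, strata_skipped = strata_skipped)),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  zlab <- if (length(x$Z)) paste(x$Z, collapse = ",") else "(none)"
  cat(sprintf("chi-square CI test: %s _||_ %s | %s\n", x$x, x$y, zlab))
  cat(sprintf("  X2 = %.4g, dof = %d, p = %.4g, n = %d%s\n", x$statistic,
              x$dof, x$p_value, x$n,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' Chi-square test of marginal independence
#'
#' Pearson chi-square on the x-by-y contingency table. Degrees of freedom are
#' computed after dropping all-zero rows and columns; the p-value is the
#' upper tail of the chi-square distribution. The test carries a reliability
#' flag (`n >= 5 * dof`, the classic heuristic from constraint-based
#' structure learning); callers treat unreliable tests as "independence not
#' rejected" so sparse tables never fabricate edges.
#'
#' @param x,y factors, integer state codes, or column names of `data`.
#' @param data optional `feature_matrix` or data frame supplying named
#'   columns.
#' @return An object of class `ci_test`: `statistic`, `dof`, `p_value`,
#'   `reliable`, `n`.
#' @examples
#' chi2_independence(rep(1:2, each = 50), rep(1:2, times = 50))
#' @export
chi2_independence <- function(x, y, data = NULL) {
  chi2_conditional(x, y, Z = NULL, data = data)
}

#' Chi-square test of conditional independence
#'
#' Stratifies on the observed joint states of the conditioning set `Z`, sums
#' the per-stratum Pearson statistics and degrees of freedom (the standard
#' d-separation test form for discrete data), and refers the total to the
#' chi-square upper tail. Strata where either variable has fewer than two
#' observed states, or whose sample size falls below five observations per
#' stratum degree of freedom (the reliability heuristic applied locally, so
#' near-empty strata cannot inflate the statistic), contribute nothing and
#' are counted as skipped. An empty `Z` reduces exactly to
#' [chi2_independence()].
#'
#' @inheritParams chi2_independence
#' @param Z a list/vector of conditioning columns (names, factors, or codes);
#'   `NULL` or empty for the marginal test.
#' @return An object of class `ci_test`.
#' @export
chi2_conditional <- function(x, y, Z = NULL, data = NULL) {
  xname <- if (is.character(x) && length(x) == 1L) x else "x"
  yname <- if (is.character(y) && length(y) == 1L) y else "y"
  znames <- if (is.character(Z)) Z else if (length(Z)) rep("z", length(Z)) else character(0)
  xr <- .resolve_column(x, data)
  yr <- .resolve_column(y, data)
  n <- length(xr$code)
  if (length(yr$code) != n) stop("x and y must have equal length", call. = FALSE)
  if (xr$m < 2L || yr$m < 2L ||
      length(unique(xr$code)) < 2L || length(unique(yr$code)) < 2L) {
    stop("degenerate variable: fewer than 2 observed states", call. = FALSE)
  }

  if (is.character(Z) || is.factor(Z) || (is.atomic(Z) && !is.null(Z))) {
    Z <- if (is.character(Z)) as.list(Z) else list(Z)
  }
  if (length(Z) == 0L) {
    core <- .chi2_core(xr$code, yr$code, xr$m, yr$m)
    if (is.null(core)) {
      return(.ci_result(xname, yname, character(0), 0, 0L, n))
    }
    return(.ci_result(xname, yname, character(0), core$statistic, core$dof, n))
  }

  zr <- lapply(Z, .resolve_column, data = data)
  stratum <- rep(1L, n)
  mult <- 1L
  for (z in zr) {
    stratum <- stratum + (z$code - 1L) * mult
    mult <- mult * z$m
  }
  stat <- 0
  dof <- 0L
  used <- 0L
  skipped <- 0L
  for (rows in split(seq_len(n), stratum)) {
    core <- .chi2_core(xr$code[rows], yr$code[rows], xr$m, yr$m)
    # the reliability heuristic applied per stratum: a stratum must carry at
    # least 5 observations per degree of freedom or its (badly calibrated)
    # contribution is dropped
    if (is.null(core) || length(rows) < 5 * core$dof) {
      skipped <- skipped + 1L
    } else {
      stat <- stat + core$statistic
      dof <- dof + core$dof
      used <- used + 1L
    }
  }
  .ci_result(xname, yname, znames, stat, dof, n, used, skipped)
}

# Dependence decision used by the learning phases: a rejection only counts
# when the test is reliable.
.is_dependent <- function(test, alpha) {
  isTRUE(test$reliable) && test$p_value <= alpha
}
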