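# Odds-ratio verification of discovered cause combinations: one 2x2 table
# per non-empty exposure profile over the discovered medications.

#' Exposure vector for one combination profile
#'
#' A row is exposed to a combination when its states match the 0/1 mask on
#' every discovered cause (1 = the medication's "yes" state, 0 = "no"):
#' exact-profile matching, so the `2^k` masks partition the cohort. Set
#' `mode = "at_least"` for the alternative reading in which mask bits equal
#' to 0 are unconstrained.
#'
#' @param data a `feature_matrix` or data frame of factors.
#' @param causes character vector of binary (yes/no) cause features.
#' @param mask 0/1 integer vector, one bit per cause, not all zero.
#' @param mode `"exact"` (default) or `"at_least"`.
#' @return logical exposure vector, one per row.
#' @export
combination_exposure <- function(data, causes, mask, mode = c("exact", "at_least")) {
  mode <- match.arg(mode)
  if (inherits(data, "feature_matrix")) data <- data$data
  if (length(mask) != length(causes)) {
    stop("mask length must equal the number of causes", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1)) || sum(mask) == 0) {
    stop("mask must be 0/1 with at least one 1", call. = FALSE)
  }
  exposed <- rep(TRUE, nrow(data))
  for (j in seq_along(causes)) {
    v <- data[[causes[j]]] == "yes"
    exposed <- exposed & if (mask[j] == 1) v else if (mode == "exact") !v else TRUE
  }
  exposed
}

#' Odds ratio of a 2x2 exposure/outcome table
#'
#' `OR = (a d) / (b c)` with `a` exposed cases, `b` exposed controls, `c`
#' unexposed cases, `d` unexposed controls; the 95% confidence interval is
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells so both the
#' estimate and the interval stay finite.
#'
#' @param exposure,outcome logical/binary vectors of equal positive length.
#' @return An object of class `or_result`: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `haldane`.
#' @examples
#' odds_ratio(rep(c(TRUE, FALSE), c(30, 70)), rep(c(1, 0, 1, 0), c(10, 20, 5, 65)))
#' @export
odds_ratio <- function(exposure, outcome) {
  if (length(exposure) == 0L) stop("empty vectors", call. = FALSE)
  if (length(exposure) != length(outcome)) {
    stop("exposure and outcome must have equal length", call. = FALSE)
  }
  e <- as.logical(exposure)
  o <- as.logical(outcome)
  a <- sum(e & o); b <- sum(e & !o); c_ <- sum(!e & o); d <- sum(!e & !o)
  haldane <- min(a, b, c_, d) == 0L
  aa <- a + 0.5 * haldane; bb <- b + 0.5 * haldane
  cc <- c_ + 0.5 * haldane; dd <- d + 0.5 * haldane
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  structure(list(
    a = a, b = b, c = c_, d = d, odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se), ci_high = exp(log(or) + 1.96 * se),
    haldane = haldane
  ), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.3g [%.3g, %.3g]  (a=%d b=%d c=%d d=%d%s)\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$a, x$b, x$c, x$d,
              if (x$haldane) ", Haldane +0.5" else ""))
  invisible(x)
}

# Non-zero masks over k causes in the published presentation order:
# ascending number of exposed medications, then ascending position of the
# first exposed one, then ascending binary value of the mask (first bit most
# significant).
.combination_masks <- function(k) {
  masks <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  masks <- masks[rowSums(masks) > 0, , drop = FALSE]
  popc <- rowSums(masks)
  firstbit <- apply(masks, 1L, function(m) which(m == 1)[1L])
  value <- as.vector(masks %*% 2^((k - 1):0))
  masks[order(popc, firstbit, value), , drop = FALSE]
}

#' Odds ratios of all combinations of the discovered causes
#'
#' One [odds_ratio()] row per non-zero exposure mask over the `k` discovered
#' cause medications (`2^k - 1` rows), ordered by ascending combination size
#' and then by the position of the first exposed medication.
#'
#' @inheritParams combination_exposure
#' @param y binary outcome vector (taken from `data` when it is a
#'   `feature_matrix`).
#' @return data frame with columns `combination` (`CoRF1` ...), one 0/1
#'   column per cause, `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `haldane`.
#' @export
combination_table <- function(data, causes, y = NULL, mode = c("exact", "at_least")) {
  mode <- match.arg(mode)
  if (inherits(data, "feature_matrix")) {
    y <- data$y
    data <- data$data
  }
  k <- length(causes)
  if (k < 1L || k > 8L) stop("need between 1 and 8 causes", call. = FALSE)
  masks <- .combination_masks(k)
  rows <- lapply(seq_len(nrow(masks)), function(i) {
    e <- combination_exposure(data, causes, masks[i, ], mode = mode)
    r <- odds_ratio(e, y)
    cbind(
      data.frame(combination = sprintf("CoRF%d", i), stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(masks[i, ], causes))),
      data.frame(a = r$a, b = r$b, c = r$c, d = r$d,
                 odds_ratio = r$odds_ratio, ci_low = r$ci_low,
                 ci_high = r$ci_high, haldane = r$haldane)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
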