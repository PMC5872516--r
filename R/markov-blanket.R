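#' Discover the Markov blanket of the outcome
#'
#' Phase 1 of the two-phase causal discovery: an IAMB-style interleaved
#' grow/shrink search over the feature columns, using the chi-square
#' conditional-independence kernel. Grow admits the candidate with the
#' smallest p-value among those reliably dependent on the outcome given the
#' current blanket; after each admission a shrink pass removes any member
#' that has become independent of the outcome given the rest of the blanket.
#' Conditioning sets are capped at `max_cond_size` members, chosen as the
#' strongest marginal associates, since with a few hundred rows larger sets
#' are almost never reliable under the `n >= 5 * dof` rule. Ties on p-value
#' break lexicographically on feature name, so the result is invariant to
#' column order.
#'
#' With hundreds of candidate features the minimum null p-value per grow
#' round is far below any fixed `alpha`, so an uncorrected search admits
#' spurious members roughly in proportion to the feature count. The default
#' `correction = "bonferroni"` therefore divides the admission threshold by
#' the number of candidates in the round (the shrink threshold stays at
#' `alpha`); set `correction = "none"` for the raw search.
#'
#' @param x a `feature_matrix`, or a data frame of factors.
#' @param y outcome vector (ignored when `x` is a `feature_matrix`).
#' @param alpha significance level in (0, 1) for every test.
#' @param max_cond_size largest conditioning-set size (>= 1).
#' @param correction multiple-testing control for grow-phase admissions.
#' @return An object of class `markov_blanket`: `members` (sorted feature
#'   names), `trace` (data frame of admit/remove events with the justifying
#'   test), `alpha`, `max_cond_size`.
#' @examples
#' \donttest{
#' net <- generate_discrete_network(synthetic_spec(seed = 1, n_features = 30))
#' learn_markov_blanket(net$x, net$y)
#' }
#' @export
learn_markov_blanket <- function(x, y = NULL, alpha = 0.05, max_cond_size = 3,
                                 correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$data
  }
  stopifnot(is.data.frame(x))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is_count(max_cond_size) || max_cond_size < 1) {
    stop("max_cond_size must be a positive integer", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("degenerate matrix: need at least 2 rows", call. = FALSE)
  yf <- factor(y)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("degenerate outcome: constant", call. = FALSE)
  }
  cols <- lapply(x, function(col) {
    f <- if (is.factor(col)) col else factor(col)
    list(code = as.integer(f), m = nlevels(f))
  })
  yc <- list(code = as.integer(yf), m = nlevels(yf))
  n <- nrow(x)
  usable <- vapply(cols, function(cl) length(unique(cl$code)) >= 2L, TRUE)
  feat_names <- sort(names(x)[usable])

  run_test <- function(fname, cond) {
    zr <- cols[cond]
    stratum <- rep(1L, n)
    mult <- 1L
    for (z in zr) {
      stratum <- stratum + (z$code - 1L) * mult
      mult <- mult * z$m
    }
    xr <- cols[[fname]]
    stat <- 0; dof <- 0L
    if (length(zr) == 0L) {
      core <- .chi2_core(xr$code, yc$code, xr$m, yc$m)
      if (!is.null(core)) { stat <- core$statistic; dof <- core$dof }
    } else {
      for (rows in split(seq_len(n), stratum)) {
        core <- .chi2_core(xr$code[rows], yc$code[rows], xr$m, yc$m)
        if (!is.null(core) && length(rows) >= 5 * core$dof) {
          stat <- stat + core$statistic; dof <- dof + core$dof
        }
      }
    }
    if (dof < 1L) {
      return(list(statistic = 0, dof = 0L, p_value = 1, reliable = FALSE))
    }
    list(statistic = stat, dof = dof,
         p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
         reliable = n >= 5 * dof)
  }

  marginal_p <- vapply(feat_names, function(f) run_test(f, character(0))$p_value, 1)

  # conditioning set: the whole blanket when small, else its strongest
  # marginal associates (deterministic given the marginal ranking)
  cond_for <- function(mb) {
    if (length(mb) <= max_cond_size) return(mb)
    mb[order(marginal_p[mb], mb)][seq_len(max_cond_size)]
  }

  mb <- character(0)
  trace <- list()
  note <- function(action, feature, t) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, action = action, feature = feature,
      statistic = t$statistic, dof = t$dof, p_value = t$p_value,
      reliable = t$reliable, cond_size = length(cond_for(setdiff(mb, feature))),
      stringsAsFactors = FALSE
    )
  }

  shrink <- function() {
    repeat {
      removed <- FALSE
      for (member in mb) {
        t <- run_test(member, cond_for(setdiff(mb, member)))
        if (!(isTRUE(t$reliable) && t$p_value <= alpha)) {
          mb <<- setdiff(mb, member)
          note("remove", member, t)
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
  }

  repeat {
    cand <- setdiff(feat_names, mb)
    if (length(cand) == 0L) break
    cond <- cond_for(mb)
    tests <- lapply(cand, run_test, cond = cond)
    p <- vapply(tests, `[[`, 1, "p_value")
    thr <- if (correction == "bonferroni") alpha / length(cand) else alpha
    ok <- vapply(tests, function(t) isTRUE(t$reliable), TRUE) & p <= thr
    if (!any(ok)) break
    pick <- which(ok)[order(p[ok], cand[ok])][1L]
    mb <- c(mb, cand[pick])
    note("admit", cand[pick], tests[[pick]])
    shrink()
  }

  structure(list(
    members = sort(mb),
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(), action = character(), feature = character(),
                 statistic = numeric(), dof = integer(), p_value = numeric(),
                 reliable = logical(), cond_size = integer(),
                 stringsAsFactors = FALSE),
    alpha = alpha, max_cond_size = max_cond_size, correction = correction,
    n = n
  ), class = "markov_blanket")
}

#' @export
print.markov_blanket <- function(x, ...) {
  cat("Markov blanket of the outcome (", length(x$members), " members, alpha = ",
      x$alpha, "):\n", sep = "")
  if (length(x$members)) cat(" ", paste(x$members, collapse = ", "), "\n")
  cat("  search trace:", sum(x$trace$action == "admit"), "admissions,",
      sum(x$trace$action == "remove"), "removals\n")
  invisible(x)
}
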