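#' Two-phase causal discovery of direct risk factors
#'
#' Fits the full two-phase procedure to a categorical feature matrix with a
#' binary outcome: phase 1 learns the outcome's Markov blanket by chi-square
#' conditional-independence testing ([learn_markov_blanket()]), deleting
#' every feature outside it; phase 2 identifies the direct-cause subset of
#' the blanket by many-to-one additive-noise direction learning on the
#' joint-state converted feature ([discover_causes()]).
#'
#' @param x a `feature_matrix`, a data frame of factor features, or a
#'   formula such as `y ~ .` with `data`.
#' @param ... passed on to methods.
#' @return An object of class `mcdsl` with components `blanket`
#'   (`markov_blanket`), `result` (`causal_result`), `causes`, `alpha`,
#'   `n`, `p`, `call`. Methods: `print`, `summary`, `coef` (marginal log
#'   odds ratios of the accepted causes), `residuals` (cyclic additive-noise
#'   residuals of the accepted forward fit), `plot`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_cases = 60, n_controls = 60, n_features = 40, seed = 3)
#' net <- generate_discrete_network(spec)
#' fit <- mcdsl(net$x, net$y)
#' print(fit)
#' }
#' @export
mcdsl <- function(x, ...) UseMethod("mcdsl")

#' @rdname mcdsl
#' @param y binary outcome (0/1), one per row.
#' @param alpha significance level shared by both phases.
#' @param max_cond_size conditioning-set cap for phase 1.
#' @param max_set_size largest candidate cause-set size for phase 2.
#' @export
mcdsl.data.frame <- function(x, y, alpha = 0.05, max_cond_size = 3,
                             max_set_size = 4, ...) {
  mcdsl.feature_matrix(feature_matrix(x, y), alpha = alpha,
                       max_cond_size = max_cond_size,
                       max_set_size = max_set_size, call = sys.call(-1L))
}

#' @rdname mcdsl
#' @param data data frame holding the formula's variables.
#' @export
mcdsl.formula <- function(x, data, alpha = 0.05, max_cond_size = 3,
                          max_set_size = 4, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.fail)
  y <- mf[[1L]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  mcdsl.feature_matrix(feature_matrix(mf[-1L], y), alpha = alpha,
                       max_cond_size = max_cond_size,
                       max_set_size = max_set_size, call = sys.call(-1L))
}

#' @rdname mcdsl
#' @param call internal.
#' @export
mcdsl.feature_matrix <- function(x, alpha = 0.05, max_cond_size = 3,
                                 max_set_size = 4, call = NULL, ...) {
  blanket <- learn_markov_blanket(x, alpha = alpha, max_cond_size = max_cond_size)
  result <- discover_causes(x, blanket, alpha = alpha, max_set_size = max_set_size)
  fit <- structure(list(
    blanket = blanket, result = result, causes = result$causes,
    alpha = alpha, n = nrow(x$data), p = ncol(x$data),
    matrix = x, call = call %||% sys.call(-1L)
  ), class = "mcdsl")
  fit
}

#' @export
print.mcdsl <- function(x, ...) {
  cat("Two-phase causal risk-factor discovery (n =", x$n, ", p =", x$p, ")\n")
  cat("Phase 1 - Markov blanket (", length(x$blanket$members), " members): ",
      paste(x$blanket$members, collapse = ", "), "\n", sep = "")
  if (x$result$accepted) {
    cat("Phase 2 - accepted direct causes: {",
        paste(x$causes, collapse = ", "), "} -> outcome\n", sep = "")
    cat(sprintf("  forward p = %.4g, backward p = %.4g (alpha = %g)\n",
                x$result$forward_p, x$result$backward_p, x$alpha))
  } else {
    cat("Phase 2 - no direction-identifiable cause subset (accepted = FALSE)\n")
  }
  invisible(x)
}

#' @export
summary.mcdsl <- function(object, ...) {
  s <- list(
    n = object$n, p = object$p, alpha = object$alpha,
    blanket = object$blanket$members,
    n_admit = sum(object$blanket$trace$action == "admit"),
    n_remove = sum(object$blanket$trace$action == "remove"),
    causes = object$causes, accepted = object$result$accepted,
    forward_p = object$result$forward_p, backward_p = object$result$backward_p,
    subsets_examined = nrow(object$result$search),
    coef = tryCatch(stats::coef(object), error = function(e) NULL)
  )
  class(s) <- "summary.mcdsl"
  s
}

#' @export
print.summary.mcdsl <- function(x, ...) {
  cat("Causal risk-factor discovery summary\n")
  cat(sprintf("  data: %d rows x %d features, alpha = %g\n", x$n, x$p, x$alpha))
  cat(sprintf("  blanket: %d members (%d admissions, %d removals)\n",
              length(x$blanket), x$n_admit, x$n_remove))
  cat(sprintf("  direction search: %d subsets examined\n", x$subsets_examined))
  if (x$accepted) {
    cat("  accepted causes with marginal log odds ratios:\n")
    print(round(x$coef, 3))
  } else {
    cat("  no accepted cause set\n")
  }
  invisible(x)
}

#' @export
coef.mcdsl <- function(object, ...) {
  if (!object$result$accepted || length(object$causes) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  d <- object$matrix$data
  y <- object$matrix$y
  vapply(object$causes, function(nm) {
    e <- d[[nm]] == "yes"
    log(odds_ratio(e, y)$odds_ratio)
  }, 1)
}

#' @export
residuals.mcdsl <- function(object, ...) {
  if (!object$result$accepted) {
    stop("no accepted cause set: no additive-noise residuals", call. = FALSE)
  }
  cf <- convert_features(object$matrix, object$causes)
  fit_anm(cf, object$matrix$y, m_y = 2L)$residuals
}

#' @export
plot.mcdsl <- function(x, ...) {
  tr <- x$blanket$trace
  if (nrow(tr) == 0L) {
    plot.new()
    title("No admissions: empty Markov blanket")
    return(invisible(x))
  }
  members <- x$blanket$members
  admit <- tr[tr$action == "admit" & tr$feature %in% members, , drop = FALSE]
  admit <- admit[!duplicated(admit$feature, fromLast = TRUE), , drop = FALSE]
  h <- -log10(pmax(admit$p_value, 1e-300))
  col <- ifelse(admit$feature %in% x$causes, "firebrick", "grey60")
  op <- graphics::par(mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(h, names.arg = admit$feature, las = 2, col = col,
                    ylab = expression(-log[10](p)),
                    main = "Markov-blanket members (red = accepted causes)")
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}
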