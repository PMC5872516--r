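#' Specification of a synthetic EHR cohort world
#'
#' Describes the generating process for a matched stage-3 AKI case-control
#' cohort with a known planted causal structure: a roster of categorical
#' clinical features (binary medications/history/diagnoses, 3-state labs,
#' binned vitals with an Unknown state), a small set of planted direct-cause
#' medications, the outcome mechanism, demographics, and serum-creatinine
#' trajectory shapes consistent with each encounter's intended KDIGO stage.
#'
#' The outcome mechanism is a table-parameterized threshold rule with
#' constant exception noise: the latent indicator is 1 exactly when the
#' product of the per-state odds multipliers of the planted causes exceeds 1
#' (with the default single multiplier per cause, that is "any planted cause
#' active"), and the recorded outcome flips the indicator with probability
#' `noise_flip_prob` independently of all features. This is the discrete
#' additive-noise mechanism the direction-learning phase is designed to
#' detect. The default cause prevalence `1 - 2^(-1/n_causes)` makes the
#' latent indicator balanced, so balanced case-control sampling leaves the
#' exception noise constant across joint cause states.
#'
#' @param n_cases,n_controls arm sizes of the matched cohort (defaults mirror
#'   the 179 + 179 = 358-encounter design).
#' @param n_features total number of feature columns, demographics included
#'   (>= 26; 3 demographics, 5 vitals and 14 labs are fixed, the remainder is
#'   split among medications, history, admission diagnoses and comorbidities
#'   in realistic proportions).
#' @param planted_causes named numeric vector: medication feature names with
#'   the odds multiplier of their active ("yes") state; `NULL` plants
#'   `n_planted` causes on the first medication features.
#' @param n_planted number of default planted causes.
#' @param effect_multiplier default multiplier for auto-planted causes (> 1
#'   for a risk effect).
#' @param cause_prevalence marginal probability that a planted cause is
#'   active; default `1 - 2^(-1/n_planted)`.
#' @param confounder_edges optional data frame (`from`, `to`) of directed
#'   edges among binary features; must be acyclic.
#' @param noise_flip_prob outcome exception-noise probability in \[0, 0.5).
#' @param n_children,n_spouses optional child/spouse structure around the
#'   outcome (used by [generate_discrete_network()] so the true Markov
#'   blanket is known); children are binary features driven by the outcome
#'   and their spouse parents.
#' @param demographics list: `age_mean`, `age_sd` (years), `gender_probs`,
#'   `race_probs` (named probability vectors).
#' @param scr_model list: `baseline_meanlog`, `baseline_sdlog`,
#'   `baseline_range` (mg/dL), `peak_ratio` (stage-3 peak over baseline,
#'   strictly inside the stage-3 region), `pre_peak_ratio` (largest ratio
#'   before onset, strictly below 3).
#' @param seed integer master seed; equal seeds give byte-identical outputs.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cases = 179, n_controls = 179, n_features = 200,
                           planted_causes = NULL, n_planted = 4,
                           effect_multiplier = 3,
                           cause_prevalence = NULL,
                           confounder_edges = NULL,
                           noise_flip_prob = 0.15,
                           n_children = 0, n_spouses = 0,
                           demographics = list(
                             age_mean = 62, age_sd = 15,
                             gender_probs = c(F = 0.54, M = 0.46),
                             race_probs = c(white = 0.74, black = 0.13,
                                            asian = 0.04, hispanic = 0.06,
                                            other = 0.03)
                           ),
                           scr_model = list(
                             baseline_meanlog = log(0.85),
                             baseline_sdlog = 0.12,
                             baseline_range = c(0.55, 1.25),
                             peak_ratio = 3.5,
                             pre_peak_ratio = 2.8
                           ),
                           seed = 1) {
  if (!is_count(n_cases)) stop_field("n_cases", "must be a non-negative integer")
  if (!is_count(n_controls)) stop_field("n_controls", "must be a non-negative integer")
  if (!is_count(n_features) || n_features < 26) {
    stop_field("n_features", "must be an integer >= 26")
  }
  if (!is.numeric(noise_flip_prob) || noise_flip_prob < 0 || noise_flip_prob >= 0.5) {
    stop_field("noise_flip_prob", "must lie in [0, 0.5)")
  }
  if (!is_count(seed %% 2^31)) stop_field("seed", "must be an integer")

  dict <- make_feature_dictionary(n_features)
  meds <- dict$name[dict$category == "medication"]
  if (is.null(planted_causes)) {
    if (!is_count(n_planted) || n_planted > length(meds)) {
      stop_field("n_planted", "must not exceed the number of medication features")
    }
    planted_causes <- stats::setNames(rep(effect_multiplier, n_planted),
                                      meds[seq_len(n_planted)])
  }
  if (length(planted_causes) &&
      (is.null(names(planted_causes)) || anyNA(names(planted_causes)))) {
    stop_field("planted_causes", "must be a named numeric vector")
  }
  bad <- setdiff(names(planted_causes), dict$name)
  if (length(bad)) {
    stop_field("planted_causes", paste("not in the feature roster:",
                                       paste(bad, collapse = ", ")))
  }
  if (any(planted_causes <= 0)) {
    stop_field("planted_causes", "multipliers must be positive")
  }
  if (is.null(cause_prevalence)) {
    k <- max(length(planted_causes), 1L)
    cause_prevalence <- 1 - 2^(-1 / k)
  }
  if (cause_prevalence <= 0 || cause_prevalence >= 1) {
    stop_field("cause_prevalence", "must lie in (0, 1)")
  }
  if (!is.null(confounder_edges)) {
    stopifnot(is.data.frame(confounder_edges),
              all(c("from", "to") %in% names(confounder_edges)))
    bad <- setdiff(c(confounder_edges$from, confounder_edges$to), dict$name)
    if (length(bad)) {
      stop_field("confounder_edges", paste("unknown feature(s):",
                                           paste(bad, collapse = ", ")))
    }
    if (is.null(.toposort(dict$name, confounder_edges))) {
      stop_field("confounder_edges", "must be acyclic")
    }
  }
  if (!is_count(n_children) || !is_count(n_spouses)) {
    stop_field("n_children", "n_children and n_spouses must be non-negative integers")
  }
  if (n_spouses > 0 && n_children == 0) {
    stop_field("n_spouses", "spouses require at least one child")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_features = as.integer(n_features), features = dict,
    planted_causes = planted_causes, cause_prevalence = cause_prevalence,
    confounder_edges = confounder_edges, noise_flip_prob = noise_flip_prob,
    n_children = as.integer(n_children), n_spouses = as.integer(n_spouses),
    demographics = demographics, scr_model = scr_model,
    seed = as.integer(seed %% 2^31)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_cases, "cases +", x$n_controls,
      "controls,", x$n_features, "features\n")
  cat("  planted causes:", if (length(x$planted_causes))
    paste(sprintf("%s (x%g)", names(x$planted_causes), x$planted_causes),
          collapse = ", ") else "(none)", "\n")
  cat("  cause prevalence:", signif(x$cause_prevalence, 4),
      " exception noise:", x$noise_flip_prob, " seed:", x$seed, "\n")
  invisible(x)
}

# Feature roster: fixed demographics/vitals/labs plus a proportional split of
# the remainder into medications, history, admission diagnoses and
# comorbidities (weights echo a large tertiary-care feature inventory).
make_feature_dictionary <- function(n_features) {
  labs <- lab_reference_ranges()$name
  vitals <- names(vital_states())
  n_rest <- n_features - 3L - length(labs) - length(vitals)
  w <- c(medication = 482, history = 230, admission_dx = 129, comorbidity = 28)
  counts <- floor(n_rest * w / sum(w))
  counts["medication"] <- counts["medication"] + (n_rest - sum(counts))
  mk <- function(prefix, k) if (k > 0) sprintf("%s_%03d", prefix, seq_len(k)) else character(0)
  data.frame(
    name = c(labs, vitals,
             mk("med", counts["medication"]), mk("hist", counts["history"]),
             mk("adx", counts["admission_dx"]), mk("comorb", counts["comorbidity"])),
    category = c(rep("lab", length(labs)), rep("vitals", length(vitals)),
                 rep("medication", counts["medication"]),
                 rep("history", counts["history"]),
                 rep("admission_dx", counts["admission_dx"]),
                 rep("comorbidity", counts["comorbidity"])),
    stringsAsFactors = FALSE
  )
}

# Kahn topological sort; NULL when the edge set is cyclic.
.toposort <- function(nodes, edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(nodes)
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}
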