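# Sampling engines for the synthetic EHR world: a discrete network generator
# with known ground truth, and the full cohort generator emitting long-format
# encounter / SCr / feature-event tables.

.binary_states <- c("no", "yes")

# Frozen per-feature marginals and structural roles, drawn once per run from
# the already-seeded stream so a single master seed fixes the whole world.
.build_world <- function(spec) {
  dict <- spec$features
  p <- nrow(dict)
  states <- vector("list", p)
  probs <- vector("list", p)
  for (j in seq_len(p)) {
    cat_j <- dict$category[j]
    if (cat_j == "lab") {
      states[[j]] <- lab_states()
      pr <- c(0.55, 0.18, 0.27) + stats::runif(3, -0.05, 0.05)
      probs[[j]] <- pr / sum(pr)
    } else if (cat_j == "vitals") {
      st <- vital_states(dict$name[j])
      k <- length(st) - 1L
      center <- stats::dnorm(seq_len(k), mean = (k + 1) / 2, sd = k / 3)
      pr <- c(0.85 * center / sum(center), 0.15)
      states[[j]] <- st
      probs[[j]] <- pr
    } else {
      states[[j]] <- .binary_states
      pyes <- stats::runif(1, 0.03, 0.40)
      probs[[j]] <- c(1 - pyes, pyes)
    }
  }
  names(states) <- names(probs) <- dict$name
  causes <- names(spec$planted_causes)
  for (nm in causes) {
    probs[[nm]] <- c(1 - spec$cause_prevalence, spec$cause_prevalence)
  }

  # optional child/spouse structure around the outcome: rewires binary
  # features that are neither causes nor confounder nodes
  reserved <- c(causes,
                if (!is.null(spec$confounder_edges))
                  unique(c(spec$confounder_edges$from, spec$confounder_edges$to)))
  free_bin <- setdiff(dict$name[dict$category %in% .binary_categories], reserved)
  n_kid <- spec$n_children
  n_sp <- spec$n_spouses
  if (n_kid + n_sp > length(free_bin)) {
    stop("not enough binary features for the requested children/spouses",
         call. = FALSE)
  }
  children <- if (n_kid) free_bin[seq_len(n_kid)] else character(0)
  spouses <- if (n_sp) free_bin[n_kid + seq_len(n_sp)] else character(0)
  # each spouse co-parents one child (round-robin)
  spouse_of <- if (n_sp) stats::setNames(children[(seq_len(n_sp) - 1L) %% n_kid + 1L],
                                         spouses) else character(0)
  list(dict = dict, states = states, probs = probs, causes = causes,
       multipliers = spec$planted_causes, children = children,
       spouses = spouses, spouse_of = spouse_of,
       flip = spec$noise_flip_prob, edges = spec$confounder_edges)
}

# Sample n rows of integer state codes plus the outcome. Children of the
# outcome are generated after y; confounder edges overwrite their target
# column in topological order.
.sample_rows <- function(world, n) {
  p <- nrow(world$dict)
  X <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, world$dict$name))
  for (j in seq_len(p)) {
    pr <- world$probs[[j]]
    X[, j] <- sample.int(length(pr), n, replace = TRUE, prob = pr)
  }
  if (!is.null(world$edges) && nrow(world$edges)) {
    ord <- .toposort(world$dict$name, world$edges)
    for (v in intersect(ord, unique(world$edges$to))) {
      parents <- world$edges$from[world$edges$to == v]
      any_active <- rowSums(X[, parents, drop = FALSE] == 2L) > 0
      X[, v] <- 1L + as.integer(xor(any_active, stats::rbinom(n, 1L, 0.3) == 1L))
    }
  }
  # outcome: threshold on the product of active-state odds multipliers,
  # flipped with constant exception noise
  if (length(world$causes)) {
    active <- X[, world$causes, drop = FALSE] == 2L
    logmult <- active %*% log(world$multipliers)
    f <- as.integer(logmult > 0)
  } else {
    f <- rep(0L, n)
  }
  y <- as.integer(xor(f == 1L, stats::rbinom(n, 1L, world$flip) == 1L))
  for (ch in world$children) {
    sp <- names(world$spouse_of)[world$spouse_of == ch]
    drive <- y == 1L
    if (length(sp)) {
      drive <- drive | rowSums(X[, sp, drop = FALSE] == 2L) > 0
    }
    X[, ch] <- 1L + as.integer(xor(drive, stats::rbinom(n, 1L, world$flip) == 1L))
  }
  list(X = X, y = y, f = f)
}

.world_graph <- function(world) {
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  if (length(world$causes)) {
    edges <- rbind(edges, data.frame(from = world$causes, to = "outcome",
                                     stringsAsFactors = FALSE))
  }
  if (length(world$children)) {
    edges <- rbind(edges, data.frame(from = "outcome", to = world$children,
                                     stringsAsFactors = FALSE))
  }
  if (length(world$spouse_of)) {
    edges <- rbind(edges, data.frame(from = names(world$spouse_of),
                                     to = unname(world$spouse_of),
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(world$edges) && nrow(world$edges)) {
    edges <- rbind(edges, world$edges[, c("from", "to")])
  }
  edges
}

#' Sample a discrete network with known ground truth around the outcome
#'
#' Draws feature columns from the spec's world and the binary outcome from
#' the planted threshold-noise mechanism, optionally adding outcome children
#' and their spouse parents, so the true Markov blanket of the outcome
#' (parents, children, and children's other parents) is known and recorded.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of rows; defaults to `n_cases + n_controls`.
#' @return list: `x` (data frame of factors), `y` (0/1 integer vector),
#'   `graph` (edge data frame, `"outcome"` denoting the target), `mb` (true
#'   Markov blanket feature names), `causes`, `f` (latent noiseless
#'   outcome).
#' @export
generate_discrete_network <- function(spec, n = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(n %||% (spec$n_cases + spec$n_controls))
  set.seed(derive_seed(spec$seed, 11))
  world <- .build_world(spec)
  s <- .sample_rows(world, n)
  x <- as.data.frame(lapply(seq_len(ncol(s$X)), function(j) {
    factor(world$states[[j]][s$X[, j]], levels = world$states[[j]])
  }), optional = TRUE)
  names(x) <- colnames(s$X)
  list(
    x = x, y = s$y, graph = .world_graph(world),
    mb = sort(c(world$causes, world$children, world$spouses)),
    causes = sort(world$causes), f = s$f
  )
}

#' Generate a synthetic matched AKI cohort as long-format EHR tables
#'
#' Produces the three raw tables the cohort pipeline consumes - encounters
#' (demographics, admission/discharge, eGFR), serum-creatinine measurements,
#' and feature events - together with a truth record of the planted causal
#' structure and each encounter's intended KDIGO stage. Case encounters carry
#' piecewise-linear SCr trajectories rising to a peak strictly inside the
#' stage-3 region (default ratio 3.5 over baseline), so independent staging
#' must classify them stage 3; control trajectories stay strictly inside the
#' stage-0 region. Feature-state-realizing events are emitted before day 2.5,
#' ahead of every reachable checkpoint, so the feature builder recovers the
#' generated states exactly.
#'
#' Arm sampling is prospective rejection: rows are drawn from the joint
#' feature/outcome law until both arms are filled, which reproduces matched
#' case-control sampling from the implied population.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_cohort`: data frames `encounters`,
#'   `scr`, `events`, `features` (dictionary), and `truth` (planted causes,
#'   generating graph, intended stages, generated feature states).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 29))
  world <- .build_world(spec)
  n_cases <- spec$n_cases
  n_controls <- spec$n_controls
  total <- n_cases + n_controls

  # fill both arms by prospective rejection
  Xc <- NULL; Xk <- NULL
  guard <- 0L
  while ((is.null(Xc) || nrow(Xc) < n_cases) ||
         (is.null(Xk) || nrow(Xk) < n_controls)) {
    guard <- guard + 1L
    if (guard > 200L) stop("arm filling did not converge", call. = FALSE)
    s <- .sample_rows(world, max(512L, 2L * total))
    Xc <- rbind(Xc, s$X[s$y == 1L, , drop = FALSE])
    Xk <- rbind(Xk, s$X[s$y == 0L, , drop = FALSE])
    if (total == 0L) break
  }
  X <- rbind(Xc[seq_len(n_cases), , drop = FALSE],
             Xk[seq_len(n_controls), , drop = FALSE])
  arm <- rep(c("case", "control"), c(n_cases, n_controls))
  ids <- sprintf("E%04d", seq_len(total))

  # demographics: controls clone a template case's gender/race with a small
  # age jitter, emulating the matched design
  dg <- spec$demographics
  draw_demo <- function(k) {
    age <- round(stats::rnorm(k, dg$age_mean, dg$age_sd))
    age <- pmin(pmax(age, 19), 90)
    data.frame(
      age = age,
      gender = sample(names(dg$gender_probs), k, TRUE, prob = dg$gender_probs),
      race = sample(names(dg$race_probs), k, TRUE, prob = dg$race_probs),
      stringsAsFactors = FALSE
    )
  }
  demo_case <- draw_demo(n_cases)
  if (n_controls > 0L) {
    if (n_cases > 0L) {
      # controls clone a template case's demographics exactly; with equal age
      # multisets per gender/race stratum a perfect greedy matching is
      # guaranteed, emulating the fully matched design
      tmpl <- (seq_len(n_controls) - 1L) %% n_cases + 1L
      demo_ctrl <- demo_case[tmpl, , drop = FALSE]
    } else {
      demo_ctrl <- draw_demo(n_controls)
    }
  } else {
    demo_ctrl <- demo_case[0, , drop = FALSE]
  }
  demo <- rbind(demo_case, demo_ctrl)

  onset <- rep(NA_real_, total)
  if (n_cases > 0L) onset[seq_len(n_cases)] <- sample(4:8, n_cases, TRUE)
  discharge <- ifelse(arm == "case", onset + sample(1:3, total, TRUE),
                      sample(7:12, total, TRUE))
  encounters <- data.frame(
    encounter_id = ids, age = demo$age, gender = demo$gender, race = demo$race,
    admission = 0, discharge = discharge,
    egfr = round(stats::runif(total, 65, 110), 1),
    stringsAsFactors = FALSE
  )

  scr <- .make_scr_series(ids, arm, onset, discharge, spec$scr_model)
  events <- .make_events(ids, X, world)

  truth <- structure(list(
    planted = spec$planted_causes,
    graph = .world_graph(world),
    markov_blanket = sort(c(world$causes, world$children, world$spouses)),
    stage_intent = data.frame(
      encounter_id = ids, stage = ifelse(arm == "case", 3L, 0L),
      onset_time = onset, stringsAsFactors = FALSE
    ),
    states = X
  ), class = "cohort_truth")

  structure(list(encounters = encounters, scr = scr, events = events,
                 features = world$dict, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$encounters), "encounters,",
      nrow(x$scr), "SCr measurements,", nrow(x$events), "feature events\n")
  cat("  planted causes:", paste(names(x$truth$planted), collapse = ", "), "\n")
  invisible(x)
}

# Serum-creatinine trajectories. Cases: flat at baseline, then a linear rise
# to pre_peak_ratio at onset - 1 and a jump to peak_ratio at onset; controls:
# small fluctuation strictly inside stage 0.
.make_scr_series <- function(ids, arm, onset, discharge, sm) {
  total <- length(ids)
  b <- stats::rlnorm(total, sm$baseline_meanlog, sm$baseline_sdlog)
  for (it in 1:50) {
    out <- b < sm$baseline_range[1] | b > sm$baseline_range[2]
    if (!any(out)) break
    b[out] <- stats::rlnorm(sum(out), sm$baseline_meanlog, sm$baseline_sdlog)
  }
  b <- pmin(pmax(b, sm$baseline_range[1]), sm$baseline_range[2])
  has_pre <- stats::rbinom(total, 1, 0.8) == 1L

  per <- vector("list", total)
  for (i in seq_len(total)) {
    times <- c(if (has_pre[i]) -1, 0.25)
    vals <- c(if (has_pre[i]) b[i], b[i])
    days <- seq(1, discharge[i])
    if (arm[i] == "case") {
      o <- onset[i]
      ramp_days <- days[days < o]
      ratio <- 1 + (sm$pre_peak_ratio - 1) * (ramp_days - 1) / max(o - 2, 1)
      jit <- 1 + stats::runif(length(ramp_days), -0.02, 0.02)
      vr <- b[i] * pmin(ratio * jit, 2.9)
      peak_days <- days[days >= o]
      vp <- rep(b[i] * sm$peak_ratio, length(peak_days))
      times <- c(times, ramp_days, peak_days)
      vals <- c(vals, vr, vp)
    } else {
      jit <- stats::runif(length(days), -0.08, 0.08)
      vv <- b[i] * (1 + jit)
      # keep the 24-h window clear of the abnormal-SCr exclusion threshold
      vv[days <= 1] <- pmin(vv[days <= 1], 1.29)
      times <- c(times, days)
      vals <- c(vals, vv)
    }
    per[[i]] <- list(times = times, vals = vals)
  }
  data.frame(
    encounter_id = rep(ids, vapply(per, function(z) length(z$times), 1L)),
    time = unlist(lapply(per, `[[`, "times")),
    value = round(unlist(lapply(per, `[[`, "vals")), 3),
    stringsAsFactors = FALSE
  )
}

# Long feature-event table realizing the generated states. All events land
# strictly before day 2.5, ahead of every reachable checkpoint (onsets are
# >= day 4). State "no" / "unknown" / "Unknown" emits no event.
.make_events <- function(ids, X, world) {
  ranges <- lab_reference_ranges()
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    nm <- world$dict$name[j]
    cat_j <- world$dict$category[j]
    code <- X[, j]
    if (cat_j %in% .binary_categories) {
      rows <- which(code == 2L)
      if (!length(rows)) next
      tt <- if (cat_j %in% c("comorbidity", "admission_dx")) rep(0, length(rows))
            else round(stats::runif(length(rows), 0.1, 2.4), 3)
      out[[j]] <- data.frame(encounter_id = ids[rows], time = tt, feature = nm,
                             category = cat_j, value = 1,
                             stringsAsFactors = FALSE)
    } else if (cat_j == "lab") {
      ri <- match(nm, ranges$name)
      span <- ranges$high[ri] - ranges$low[ri]
      rows <- which(code != 3L)
      if (!length(rows)) next
      val <- ifelse(code[rows] == 1L,
                    ranges$low[ri] + 0.5 * span +
                      stats::runif(length(rows), -0.3, 0.3) * span * 0.5,
                    ranges$high[ri] + stats::runif(length(rows), 0.1, 0.5) * span)
      out[[j]] <- data.frame(encounter_id = ids[rows],
                             time = round(stats::runif(length(rows), 0.1, 2.4), 3),
                             feature = nm, category = cat_j,
                             value = round(val, 3), stringsAsFactors = FALSE)
    } else if (cat_j == "vitals") {
      bins <- .vital_bins[[nm]]
      k <- length(bins$labels)
      rep_val <- c(bins$breaks[1] - 1,
                   (bins$breaks[-length(bins$breaks)] + bins$breaks[-1]) / 2,
                   bins$breaks[length(bins$breaks)] + 1)
      rows <- which(code <= k)  # last state is Unknown
      if (!length(rows)) next
      out[[j]] <- data.frame(encounter_id = ids[rows],
                             time = round(stats::runif(length(rows), 0.1, 2.4), 3),
                             feature = nm, category = cat_j,
                             value = rep_val[code[rows]],
                             stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev)) {
    ev <- data.frame(encounter_id = character(0), time = numeric(0),
                     feature = character(0), category = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(ev) <- NULL
  ev
}
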