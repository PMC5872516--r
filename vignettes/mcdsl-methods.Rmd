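---
title: "Methods: two-phase causal risk-factor discovery for stage-3 AKI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase causal risk-factor discovery for stage-3 AKI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdsl)
```

## The problem and the model

Stage-3 acute kidney injury is rare (a fraction of a percent of admissions)
while EHR systems record hundreds of candidate risk features per encounter.
With ~358 usable encounters against ~900 features, correlation-based
selection both overfits and — by construction — cannot distinguish direct
causes from effects and confounded correlates. The package implements a
two-phase discrete causal discovery procedure:

1. **Structure learning** finds the Markov blanket of the binary outcome
   \(y\) (stage-3 vs never-AKI) with chi-square conditional-independence
   tests, and deletes everything outside it. The blanket of \(y\) — parents,
   children, and children's other parents — is exactly the set that renders
   \(y\) independent of all remaining features, so it is the smallest safe
   reduction.
2. **Direction learning** separates the *direct causes* inside the blanket.
   Several candidate causes \(x_1, x_2, \dots\) are collapsed into one
   converted feature \(\bar{x} = g(x_1, x_2, \dots)\) whose states enumerate
   the joint component states (mixed-radix, last component fastest), because
   the additive-noise criterion decides one-to-one arrows only. A discrete
   additive-noise model \(y = f(\bar{x}) + N\) with \(N \perp \bar{x}\) is
   fitted; the asymmetry of that independence between the two directions
   identifies the causal one.

### Assumptions

* Causal sufficiency within the feature roster, faithfulness, and discrete
  mechanisms with exception-type noise. The direction test is only
  informative when the mechanism is genuinely asymmetric: a binary cause with
  a binary effect and symmetric noise is not identifiable, and the procedure
  then reports "not accepted" rather than guessing.
* The matched case-control design is taken at face value: tests are run on
  the balanced sample. Exception noise that is constant across joint cause
  states in the population stays constant in the sample only when the
  latent mechanism splits the population evenly; the synthetic world is
  calibrated accordingly (below).

## Cohort construction

* **Baseline SCr**: last measurement in the 48 h window before admission,
  else the first inpatient measurement. All values are mg/dL internally;
  µmol/L inputs must be divided by 88.4. Where the printed dual-unit
  thresholds disagree slightly (26.4 µmol/L vs 0.3 mg/dL × 88.4), the mg/dL
  value is canonical.
* **Staging**: stage 1 at increase > 0.3 mg/dL (strict) or ratio in
  [1.5, 2.0); stage 2 at ratio in [2.0, 3.0); stage 3 at ratio ≥ 3.0 or
  SCr > 4.0 mg/dL. The printed ratio bands ("1.5–1.9", "2.0–2.9") are
  implemented as half-open intervals so the bands tile the positive line;
  onset is the first measurement satisfying the maximal stage's criterion.
* **Exclusions**: < 2 SCr measurements; eGFR < 60 mL/min/1.73 m²; SCr
  > 1.3 mg/dL within 24 h of admission. eGFR arrives as a precomputed
  column — no CKD-EPI/MDRD formula is implemented because none is mandated —
  and the 24 h window is applied to both the eGFR and SCr rules.
* **Matching**: exact on gender and race, nearest age within a caliper
  (default 5 years), greedy most-constrained-case-first, ties broken by the
  lowest control encounter id. This is deterministic without a seed and
  invariant to row order except through the documented tie-break.

Stage-1/2 encounters are set aside entirely: the contrast is stage-3 versus
encounters that never met any AKI criterion.

## Feature encoding

Time-dependent features are frozen at the **checkpoint**, 24 h before
stage-3 onset. Controls have no onset; each control inherits its matched
case's checkpoint-to-admission offset applied to its own admission, capped at
discharge. This offset-transfer rule is a package decision (the design gives
no rule for controls) and is flagged here prominently; encounters whose
checkpoint would precede admission are dropped and logged.

* Labs: last value strictly before the checkpoint, categorized against
  reference ranges into present-normal / present-abnormal / unknown.
  Shipped default ranges for the 14 labs are conventional adult intervals
  (`lab_reference_ranges()`), overridable per site.
* Vitals: last value strictly before the checkpoint, binned per the printed
  categories. Printed bins leave boundary gaps (e.g. diastolic "[90–99]"
  then "> 100"); bins are implemented left-closed right-open with breaks at
  each printed lower bound and the terminal threshold, so every finite value
  maps to exactly one bin. Missing vitals and labs become explicit
  Unknown/unknown states — no cell is ever empty.
* Medications and history: yes iff an event exists at or before the
  checkpoint (historical medications respect the checkpoint too — the
  conservative reading). Comorbidities, admission diagnoses and demographics
  are time-independent.
* Age is discretized into decade bands so that every feature is categorical.

## The conditional-independence kernel

Pearson chi-square with zero-margin rows/columns dropped before computing
degrees of freedom. Conditional tests stratify on the joint states of the
conditioning set and sum per-stratum statistics and dofs — the standard
d-separation test form for discrete data. Two reliability safeguards:

* the classic heuristic *n ≥ 5 · dof*, reported as a `reliable` flag;
  unreliable tests are treated as "independence not rejected" everywhere, so
  sparse tables can never fabricate edges;
* the same rule applied **per stratum**: a stratum with fewer than five
  observations per stratum-dof is skipped. Without this, near-empty strata
  (unavoidable when conditioning on three binary features at n = 358)
  contribute badly calibrated Pearson terms and the summed statistic becomes
  anti-conservative enough to admit pure-noise features.

Significance level `alpha` defaults to 0.05 and is shared across phases. The
kernel itself applies no multiple-testing correction; control lives at the
search level (next section).

## Structure learning choices

The search is IAMB-style interleaved grow/shrink: grow admits the candidate
with the smallest p-value among those reliably dependent on \(y\) given the
current blanket; each admission is followed by a shrink pass removing any
member independent of \(y\) given the rest. Choices made where the method
description is silent:

* **Multiple-testing control** (`correction = "bonferroni"`, default): the
  grow threshold is `alpha / #candidates` per round. With ~200 candidates
  the minimum null p-value per round is far below any fixed alpha, so the
  uncorrected search admits spurious members in proportion to the feature
  count; Bonferroni keeps the false-admission probability per round near
  alpha while the planted-signal p-values (~1e-12 at n = 358) pass
  unharmed. The shrink threshold stays at `alpha`.
* **Conditioning cap** (`max_cond_size = 3`): with a few hundred rows and
  the 5·dof rule, larger conditioning sets are almost never reliable. When
  the blanket exceeds the cap, the conditioning set is the cap-many members
  with the strongest marginal association — deterministic given the data.
* **Tie-breaks**: equal p-values resolve lexicographically by feature name,
  so results do not depend on column order.

## Direction learning choices

* **Regression and residual**: \(\hat f(s)\) is the conditional mode of the
  effect per converted-feature state; the residual is the cyclic difference
  \(N = (y - \hat f(\bar{x})) \bmod m_y\) on the integer state scale, the
  standard discrete additive-noise construction. A signed residual was
  considered and rejected: for a binary outcome with non-constant \(f\) the
  *sign* of a nonzero residual is a deterministic function of
  \(f(\bar{x})\), so a signed-residual independence test rejects the true
  direction asymptotically. The cyclic residual equals the generating noise
  exactly when \(\hat f\) recovers \(f\), making the forward test consistent.
* **Independence test**: the same chi-square kernel, keeping the entire
  pipeline on one test; states of \(\bar{x}\) with zero support fall back to
  the global mode and are flagged.
* **Backward model**: the converted feature is regressed on the outcome as a
  whole (\(\bar{x} = f'(y) + N' \bmod m_{\bar x}\)) rather than per
  component, for symmetry with the forward test.
* **Reliability cap**: subsets with \(n < 5 (m_{\bar{x}} - 1)\) are skipped;
  at n ≈ 358 this bounds practical subsets near four binary causes.
* **Acceptance rule**: a subset is admissible when the forward independence
  is not rejected and the backward one is (both tests reliable). The
  accepted cause set is the **union of all admissible subsets, provided the
  union is itself admissible**; otherwise nothing is accepted. This
  operationalizes "the many-to-one structure is tenable iff the unique set
  of all causes is discovered". The alternative — scoring candidates by
  forward p-value — was rejected after analysis: strict subsets of the true
  cause set routinely pass the forward test as well (omitting one cause
  perturbs the residual distribution only mildly at n = 358, so the test has
  limited power against them), and forward p-values are approximately
  uniform for every passing candidate, making an argmax-p choice a lottery
  among the true set and its fragments. The union rule returns the full set
  or, when the admissible family is inconsistent with any single many-to-one
  structure (e.g. a noise feature slipped into the blanket), explicitly
  nothing.

## Association and evaluation

Odds ratios use exact-profile exposure (each mask fixes *every* cause's
state), because the published combination rows are mutually exclusive
profiles — the partition invariant (all 2ᵏ exposure profiles partition the
cohort) confirms this reading; an "at least" mode is available behind a
flag. Wald CIs on the log scale; Haldane +0.5 on all cells when any cell is
zero. Rows are ordered by ascending combination size, then the position of
the first exposed medication, then mask value — reproducing the published
sequence (the simpler "reversed-mask binary" rule does not).

Evaluation is stratified k-fold cross-validation (default 10) per classifier
and feature subset, positive class stage-3, threshold 0.5, rank-based AUC,
CIs as mean ± 1.96·sd/√k across folds (fold-normal; the design names no CI
method). No hyperparameters are prescribed, so defaults are documented
package choices: KNN k = 5 (FNN); decision tree: greedy Gini CART, minimum
leaf 5, on the one-hot design; random forest: 500 bagged such trees over
√p-sized random feature subspaces; BPNN: one hidden layer of 16 logistic
units trained by full-batch backpropagation with momentum; ensemble:
soft-voting over the other four. The tree, forest and network are small
internal implementations because the runtime environment provides no
tree/NN/forest package.

## The synthetic world

`generate_cohort()` emits the three long-format tables a real extraction
would provide (encounters with demographics and eGFR, SCr measurements,
feature events) plus a truth record. Its defaults are the stated world of
the reference design: 179 cases + 179 matched controls, 200 features in
realistic category proportions, four planted medication causes.

* **Outcome mechanism**: latent indicator \(f(s) = 1\) iff the product of
  per-state odds multipliers of the planted causes exceeds 1 (with default
  multiplier 3 per active cause: "any planted cause active"), flipped with
  constant probability `noise_flip_prob = 0.15` independent of everything —
  exactly the discrete additive-noise mechanism the direction phase is
  designed to detect, i.e. the infinite-gain limit of a logistic link. A
  finite-slope logistic was rejected because its graded, state-dependent
  exception noise violates the constant-noise assumption and the planted
  forward direction would be (correctly!) rejected at scale.
* **Cause prevalence** defaults to \(1 - 2^{-1/4} \approx 0.159\), which
  makes the latent indicator balanced; balanced case-control sampling then
  leaves the exception noise constant across joint cause states (the
  selection odds factor is 1), so the planted model remains a valid
  additive-noise model *in the matched sample*. With a rare latent
  indicator, case-control selection rescales state-wise odds non-uniformly
  and no generator could satisfy the forward test — a real limitation of
  ANM-based direction learning on case-control data worth knowing about.
* **SCr trajectories**: cases hold baseline, rise piecewise-linearly to
  2.8× baseline the day before onset and jump to 3.5× at onset — strictly
  inside the stage-3 region, away from every boundary; controls fluctuate
  within ±8% (clamped below the 1.3 mg/dL admission-window threshold).
  Onsets fall on days 4–8 and all feature events land before day 2.5, so
  every reachable checkpoint sees the same frozen states and the feature
  builder recovers the generated matrix exactly.
* **Demographics**: controls clone a template case's gender/race/age, so a
  perfect matching exists and the deterministic greedy matcher finds it —
  emulating the fully matched design rather than testing matching failure
  modes (unit tests cover those separately).
* **Determinism**: one master seed; sub-streams are derived with fixed
  offsets per generator so reordering calls does not change results.

What the generator does **not** emulate: realistic pharmacology or
correlated medication co-prescription, EHR source-system idiosyncrasies,
informative missingness (unknown states are drawn independently of the
outcome), multi-admission linkage, or urine-output staging criteria. A green
end-to-end test therefore establishes that the pipeline recovers planted
discrete-ANM structure under clean conditions at the reference scale — not
that it would recover causes from any real hospital's data.

## Numerical and degenerate-input conventions

* Timestamps are numeric days on a shared axis; "last value before" is
  strict, event presence "at or before" the checkpoint.
* Constant residuals (deterministic mechanisms) have independence p = 1 by
  convention; a constant outcome or single-row matrix is an error; an empty
  blanket yields `accepted = FALSE`, never an error.
* Precision with no positive predictions is 0 in a fold (conservative);
  folds are stratified and a class with fewer members than folds fails
  loudly rather than silently re-balancing.
* The pipeline manifest records wall-clock per stage; every other output of
  a fixed-seed run is byte-reproducible, and the manifest is reproducible
  once its timing block is stripped.

## Known limitations

* The direction test needs mechanism asymmetry: binary-cause/binary-outcome
  pairs are unidentifiable and reported as such.
* Case-control sampling distorts exception noise unless the latent
  mechanism is balanced (see above); on strongly unbalanced designs the
  forward test will reject true causes.
* The union acceptance rule is conservative: one spurious blanket member
  that happens to form an admissible set typically voids acceptance for
  that run rather than contaminating the cause set.
* Odds-ratio verification is unadjusted (no conditional or
  regression-adjusted ORs), matching the published verification design.
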