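# mcdsl: causal risk-factor discovery for stage-3 acute kidney injury

Stage-3 acute kidney injury (AKI) — the irreversible, most lethal KDIGO
stage — is rare among hospitalized patients, while electronic health records
carry hundreds of candidate risk features per encounter. In that
small-n / large-p regime, correlation-based feature selection breaks down and,
more importantly, cannot separate *causes* (which clinicians could act on)
from mere correlates. `mcdsl` implements a two-phase causal feature-selection
pipeline for matched stage-3 AKI case-control cohorts built from longitudinal
serum-creatinine (SCr) records and categorical clinical features, and ships a
synthetic EHR generator with planted causal structure so the whole method can
be validated without access to protected health data.

## The method

**Cohort.** Encounters hospitalized ≥ 2 days are staged by the KDIGO SCr
criteria against a baseline (last SCr within 48 h before admission, else the
first inpatient value): stage 1 for an increase > 0.3 mg/dL or ratio in
[1.5, 2.0), stage 2 for ratio in [2.0, 3.0), stage 3 for ratio ≥ 3.0 or
SCr > 4.0 mg/dL. Encounters with < 2 SCr measurements, eGFR < 60
mL/min/1.73 m², or SCr > 1.3 mg/dL within 24 h of admission are excluded;
stage-3 cases are 1:1 matched to stage-0 controls exactly on gender and race
and nearest in age. Time-dependent features (medications, labs, vitals,
history) are frozen at a **checkpoint 24 h before stage-3 onset** (controls
inherit their matched case's offset); labs become
normal / abnormal / unknown, vitals are binned, everything else is yes/no, so
every feature is categorical with an explicit missingness state.

**Phase 1 — structure learning.** The Markov blanket of the outcome *y* is
learned by an IAMB-style grow/shrink search driven by stratified chi-square
conditional-independence tests (the d-separation test for discrete data),
deleting every feature outside the blanket.

**Phase 2 — direction learning.** Candidate cause subsets
{x₁, x₂, …} ⊆ blanket are collapsed into one *converted feature*
x̄ = g(x₁, x₂, …) whose states enumerate the joint component states. A
discrete additive-noise model y = f(x̄) + N (mod m) is fitted by conditional
mode; the direction is causal when the residual N is independent of x̄
forward and dependent backward. The accepted cause set is the union of all
admissible subsets, which must itself be admissible — the many-to-one
structure {x₁, x₂, …} → y is tenable only when the unique set of *all*
causes is found.

Discovered causes are verified by odds ratios (95% Wald CI, Haldane-corrected)
of all 2ᵏ − 1 exposure combinations, and their predictive value is measured by
stratified 10-fold cross-validation (AUC, precision, recall, F-score) over
KNN, decision tree, backpropagation network, random forest and a soft-voting
ensemble.

## Worked example

A synthetic matched cohort at the reference scale (179 cases + 179 matched
controls, 200 features, 4 planted medication causes with odds multiplier 3,
15% exception noise):

```r
library(mcdsl)
spec   <- synthetic_spec(seed = 1)
sim    <- generate_cohort(spec)                 # encounters / SCr / events tables
cohort <- build_cohort(sim$encounters, sim$scr) # KDIGO staging + matching
fm     <- assemble_matrix(cohort, sim$encounters, sim$events, sim$features)
fit    <- mcdsl(fm)                             # two-phase causal discovery
print(fit)
```

```
Two-phase causal risk-factor discovery (n = 358 , p = 200 )
Phase 1 - Markov blanket (4 members): med_001, med_002, med_003, med_004
Phase 2 - accepted direct causes: {med_001, med_002, med_003, med_004} -> outcome
  forward p = 0.6496, backward p = 7.961e-33 (alpha = 0.05)
```

All four planted medications are recovered from 200 features at n = 358: the
forward residual-independence test is not rejected (p = 0.65) while the
backward direction is overwhelmingly rejected. Verification and evaluation:

```r
combination_table(fm, fit$causes)[1:4, ]   # singleton exposure profiles
```

```
  combination med_001 med_002 med_003 med_004  a b   c   d odds_ratio ci_low ci_high
1       CoRF1       1       0       0       0 31 6 148 173       6.04   2.45   14.87
2       CoRF2       0       1       0       0 25 7 154 172       3.99   1.68    9.48
3       CoRF3       0       0       1       0 25 1 154 178      28.90   3.87  215.75
4       CoRF4       0       0       0       1 29 4 150 175       8.46   2.91   24.61
```

```r
run_cv(fm, fit$causes, "DT", seed = 1)
```

```
DT on 4 features, 10-fold stratified CV (seed 1)
  auc       0.871 [0.848, 0.895]
  precision 0.867 [0.837, 0.896]
  recall    0.872 [0.818, 0.926]
  f_score   0.865 [0.840, 0.891]
```

Four discovered features carry essentially all the predictive signal the
generator planted — the dimension-reduction-without-accuracy-loss property
the method is designed for.

The same analysis runs end to end with
`run_pipeline(mcdsl_config(synthetic = spec), "out/")`, which writes every
stage's CSV outputs plus a JSON manifest, or from a shell via the thin
wrapper `inst/cli/mcdsl.R` (subcommands `simulate`, `cohort`, `features`,
`discover`, `associate`, `evaluate`, `run-all`, `init-config`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the default synthetic world
(simulation → staging → matching → feature assembly → structure learning →
direction learning → odds ratios → cross-validated evaluation) under the
given seed and writes the JSON report to `--out`.

## Vignette

`vignettes/mcdsl-methods.Rmd` documents the model and its assumptions, every
tunable parameter with its default and rationale, what the synthetic world
does and does not emulate, and the numerical/design choices made where the
method description left them open.
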