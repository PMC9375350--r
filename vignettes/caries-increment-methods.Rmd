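---
title: "Methods: longitudinal caries increment and risk-based recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal caries increment and risk-based recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesrecall)
```

This vignette is the package's account of its own methods: the measurement
model, the choices that were genuinely open and how they were settled, the
numerical edge cases, and what the synthetic-data tests do and do not
establish about real cohorts.

## The measurement model

The observation unit is the tooth surface. Each of the 28 permanent teeth
(third molars excluded — the target population is 11–12-year-olds) carries
up to five surfaces (mesial, occlusal, distal, buccal, lingual), and every
surface at every attended visit is recorded in one of eleven states: sound;
`NONCAV_A` (modified ICDAS code A, the merged codes 1–2 used when surfaces
cannot be air-dried); cavitated severities `CAV3`–`CAV6`; three filled
states carrying associated-decay status; and the terminal states `MISSING`
and `CROWNED`.

Two diagnostic cutoffs project this alphabet onto an eight-state analysis
alphabet (`collapse_state()`). Under `"3-6"` only cavitated lesions count as
decay, so code A folds into sound; under `"A-6"` code A remains a decayed
state. All four cavitated severities merge into one `CAV` state under both
cutoffs: the increment analysis cares whether a surface is cavitated, not
how badly.

### Transition classes

For each surface observed at baseline and a follow-up,
`classify_transition()` assigns exactly one of *progression*, *regression*
or *neither* to the ordered pair of collapsed states. The mapping is a total
8 × 8 lookup table. Its core is uncontroversial (new decay is progression,
return to sound is regression, no change is neither, anything out of a
missing surface is neither), but four cells were genuinely open and are
package decisions:

* **Sound/non-cavitated → filled, and sound → cavitated** are classified as
  progression. A restorative intervention on a previously unrestored
  surface, like direct cavitation, is disease (or treatment) incidence;
  excluding these transitions would understate increments in treated
  children.
* **`CROWNED` is terminal**, treated exactly like `MISSING`: a surface
  progresses *into* it once and everything out of it is neither. Only
  missing surfaces are classically described this way; extending the rule to
  crowns follows from the same logic (the original surface can no longer be
  scored).
* **Transitions out of `CAV` or `FILLED_CAV`** other than the explicit
  regressions (to sound; cavitated filling to non-cavitated filling) are
  neither — a cavitated surface that becomes missing or filled is not *new*
  disease.
* **Surfaces first seen at a follow-up** (erupted between visits) are
  classified against an implied sound baseline: newly erupted surfaces are
  caries-free, and dropping them would shrink denominators as second molars
  erupt across the study window.

Biologically implausible reversals are deliberately **not** filtered. The
adjusted increment exists precisely because reversals are informative about
examiner behaviour; the method cannot, and does not try to, distinguish
plausible remineralisation from mis-scoring.

### The adjusted increment

Per child and interval, with `P`, `R`, `N` the counts of progressed,
regressed and unchanged surfaces,

$$\mathrm{ADJCI} = \frac{P \times N}{R + N}.$$

`R/(R+N)` estimates the examiner reversal rate among surfaces that did not
progress; `N/(R+N)` therefore deflates the crude increment `P` by the same
rate. Numerical edges: `R = 0` gives exactly `P`; `P = 0` gives 0; and the
degenerate `R + N = 0` (every surface progressed) is 0/0, for which we
return `P`, its limit as `N` grows from zero. `ADJCI ≤ P` always.

Intervals are always **baseline → follow-up** (cumulative), not
visit-to-visit: the 6-, 12- and 18-month increments share the same baseline,
which is what makes the repeated-measures comparison of "increment so far"
across follow-ups meaningful.

## Statistics

* **Chi-square** (`chi_square_test()`): Pearson statistic without continuity
  correction, delegated to `stats::chisq.test()`; tables with a zero
  marginal are rejected as degenerate rather than producing NaN expected
  counts.
* **Repeated-measures ANOVA** (`rm_anova()`): the one-way within-subject
  partition computed explicitly (SS subject, time, error), with
  `F = MS_time / MS_error` on `(t−1, (t−1)(n−1))` df. We compute the
  partition by hand rather than through `aov()` for two reasons: degenerate
  inputs (zero error variance) get defined answers — `F = 0, p = 1` when
  there is also no time effect, `F = ∞, p = 0` when the effect is exact —
  and a Greenhouse–Geisser epsilon (from the double-centred covariance of
  the interval columns, clamped to `[1/(t−1), 1]`) is available as an
  option. No sphericity correction is applied by default; the correction
  used is recorded in the output. The test suite cross-checks the statistic
  against `aov(y ~ time + Error(subject))` on random data.
* **Post hoc**: only two comparisons are made — 12 vs 6 months and 18 vs 6
  months — by paired t tests with Bonferroni factor 2 (`p_adj = min(1,
  2p)`). The first follow-up is the reference because the question the
  design answers is whether the increment *grows beyond* its six-month
  level.
* **Weighted kappa** (`weighted_kappa()`): linear disagreement weights by
  default (quadratic available). The weighting scheme used in any given
  calibration report is rarely stated; linear is the more conservative
  default and the choice is recorded in the result. With two categories
  both weightings reduce to unweighted Cohen kappa, which the tests exploit
  as an oracle.

## Missing data

Attendance distinguishes *absent* (can reappear) from *dropped* (absorbing).
A child missing baseline or a follow-up has no observable transition for
that interval; `count_transitions()` refuses such intervals and the caller
routes them to imputation.

Imputation (`impute_increments()`) is **stratified hot deck at the
transition-count level**: a missing child-interval receives the `(P, R, N)`
— hence the increment — of a donor drawn uniformly from the same risk
stratum's observed children at that interval. Operating on counts rather
than raw surface trajectories is sufficient for every downstream statistic
and avoids inventing surface-level histories. `m = 20` completed datasets by
default; per-dataset estimates are pooled by Rubin's rules
(`pool_estimates()`), with total variance `W + (1 + 1/m)B` and the
small-sample df formula. This is a declared, simple stand-in for model-based
multiple imputation, not a reconstruction of any particular MI model; under
missingness unrelated to outcome it leaves stratum means unbiased, which the
test suite verifies by a delete-30%-at-random simulation.

## Recall rules

Per (risk stratum, cutoff), the recommended recall interval is the earliest
follow-up whose increment evidence is significant at α = 0.05, else the
18-month horizon (`recommend_recall()`). The evidence vector is built by
`significance_table()`:

* `p12`, `p18`: the Bonferroni-adjusted paired comparisons against the
  6-month increment from the repeated-measures analysis.
* `p6`: the 6-month increment has no earlier increment to be compared with,
  so its evidence is a **one-sample t test of the 6-month increments
  against zero** — "did measurable progression occur within the first
  interval at all?". It is reported raw (a single hypothesis per cell); the
  ×2 Bonferroni belongs to the post hoc family, which this test is not part
  of.

`recall_table()` accepts an explicit `overrides` argument for policy
departures from the evidence-driven rule (for example, shortening a
stratum's recall on grounds external to the increment comparison). Overrides
are flagged in the output and the evidence columns are kept, so an audited
departure is visible as such.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes:

* **226 children, 90/69/67** in low/medium/high risk; risk is assigned, not
  derived — the risk-assessment instrument is treated as a black box.
* **126 scoreable surfaces per child** (a per-child random subset of the
  140 slots), matching the ≈126 surfaces/child implied by a 28,415-surface
  baseline over 226 children.
* **Baseline states i.i.d.** from the observed distribution of a low-caries
  school population: 97.54% sound, 1.81% code A, the rest cavitated at
  decreasing severity; no filled/missing surfaces at baseline.
* **Risk-specific 6-month Markov kernels** over the eleven states. Three
  per-risk progression rates (sound→A, sound→cavitated, A→cavitated) were
  calibrated once, numerically, so the closed-form expected stratum mean
  ADJCI at 18 months (`expected_increment()`, via the kernel's matrix
  powers) sits at 0.18/0.70/1.95 (cutoff 3–6) and 1.11/2.48/4.01 (A-6) for
  low/medium/high — the increment gradient the recall rules must resolve.
  Shared rates add a 25%/step reversal of code A, a small (3%) examiner
  reversal at the cavitation margin, severity progression among cavitated
  codes, and small treatment/extraction flows into the filled, missing and
  crowned states so every classifier path is exercised.
* **Attendance**: per-visit absence (2.7/11.2/5.9/0%) and absorbing
  new-dropout hazards (0/13.3/5.6/1.1%), chosen to reproduce a realistic
  ≈220/174/174/183-of-226 attendance trajectory with ≈36% cumulative
  missingness.
* **Demographics conditional on risk**, so the strong school-type × risk
  association (low-risk children predominantly privately schooled) is
  present and the chi-square stage has signal.

`ground_truth` carries both the closed-form expectations and the realized
per-child counts from the latent trajectories (which continue to evolve
while a child is absent), enabling parameter-recovery tests: on a ×10-size
cohort the pipeline's observed stratum means must sit within 3 Monte-Carlo
SEs of the expectations, with the strict high > medium > low ordering at
every interval and cutoff.

### What the generator does *not* emulate

* **Within-mouth correlation.** Surfaces evolve independently by default. A
  child-level log-normal frailty multiplier on the progression rates is
  available (`frailty_sd`, default 0 — its realistic magnitude is unknowable
  from aggregate tables, so it is off rather than arbitrary). The
  consequence is that between-child SDs of the increment are Poisson-scale,
  several times smaller than the SDs real cohorts show. Tests passing on
  synthetic data therefore establish the pipeline's *correctness*, not the
  *power* or significance pattern of any real study: in particular,
  one-sample tests of small mean increments reject far more readily on
  synthetic cohorts than they would on clinical data with clustered decay.
* **Time-varying hazards.** The kernels are homogeneous across the three
  steps, so expected increments grow near-linearly; real cohorts can show
  flat or super-linear stretches.
* **Risk misclassification, seasonal effects, eruption timing** (the
  surface set is fixed per child), and any covariate-driven mechanism for
  attendance (attrition is completely at random).

## Reporting conventions

Percentages are recomputed from the counts printed beside them. Rate-style
tables round half-up at 1 decimal (0 for response rates), surface-share
tables at 2 decimals. Distribution rows in the demographics table use
**largest-remainder rounding** so each row sums to exactly 100 — the
convention of clinical survey tables, where a 39.8/30.5/29.7 split is
preferred to one summing to 99.9. The increment tables record whether
observed-only or imputed-complete data produced each cell; both modes are
provided because aggregate reports rarely state which was used.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make Monte-Carlo checks
sharp while keeping a full run under a minute: module tests use 24–45-child
cohorts with 20–60 surfaces; the law-of-large-numbers check uses 3,000
children; conservation sweeps 1,000 children; the type-I-error simulation
runs 1,000 null repeated-measures datasets of 60 children; parameter
recovery runs the default configuration at ×10 size (2,260 children,
284,760 surfaces). `scripts/acceptance.R` runs the default 226-child
configuration end to end in a few seconds.

## Known limitations

* The increment is surface-count-scaled and unweighted: a new occlusal
  cavity and a new code-A lesion contribute equally under A-6. No severity
  weighting beyond the two cutoffs is offered.
* Anterior teeth use the same five-surface scheme as posterior teeth (with
  occlusal read as incisal). Four-surface anterior scoring would change
  denominators by ≤ 8%; published per-child surface counts are consistent
  with the five-slot scheme.
* The hot-deck imputation assumes missingness is ignorable within risk
  stratum; informative dropout (sicker children leaving) would bias stratum
  means downward and is not modelled.
* The recall rule is per-stratum, not per-child, and its 6-month evidence
  test answers "any progression at all?", which at large n is significant
  for any nonzero progression rate — policy use should read the effect
  sizes (the increment means) alongside the p-values.
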