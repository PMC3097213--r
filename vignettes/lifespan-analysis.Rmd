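---
title: "Quantifying ageing from cohort lifespans: maximum-lifespan statistics, AFT time ratios, and the phenoloxidase assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ageing from cohort lifespans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemax)
```

## The scientific problem

In experimental ageing studies — here, mealworm beetle (*Tenebrio molitor*)
cohorts given a non-infectious immune challenge (nylon filament or
heat-killed bacteria) at the larval or adult stage — the question is whether
the challenge *accelerates ageing*, not merely whether it shortens life on
average. `agemax` implements the two complementary analyses such designs
call for, together with the simulation machinery needed to test them when
individual-level lifespans are not publicly available:

1. **Maximum lifespan.** Ageing specifically erodes the right tail of the
   survival distribution, so the operational statistic is a high quantile of
   survival time, conventionally the 90th percentile. A single threshold is
   fixed — the 90th percentile of *all* lifespans pooled across groups — and
   each group's proportion of individuals surviving to it is compared.
2. **Median lifespan.** Parametric accelerated failure time (AFT) models
   estimate, per treatment group, a time ratio *c* by which the whole
   survival curve is rescaled relative to control; *c* = 0.9 means the
   treated arm lives 90% as long at every survival quantile.

A third, physiological, module asks whether a lifespan effect could be a
resource trade-off rather than damage: it extracts phenoloxidase activity
(Vmax) from kinetic absorbance traces and compares group means by one-way
ANOVA.

## Maximum lifespan and the exact unconditional test

For a comparison of control versus treatment, `compare_max_lifespan()`
counts survivors to the pooled threshold inclusively (an individual dying on
the threshold day survived to it), forms the 2×2 table, and reports the
**ageing-acceleration ratio** — the control survivor proportion divided by
the treatment survivor proportion, so values above 1 mean accelerated
ageing. The threshold is always computed over the whole dataset, not the
pair being compared: one threshold serves every comparison in a report, so
the per-group proportions are commensurable across rows.

Survivor counts at a high quantile are small, so asymptotic tests are
unreliable and conditional exact tests (Fisher) sacrifice power by fixing
both margins. The package therefore implements the **exact unconditional
z-pooled test**: the pooled-variance score statistic

$$ z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\bar p(1-\bar p)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
  \qquad \bar p = \frac{x_1+x_2}{n_1+n_2}, $$

with the two-sided p-value defined as the supremum over the unknown common
success probability $p \in (0,1)$ of the null probability of every outcome
table with $|z| \ge |z_{\mathrm{obs}}|$. Conventions, each chosen once:

* **Sidedness** is two-sided via $|z|$; the signed statistic is reported.
* **Degenerate pool**: when all observations are successes or all failures,
  $z = 0$ (the difference of proportions is 0 there).
* **Ties**: outcomes with $|z|$ exactly equal to $|z_{\mathrm{obs}}|$ are
  included in the rejection region.
* **Supremum strategy**: a uniform grid of 1000 interior points, then
  continuous maximisation around the top grid local maxima (the tail
  function can be multimodal for small tables). The full-range supremum is
  used — no Berger–Boos confidence-interval truncation of the nuisance
  range.
* Binomial masses are evaluated in log space, so arms of several hundred
  individuals are handled without underflow.

Correctness is anchored two ways, kept deliberately independent: a
brute-force oracle (`oracle_exact_p()`: plain enumeration on a dense
10001-point grid, no refinement, no log-space tricks) agrees with the
production routine to 10⁻⁶ over the complete sweep of tables up to 8 trials
per arm; and a hand-enumerable case — table (3,3) vs (0,3), rejection region
$\{(3,0),(0,3)\}$, tail $2p^3(1-p)^3$ maximised at $p=1/2$ — gives exactly
$2/64 = 0.03125$. For null simulations (size calibration),
`exact_unconditional_p_all()` computes the p-value of *every* table with
fixed group sizes in one grid sweep; simulated tables then index into the
result, which makes a 30 000-replicate size study a matter of seconds. The
simulated size at nominal α = 0.05 stays at or below 0.055 — unconditional
exact tests are conservative or size-α, never anti-conservative.

The **divergence scan** (`divergence_scan()`) walks the quantiles of overall
survival time; at each corresponding day it forms the groups × (alive,
dead) table and applies Pearson's chi-squared test without continuity
correction (7 groups ⇒ 6 degrees of freedom). Days at which every
individual is in one state are skipped with an annotation rather than
forced. The earliest quantile with p < α summarises when the survival
curves begin to differ — the signature of a *delayed* cost of early-life
immune challenge.

## AFT models and the c-parameter

`fit_aft()` wraps maximum-likelihood location-scale survival regression
(`survival::survreg`) for four families: Weibull, exponential (Weibull with
the error scale fixed at 1), lognormal — all acting on log time — and
gaussian on untransformed time. For the log-time families the treatment
coefficient β gives the time ratio $c = e^\beta$ with a 95% Wald interval
$e^{\beta \pm 1.96\,\mathrm{se}}$. Choices worth stating:

* **Gaussian family.** An additive model on raw time has no constant time
  ratio; to keep the single-*c* reporting interface uniform its *c* is the
  ratio of predicted median survival times (treatment/control), transformed
  endpoints for the CI, and the fit is flagged `c_is_median_ratio`.
* **AIC** is $-2\ell + 2k$ with $k \in \{2, 3\}$. Since all four families
  are fit to the same response, AIC and raw $-2\ell$ orderings can differ
  only between the nested exponential/Weibull pair; both are reported by
  `select_distribution()`, with ties broken toward fewer parameters and
  then the declared family order.
* **Confidence intervals** are Wald on the coefficient scale. Profile
  likelihood intervals would be a reasonable extension; Wald coverage is
  verified by simulation (below) at 0.95 within Monte Carlo error.
* **Self-comparison reference.** Comparing the control arm against itself
  (the data duplicated, indicator 0/1) forces the maximum-likelihood β to 0,
  so the reference row in `aft_report()` has *c* = 1 by construction — a
  useful anchor when plotting treatment effects with their intervals.
* Right-censored records enter the likelihood in the standard way;
  the quantile-based maximum-lifespan analyses instead refuse censored
  input, since an empirical quantile of censored data is not the quantile
  of the lifespan distribution.
* `survreg` is run with a tightened relative tolerance (10⁻¹¹), which makes
  analytically forced cases — e.g. a treatment arm that is exactly 0.9
  times the control arm, where β must equal log 0.9 — reproduce to 10⁻⁶.

`qq_diagnostic()` tabulates matched empirical quantiles of the two arms and
their ratio: constant ratio means a clean AFT effect; a ratio nearer 1 at
low probabilities than high ones is the fingerprint of a delayed effect.

## The cohort generator

`generate_cohort()` draws lifespans as

$$ T = \text{onset} + c \times \mathrm{Weibull}(k, \lambda), $$

one seeded stream per call, groups drawn in declared order, the full
configuration recorded in the dataset metadata. The design choices:

* **Effect mechanism** is a pure time ratio on the Weibull draw —
  AFT-consistent by construction, matching the analysis the data feed.
* **Delayed divergence** is a shared `onset_days` offset added *after*
  scaling: early survival is then near-identical across groups. This
  deliberately makes the AFT *c* fitted to full lifespans deviate slightly
  from the configured *c* (the offset dilutes the ratio), mirroring how a
  juvenile period shared by all groups dilutes a proportional effect on
  adult survival. Tests of *c*-recovery therefore use `onset_days = 0`,
  where the generator and the model coincide exactly.
* **The preset** (`generate_tenebrio_cohort()`) fixes the published design:
  group sizes 133/69/62/97/29/58/32, time ratios 1.000 down to 0.836,
  Weibull shape 8, onset 60 days, and scale calibrated in closed form so
  the Control group's theoretical 90th percentile is 224 days
  ($\lambda = (224-\text{onset})/\log(10)^{1/k}$). Shape 8 is a typical
  adult-insect value (coefficient of variation ≈ 15%, strongly senescent
  mortality); no shape was published, so this is a modelling choice,
  recorded in the metadata.

What the generator does *not* emulate: individual covariates (mass, sex),
heterogeneous frailty, non-Weibull early-death tails, or censoring.
Passing tests therefore demonstrate that the pipeline recovers what it
assumes — time-ratio effects on a smooth parametric baseline — not that
real beetle cohorts satisfy those assumptions.

The trace generator (`generate_trace()`) produces the canonical three-phase
kinetic read: flat lag, linear rise at the configured velocity, plateau,
plus iid Gaussian read noise. Defaults emulate a 60-minute L-DOPA
phenoloxidase assay read every 15 s (241 readings): 300 s lag, 5 mOD/min,
plateau at 0.25 OD from a 0.05 OD baseline, 0.5 mOD noise.

## Vmax extraction: windowing rules

The manual practice the extractor replaces is reading the slope "where the
reaction proceeds in a straight line". `extract_vmax()` makes that
algorithmic in two steps over all contiguous windows of at least
`min_window` readings (default 20 = 5 min) meeting R² ≥ 0.99:

1. the maximal-slope qualifying window **anchors** the read-out — Vmax is by
   definition the maximal reaction velocity, and the anchor locates the
   steepest phase while lag and plateau windows fail the linearity bar;
2. the reported slope comes from the **maximal-R² qualifying window
   containing the anchor** — in a well-behaved trace, the entire linear
   phase, since R² grows with window length inside the clean phase and
   falls as soon as lag or plateau readings contaminate it.

Step 2 exists because the naive "report the steepest window's own slope"
rule is materially biased under read noise: the maximum over many short
overlapping windows systematically selects upward noise excursions (about
+4% at the default noise level), whereas anchoring and then widening to the
most linear containing window is empirically unbiased (relative error
~10⁻⁴ with SD below 0.1%) while still resolving traces whose segments have
genuinely different slopes. Two conventions: a numerically flat window is
perfectly linear (R² = 1, slope ≈ 0 — a flat trace yields Vmax 0,
unflagged), and when no window qualifies the full-trace fit is returned
with `flagged = TRUE`; flagged samples are excluded from the downstream
ANOVA by `po_pipeline()` with a logged count. Slopes are reported in
mOD/min regardless of the reading interval.

The group comparison is the classic equal-variance one-way ANOVA
(`anova_oneway()`, via `stats::oneway.test`), with group means, standard
errors and the sum-of-squares decomposition attached; its null rejection
rate calibrates to α within binomial error in simulation.

## Numerical and interface choices

* **Quantile estimator**: linear interpolation of order statistics,
  position $h = (n-1)q + 1$ (R's type 7) — the most widespread default.
  Integer-valued published thresholds are consistent with several
  estimators; the choice is recorded here and used consistently
  throughout (pooled and per-group quantiles, divergence scan, QQ
  diagnostics).
* **Pooled comparisons** concatenate raw individuals, never average
  proportions — matching the contingency-table view of the data.
* **Time origin**: lifespans carry one declared origin in the dataset
  metadata (`time_origin`); every analysis is within-dataset, so the
  analyses are origin-agnostic. Whether a published integer threshold
  counts from hatch, treatment, or eclosion cannot be decided from
  summaries alone, and the package does not guess.
* **Validation** collects *all* offending rows (unknown labels,
  non-positive lifespans, duplicate ids, stage/antigen inconsistencies)
  and reports them together, rather than failing on the first.
* **Determinism**: every stochastic entry point takes a seed and restores
  the caller's RNG state; `run_report()` output is byte-identical for
  identical input and configuration (no timestamps).

## Problem sizes used by the test suite

The suite verifies, among others: oracle equivalence over the complete
enumeration of 2×2 tables up to 8 trials per arm plus 200 random tables up
to 15; test size on 10 000 simulated null tables at 60/60 for each of
p ∈ {0.1, 0.5, 0.9}; time-ratio recovery (mean within 0.02, CI coverage in
[0.92, 0.98]) over 500 replicates at 130 per arm for c* ∈ {0.84, 0.89,
0.95}; AIC selection of the generating family over 100 replicates at 500
per arm; Vmax recovery within 2% over 100 seeded traces; and ANOVA null
calibration over 2000 simulated datasets. These sizes keep each property
statistically sharp while the whole suite completes in a few minutes on a
single core.

## Known limitations

* The AFT confidence intervals are Wald; for very small arms (a few dozen)
  profile intervals would be preferable.
* The gaussian family's median-ratio *c* is not a time ratio; comparisons
  of *c* across families should be restricted to the log-time families.
* The divergence scan tests each quantile marginally; it makes no
  multiplicity adjustment, because its role is descriptive (locating the
  earliest divergence), not confirmatory.
* The unconditional exact test's nuisance supremum is located numerically;
  the grid-plus-refinement scheme is verified against the oracle only on
  small tables, and for very large tables the grid resolution (not the
  arithmetic) bounds accuracy.
* `exact_unconditional_p_all()` omits the continuous refinement step; it is
  intended for simulation studies, where the omission is orders of
  magnitude below simulation noise.
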