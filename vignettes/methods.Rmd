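---
title: "Methods: from blinded CGM and diary check-ins to daily-functioning models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from blinded CGM and diary check-ins to daily-functioning models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

People with insulin-treated diabetes experience hypoglycaemia that a blinded
continuous glucose monitor (CGM) can see but the person may not, and
episodes the person perceives that the sensor never confirms. `glucodiary`
implements a pipeline for asking which of these exposures — sensor-detected
hypoglycaemia (SDH), person-reported hypoglycaemia (PRH), or both — is
followed by worse self-reported daily functioning, using ecological
momentary assessment (EMA): brief app check-ins submitted every morning
(scheduled 07:00), afternoon (15:00) and evening (21:00), each scoring
several 0–10 functioning domains where higher is better.

The pipeline has five analytic stages, each a module with its own contract:

1. **CGM processing** — snap each participant's 5-minute glucose trace onto
   a clock-aligned grid, detect SDH episodes, and compute time-in-range
   summaries.
2. **Interval construction** — use morning and evening submission times to
   cut each 24-hour period into a daytime and a night-time exposure
   interval, and exclude intervals with poor sensor coverage.
3. **Classification** — label every valid interval A (no hypoglycaemia),
   B (SDH only), C (PRH only) or D (both), plus PRH detection/management
   subtypes and an SDH severity subtype.
4. **Modelling** — per cohort (type 1 / type 2 diabetes), phase and domain,
   regress the functioning score on the interval category with a
   participant random intercept, robust weighting, an AR(1) correction and
   Bonferroni multiplicity control, and present effects as percent change
   from the intercept.
5. **Synthesis** — a fully seeded generator that produces traces, check-ins
   and covariates with known ground truth, so every stage above is testable
   without access to any restricted cohort data.

# Episode detection

SDH is defined as interstitial glucose strictly below 3.9 mmol/l sustained
for at least 15 minutes. Working on the regularised 5-minute grid, we adopt
the convention that **each reading represents 5 minutes of coverage**, so
"at least 15 minutes" is exactly "at least 3 consecutive sub-threshold
readings". This makes the rule discretely testable and matches consensus
CGM practice. An episode is a maximal run of consecutive non-missing
sub-threshold readings; it ends at the first reading at or above the
threshold, or at a sensor gap whose *missing coverage* exceeds 10 minutes.
Under the same coverage convention a gap of one or two missing slots
(5–10 minutes of missing coverage) is bridged, three or more slots break
the run. Missing slots never add to an episode's covered duration, and
glucose is never interpolated — gaps are carried forward to the coverage
filter instead, so episodes remain verifiable against the raw data.

The episode nadir (minimum glucose in the run) sets the severity subtype:
nadir in [3.0, 3.9) → `SDH_3.9`; in (2.2, 3.0) → `SDH_3.0`; at or below
2.2 mmol/l → `SDH_2.2`. "Below threshold" is strict (< 3.9), matching the
printed inequality; the time-in-range summary counts both 3.9 and
10.0 mmol/l as in range (inclusive bounds).

The detector is verified against a brute-force oracle (grow-from-every-
start maximal-window enumeration) exhaustively over all short
sub-threshold/in-range/missing patterns and over a thousand random 24-hour
traces; the tests also check threshold monotonicity and that episode flanks
are never unexplained sub-threshold readings.

# Intervals, reporting and the coverage filter

Submission times — not scheduled times — bound the exposure intervals: the
daytime interval runs from the morning submission to the evening
submission, whose check-in carries the day's PRH report; the night-time
interval runs from the evening submission to the next morning's
submission, whose check-in reports the night. Three boundary rules are
choices the source design left open, fixed here as:

* **Missing boundary check-in** (the non-reporting end): its scheduled
  clock time (07:00 or 21:00) delimits the interval.
* **Missing reporting check-in**: the interval is emitted but invalid,
  with reason `"no reporting check-in"` — exposure without an outcome
  report cannot enter the models.
* **Duplicate check-ins** (same participant, date, kind): the earliest
  submission wins; deterministic and auditable.

Submissions are accepted within a 6-hour response window opening at the
scheduled time (configurable, and overridable at load). Afternoon
check-ins are parsed but excluded from analysis.

Sensor coverage is the percentage of expected 5-minute slots
(`floor(duration / 5 min)`) with a non-missing reading. An interval is
excluded only when *strictly more than* 30% of its expected slots are
missing — an interval with exactly 30% missing is retained. The percentage
is computed with integer counts so this boundary is exact in floating
point.

PRH follow-up answers are coded on two axes — detection (symptomatic vs
asymptomatic, i.e. noticed via the person's own glucose monitoring) and
management (treated, prevented, other). Prevented episodes count as PRH
present. When an interval carries several reports they merge by an ordered
ranking (symptomatic > asymptomatic; treated > prevented > other), chosen
to mirror the observed impact gradient and exposed as a configurable
table. Reports flagged as adjudicated severe hypoglycaemia are dropped
before coding. An episode straddling the day/night boundary counts in an
interval only through its clipped portion, which must itself sustain
15 minutes — night and day exposures therefore never double-count, at the
price that a boundary-straddling episode can vanish from both (an
enumerable edge case the recovery tests tolerate at below 1%).

# The multilevel model

For each cohort × phase × domain, the model is

$$y_{ij} = \beta_0 + \boldsymbol{x}_{ij}^\top\boldsymbol{\beta}
  + \boldsymbol{z}_{ij}^\top\boldsymbol{\gamma} + b_i + \varepsilon_{ij},$$

where $y_{ij}$ is the 0–10 score of participant $i$ after interval $j$,
$\boldsymbol{x}_{ij}$ are exposure dummies with "no hypoglycaemia" as
reference, $\boldsymbol{z}_{ij}$ baseline covariates,
$b_i \sim N(0, \sigma_b^2)$ a participant random intercept and
$\varepsilon_{ij}$ residuals with within-participant AR(1) working
correlation. Estimation choices, each a documented default:

* **Robust weighting.** Bounded 0–10 scores produce skewed, heteroscedastic
  residuals, so the fit is iteratively reweighted with Huber weights
  (tuning constant 1.345, 95% Gaussian efficiency) on MAD-scaled
  residuals; the random intercept is retained throughout, and a plain ML
  fit is available via `robust = FALSE`. Weights usually settle within
  3–5 iterations at the default tolerance of `1e-4`.
* **Autocorrelation.** Two-stage: the lag-1 correlation of the weighted
  fit's residuals (ordered by interval start within participant) estimates
  $\rho$, then the model is refitted once with that AR(1) correlation held
  fixed. Whether robust weights and the AR structure should be estimated
  jointly is genuinely open; the sequential scheme is transparent and
  reproducible.
* **Pairwise deletion.** Each model drops only rows missing its own
  outcome, exposure or covariates.
* **Wald inference.** 95% CIs are estimate ± 1.96 × SE and p values use
  the normal approximation — defensible with hundreds of participants.
* **Percent change.** Effects are presented as
  $100 \cdot \beta / \beta_0$, with CI bounds transformed by the same
  division. The intercept is treated as fixed in this transform (no delta
  method); numeric covariates are mean-centred so the intercept remains
  the expected score of the reference category and the approximation error
  stays second-order. Bounds are re-sorted after division so the lower
  bound never exceeds the upper even if an intercept were negative.
* **Multiplicity.** The primary (category A–D) family is tested at
  $\alpha = 0.05 / 266$, where $266 = (10 + 9) \times 2 \times 7$ counts
  morning domains, evening domains, cohorts and the seven model iterations
  explored during model development (only the final model is implemented;
  the 7 enters solely through the count). Exploratory subtype families
  (PRH subtypes adjusted for SDH presence; SDH subtypes adjusted for PRH
  presence) are flagged `adjusted_for_multiplicity = FALSE` and use
  unadjusted 0.05.

Linear modelling of bounded outcomes is deliberate (matching standard
practice for these instruments); clipping-induced attenuation is measured
by the recovery tests rather than corrected.

# What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study conditions: 274 + 320
participants, 70 days, 5-minute cadence, morning/evening completion 0.86
and 0.90. Glucose is a discretised mean-reverting process around a
participant baseline drawn from 7.5–9 mmol/l with stationary SD
0.9 mmol/l — high enough to look like CGM, calm enough that spontaneous
sustained dips below 3.9 are rare — with hypoglycaemic excursions inserted
as plateaus at a drawn nadir (strata 70% / 22% / 8% across the three
severity bands) with short ramps, at Poisson rates 0.28 per night and 0.31
per day. With those rates the no-hypoglycaemia share is
$e^{-0.28}(1 - 0.06) \approx 0.71$ of nights, near the emulated 72%/64%
night/day pattern. A sensor excursion is person-reported with probability
0.45; false reports occur at 0.06 per night (×1.6 by day); reports are
70% symptomatic and 60/30/10% treated/prevented/other. Scores are domain
mean (default 7) + participant intercept (SD 1.0) + a category × domain
effect + AR(1) noise (SD 1.5, ρ = 0.3), clipped to [0, 10] — clipping, not
resampling, because the instrument itself truncates; the resulting small
attenuation is visible to, not hidden from, the recovery tests. The
default effect matrix (B −0.05, C −0.45, D −0.70 points) reproduces the
qualitative ordering of interest, with type D near −10% of a 7.0
intercept. Sensor dropout arrives in runs (mean six slots) at 3% of slots.

Ground truth (per-interval true category, effect matrix, participant
intercepts) is returned alongside the data, and identical `(config, seed)`
reproduce byte-identical files.

The generator is *not* physiologically realistic: no meals, insulin or
circadian structure; excursions are placed well inside the nominal
night/day windows so truth labels are unambiguous; score residuals are
Gaussian before clipping. Passing tests therefore demonstrate the
pipeline's correctness and the estimator's statistical behaviour under
controlled conditions — they do not validate the substantive findings on
real cohort data, which remain access-restricted.

# Numerical choices and degenerate inputs

* Grid assignment is nearest-tick with ties toward the earlier slot; slot
  conflicts keep the temporally closest sample and are counted.
* Coverage percentages and the 30% boundary use integer slot counts.
* `fit_domain_model()` errors on a single participant or a single observed
  exposure level; unobserved levels are dropped; non-convergence (weights
  not settled, or the AR refit failing) is reported honestly via
  `converged = FALSE` rather than masked.
* An all-missing trace makes the glycaemic summary error rather than
  return `NaN`; a zero-length interval makes coverage error.
* Determinism end to end: `run_pipeline()` artifacts hash identically
  across re-runs of the same configuration and seed (the manifest's config
  digest excludes the output directory).

# Problem sizes used in the shipped checks

The shipped test-and-verification runs use deliberately scaled problem
sizes chosen to exercise every code path at desk scale: end-to-end
pipeline tests simulate 12–20 participants over 8–12 days; the
detector–oracle equivalence sweeps all ternary patterns to length 7 plus
1,000 random 24-hour traces; the type-I-error study uses 200 participants
× 60 nights × 200 replicates and the effect-recovery study 200 × 60 × 100
replicates (both through the interval-level score generator); the
reproduction script `scripts/acceptance.R` runs the full pipeline at 80
participants × 21 days. The parent-scale defaults (594 × 70) remain the
generator's defaults and run unchanged, just longer.

# Known limitations

* Percent-change CIs ignore intercept uncertainty.
* The AR(1) working correlation treats check-in sequence as equally
  spaced; calendar gaps from missed check-ins are ordered, not weighted.
* The merged-report ranking is a documented, configurable substitute for
  an instrument-specific coding table that is not publicly printed.
* Single fixed time offset per participant; no time-zone arithmetic.
* Linear models on bounded scores attenuate effects near the scale ends;
  the generator quantifies this but the estimator does not correct it.
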