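---
title: "Propensity-matched analysis of intraoperative hypotension: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-matched analysis of intraoperative hypotension: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twamatch)
```

`twamatch` implements the analysis chain of a retrospective,
propensity-score-matched evaluation of intraoperative hypotension under
predictive hemodynamic monitoring: hypotension burden metrics on
fixed-interval arterial-pressure series, logistic propensity scores with
greedy caliper matching and standardized-mean-difference (SMD) balance
diagnostics, normality-gated group-comparison tables, a creatinine-based
acute-kidney-injury (AKI) classifier, and a synthetic cohort generator
that provides the confounded data such an analysis is designed for. This
vignette records the model, the conventions, and the design decisions —
including the ones where the methodological literature leaves genuine
freedom.

## Hypotension burden metrics

All metrics operate on a `vital_trace`: a mean-arterial-pressure (MAP)
series sampled at a constant interval (default 30 s, the resolution of
the anesthesia record systems this emulates), optionally accompanied by a
0–100 prediction-index channel.

**Time-weighted average.** The TWA of hypotension below a threshold
$\theta$ is the deficit area below $\theta$ divided by the total
monitoring time:
$$\mathrm{TWA}(\theta) = \frac{\sum_i \max(0,\,\theta - \mathrm{MAP}_i)\,\Delta t}{N\,\Delta t},$$
in mmHg. We integrate by the per-sample rectangle rule with no
interpolation at threshold crossings: at a 30-s sampling interval,
sub-interval crossing interpolation would be spurious precision. The TWA
therefore reduces to the mean per-sample deficit, which is what
`twa_below()` computes (and what the brute-force loop oracle in the test
suite verifies to 10⁻¹² relative error). Monitoring time is the full
trace span, with each sample representing one interval.

**Episodes.** A hypotensive event is a maximal run of consecutive samples
below threshold. Because clinical studies rarely state their event
delimitation, `detect_episodes()` exposes two parameters: a minimum
episode duration (default 60 s — the one-minute convention of the
hypotension outcome literature) and a merge gap (default 0 s) that fuses
runs separated by brief recoveries. With both at zero, the sum of episode
durations equals the cumulative duration below threshold, a consistency
invariant under test. Cumulative duration itself counts *all*
below-threshold samples, regardless of event filtering, as clinical
endpoint tables do.

**Alarms.** One alarm is one maximal run of index samples **at or above**
85. We adopt the at-or-above convention because it is how the index's
trigger is described in the clinical literature ("equal or greater than
85"); table labels that read "> 85" are treated as loose labeling. The
threshold is a parameter. A missing index channel is an error, not a zero
count: absence of monitoring is not absence of alarms.

**Prevented events.** Defined per patient as
$\max(0, \text{alarms} - \text{events})$ and summed over a group. The
published arithmetic this mirrors contrasts group medians (8 alarms vs 2
events per patient → 6 prevented per patient, ×136 patients → 816); our
definition is per-patient first, then aggregated, with an explicit floor
at zero since a patient can realize more events than alarms.

## The propensity model and matching

`fit_propensity()` fits treatment on covariates by maximum-likelihood
logistic regression (iteratively reweighted least squares — Fisher
scoring). Two failure modes are explicit errors rather than quietly
diverged fits: a rank-deficient design (the error names the collinear
columns) and perfect or quasi-perfect separation (detected by fitted
probabilities at the numerical boundary; the error names the covariates
with dominant standardized coefficients). Missing covariate values are a
hard error — the design restricts to complete cases, no imputation.
Categorical covariates are expanded to indicator columns with the first
level as reference.

`match_caliper()` performs greedy 1:1 nearest-neighbor matching without
replacement. Treated units are processed in **descending propensity
score** with ties broken by ascending id; each takes the nearest
unmatched control in logit-score distance, provided the distance is
within the caliper, otherwise the unit remains unmatched. Greedy matching
is order-dependent, so the order rule is fixed and documented, and a
permutation-invariance test guarantees the pair set does not depend on
input row order. The caliper is expressed in **SD units of the logit of
the propensity score** (default 0.1): the phrase "caliper of 0.1" in the
applied literature almost always means this convention, which is also the
default of the widely used matching software; a raw-probability caliper
is available via `caliper_scale = "probability"`. Matched-pair counts are
non-decreasing in the caliper over the 0.1–0.5 robustness range, a
property under test.

**Balance.** `smd_continuous()` uses
$(\bar x_t - \bar x_c)/\sqrt{(s_t^2 + s_c^2)/2}$ with $n-1$ variances;
`smd_binary()` uses the proportion analogue on raw (unrounded)
proportions. Multi-level categoricals are expanded to per-level
indicators, each reported, with the variable summarized by its
maximum-absolute level SMD; published single-number SMDs for multi-level
variables rest on an unstated formula, so we document our convention
rather than claim equivalence. Degenerate cases are defined explicitly:
equal means at zero pooled variance give 0, unequal ones signed infinity
with a warning. The balance criterion used throughout is max |SMD| < 0.2.

## Comparison tables and outcome statistics

`build_comparison_table()` mirrors clinical baseline tables: one row per
variable, the two arms summarized side by side. Continuous variables pass
a Shapiro–Wilk normality gate at α = 0.05 **in both groups**; only if
both pass is Student's t-test used with mean (SD) summaries, otherwise
the Mann–Whitney U-test with median (IQR). The per-group (rather than
pooled-residual) gate is a documented choice where the convention is
unstated. Quartiles are type-7 linear interpolation (R's default)
everywhere, so printed IQRs should not be over-interpreted against
software using other quantile definitions. Categorical variables use the
Fisher exact test (for tables beyond 2×2, the exact network algorithm
with enlarged workspace, falling back to a chi-square approximation with
a warning only if the exact computation is infeasible). No
multiple-testing adjustment is applied, matching the reporting practice
this emulates; all tests are two-sided. The rank-sum and Fisher wrappers
are verified against independent full-enumeration oracles on small
instances, and their empirical type-I error is checked at ≤ 6% for
nominal α = 0.05.

**AKI.** `classify_aki()` is positive when creatinine rises by *strictly
more than* 0.3 mg/dL above baseline within 48 h of surgery end, or
reaches *at least* 1.5× baseline within 7 days (or the end of laboratory
follow-up, whichever is earlier). "More than" is read as strict and
"1.5 times" as inclusive; both thresholds and windows are parameters. The
window origin is surgery end (the alternative — ICU admission — is
unstated in the source conventions). Comparisons carry a 10⁻⁹ tolerance
so values exactly at a clinical boundary (a rise of exactly 0.30, or
exactly 1.5-fold) are classified by the stated rule, not by
floating-point representation. The classifier is monotone: raising any
postoperative value never revokes an AKI call (property under test). The
48-h delta criterion is checked first when both fire.

## The synthetic cohort generator

No public registry of this kind exists, so the generator *is* the data
source for every end-to-end test. It emulates the statistical structure
the analysis assumes; its defaults were fixed at design time and define
the package's reference study conditions.

**Covariates.** Marginals loosely match the demography of a
moderate/high-risk non-cardiac surgery registry: age ~ N(69, 10²),
63% male, BMI ~ N(27.5, 4.5²), physical-status class II/III/IV with
probabilities 0.28/0.62/0.10, 17% emergencies, 46% epidural catheters,
lognormal case duration (median ≈ 200 min, all > 30 min — the inclusion
threshold), four-level surgical approach, comorbidity and medication
prevalences in the 8–64% range. Exact distributional families (normal
age, lognormal duration) are our choice; only summary statistics are
emulated, not the joint distribution.

**Assignment.** Treatment ("HPI" monitoring) is Bernoulli with logit
linear in covariates. Defaults: −2.2 per emergency, +1.1 per epidural,
+0.005 per minute of case duration, −0.7 per physical-status class, with
the intercept (0.8) centring the linear predictor so the expected arm
split is about 50/50. Balanced arms are the neutral default — consistent
with the all-zero-coefficients null, which must give a 50/50 split — and
real registries' unbalanced shares (e.g. ~27% treated) are reachable
through the intercept. These weights make emergency cases predominantly
control and long epidural cases predominantly treated, driving
pre-matching |SMD| for emergency, epidural and duration well above 0.2,
as in the confounded registries this emulates.

**Episodes and the alarm channel.** Incipient hypotensive episodes arrive
as a homogeneous Poisson process (default 1.0/h) over the case; the
source literature gives no arrival model, and this is the simplest
process with a tunable burden. Depths are gamma (shape 4, mean 18 mmHg
below a per-patient baseline ~ N(78, 6²)), durations gamma (shape 2, mean
3 min). The trace is baseline + slow sinusoidal drift (amplitude 3 mmHg)
+ Gaussian noise (SD 2 mmHg) − episode deficit, with raised-cosine
episode onsets/offsets, clipped to [20, 200] mmHg; overlapping episodes
take the deepest deficit per sample. The drift amplitude is an explicit
argument of `generate_map_trace()` defaulting to zero, so a noise-free
call returns the deterministic baseline-minus-deficit signal; the cohort
generator passes the nonzero default. In the treated arm the episode rate
and mean duration are scaled by `treatment_effect_multiplier` (default
0.85), an index alarm is planted 300 s before each incipient onset (the
5-minute prediction horizon of the index this emulates; a 120-s hold at
≥ 85), and each incipient episode is independently **averted** — alarm
left in place, no pressure dip — with probability 0.6. Alarms are planted
relative to ground-truth incipient episodes rather than computed from
waveform features, because the real index algorithm is proprietary and
out of scope. Alarm windows of near-simultaneous episodes can merge into
one run, so measured alarm counts slightly undercount incipient episodes;
the prevented-events calibration test accounts for this.

**Creatinine.** AKI is drawn per patient with probability
$\mathrm{expit}(\mathrm{logit}(0.08) + 1.5 \cdot \mathrm{TWA}(65))$; the
base probability and slope are configurable. One value per 24 h for 7
days (the observation windows are stated in the conventions this follows;
the daily schedule is our choice). Emitted series are consistent with the
classifier by construction: an AKI draw guarantees a qualifying rise
within 48 h, a non-AKI draw keeps all values strictly below both
criteria — an agreement verified exhaustively in the tests.

**Monitoring start.** Traces begin at arterial-line placement (after
anesthesia induction); pre-induction hypotension is unobservable here, as
it is in the registries this emulates.

**Determinism.** A `sim_config` seed makes cohorts and traces
bit-reproducible; `run_all()` writes byte-identical outputs for identical
config + seed (no timestamps in any output).

## What the simulations do and do not show

Passing end-to-end tests on synthetic cohorts shows that the pipeline
recovers a known treatment effect under known confounding: with the
default effect (rate multiplier 0.85, aversion 0.6), the matched-cohort
median TWA(65) contrast has the correct sign in ≥ 95% of replicates at
n = 600, and with the effect switched off, matched-cohort rank-sum
p-values are approximately uniform. It does **not** show that the
propensity model is correctly specified for any real registry (in the
simulator, assignment truly is logistic in the covariates — the best case
for the method), nor that real MAP artifacts (flushes, transducer drift,
disconnections) are handled: artifact rejection beyond range clipping is
out of scope. Covariate joint structure, drug pharmacokinetics and
measurement-modality discrepancies are deliberately not modelled.

## Problem sizes and numerical tolerances

The reference balance demonstration uses n = 800 (about 400 treated),
caliper 0.1, all 23 matching covariates (26 design columns): across
seeds this yields roughly 220–250 matched pairs and post-matching
max |SMD| around 0.08–0.18. With a few hundred pairs the per-covariate
SMD sampling SD is ≈ 0.08, so the maximum over ~26 columns sits well
below 0.2 in typical runs but is genuinely stochastic — the acceptance
check on this quantity is a property of the study conditions, not a
deterministic constant. Property suites use 1 000 random traces for the
TWA oracle, 100 simulation replicates at n = 600 for effect-sign
recovery, 5 000 instances per test for type-I error, and grid-search
likelihood maximization (final resolution 4×10⁻⁴) as the logistic
oracle. IRLS tolerance is 10⁻⁸ with at most 25 iterations. These sizes
keep the full suite to a few minutes on one CPU while leaving
Monte-Carlo error well inside each test's margin.

## Known limitations

* Greedy matching is not optimal matching; with heavy treated/control
  imbalance near the score boundary it discards treated units an optimal
  algorithm might pair. Optimal/full matching, weighting and doubly
  robust estimation are out of scope.
* The per-level categorical SMD convention is not comparable to
  single-number categorical SMDs produced by other software.
* The alarm channel is planted, not computed from waveform morphology;
  alarm-performance metrics (sensitivity/specificity of the index) are
  not meaningful here.
* Episode delimitation defaults (60 s minimum, no gap merging) change
  event counts if altered; TWA and cumulative duration are unaffected by
  these parameters.
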