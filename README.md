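# twamatch

Propensity-score-matched analysis of intraoperative hypotension burden.

## The problem

Intraoperative hypotension — mean arterial pressure (MAP) below 65 mmHg —
is common during non-cardiac surgery and is associated with myocardial and
kidney injury. Predictive monitoring systems raise an alarm minutes before
an incipient hypotensive episode, giving the anesthesiologist time to
intervene; but in retrospective registries the decision to use such
monitoring is confounded by case mix (emergency status, epidural
analgesia, case duration, physical-status class). `twamatch` implements
the full analysis pipeline such a study needs, for biostatisticians and
anesthesia researchers:

* **Hypotension metrics** from fixed-interval MAP series. The primary
  endpoint is the time-weighted average (TWA) of hypotension below a
  threshold θ,

  `TWA(θ) = Σ_i max(0, θ − MAP_i) · Δt / (N · Δt)` (mmHg),

  i.e. the deficit area below θ divided by total monitoring time, plus
  episode counts (run-length segmentation with minimum-duration and
  gap-merging rules), cumulative hypotension duration, alarm counts (runs
  of a 0–100 index at or above 85) and prevented-event arithmetic
  `max(0, alarms − events)`.
* **Propensity-score matching**: maximum-likelihood logistic propensity
  model (with explicit rank-deficiency and separation diagnostics), greedy
  1:1 nearest-neighbor matching without replacement within a caliper
  expressed in SD units of the logit score (default 0.1), and
  standardized-mean-difference (SMD) balance diagnostics before and after
  matching; for a binary covariate
  `SMD = (p_t − p_c) / sqrt((p_t(1−p_t) + p_c(1−p_c))/2)`.
* **Comparison tables**: Shapiro–Wilk-gated t / Mann–Whitney tests for
  continuous variables, Fisher exact tests for categoricals, median (IQR)
  or mean (SD) summaries, and SMD columns — the machine-readable analogue
  of a clinical baseline/endpoint table.
* **AKI classification** from postoperative creatinine: a rise of more
  than 0.3 mg/dL within 48 h, or at least 1.5-fold baseline within 7 days.
* **A synthetic cohort generator** reproducing the confounding and
  treatment-effect structure such registries exhibit (Poisson hypotensive
  episodes, alarm channel with a 5-minute lead, episode aversion in the
  treated arm, burden-dependent AKI risk), so the entire pipeline is
  testable without patient data.

## Worked example

```r
library(twamatch)

cfg <- sim_config(n_patients = 800, seed = 1)   # confounded cohort
sim <- generate_cohort(cfg)

covs    <- sim$cohort[, matching_covariates()]
treated <- sim$cohort$group == "HPI"
model   <- fit_propensity(covs, treated, ids = sim$cohort$patient_id)
res     <- match_caliper(model, caliper_sd = 0.1, covariates = covs)
res
#> <match_result: 231 pairs, caliper 0.1 (logit_sd, width 0.1358), 181 treated unmatched>
#>   max |SMD| before 0.728, after 0.112

ep <- summarize_cohort(sim$traces)
rownames(ep) <- ep$patient_id
twa_c <- ep[res$pairs$control_id, "twa_65"]
twa_t <- ep[res$pairs$treated_id, "twa_65"]
median(twa_c); median(twa_t); rank_sum_test(twa_c, twa_t)
#> matched median TWA(65): non-HPI 0.151 vs HPI 0.014 mmHg, rank-sum p = 3.3e-15
```

Reading: before matching the cohort is heavily imbalanced (max |SMD|
0.73, driven by emergency surgery and epidural use); after caliper-0.1
matching every covariate satisfies the |SMD| < 0.2 balance criterion, and
on the matched pairs the index-monitored arm carries an order of magnitude
less hypotension burden — the treatment effect built into the generator,
recovered despite assignment confounding.

The same pipeline runs in one call (`run_all(cfg, out_dir = "out")`),
which writes the cohort, traces, endpoint, pair, balance and comparison
tables plus a JSON run manifest, or from the shell:

```sh
Rscript inst/cli/twamatch.R run-all --seed 1 --out-dir out/
Rscript inst/cli/twamatch.R simulate --config cfg.yaml --seed 1 --out-dir out/
Rscript inst/cli/twamatch.R metrics --traces out/traces.csv --out out/endpoints.csv
Rscript inst/cli/twamatch.R match --cohort out/cohort.csv --caliper 0.1 --out-dir out/
Rscript inst/cli/twamatch.R compare --cohort out/cohort.csv --pairs out/pairs.csv --out out/comparison.csv
```

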