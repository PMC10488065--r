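test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_patients = 3), "at least 4")
  expect_error(sim_config(sample_interval_s = 0), "positive")
  expect_error(sim_config(treatment_effect_multiplier = 0), "\\(0, 1\\]")
  expect_error(sim_config(treatment_effect_multiplier = 1.2), "\\(0, 1\\]")
  expect_error(sim_config(alarm_aversion_prob = 1.5), "\\[0, 1\\]")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("config round-trips through YAML", {
  cfg <- quick_config(n = 60, seed = 9, episode_rate_per_hour = 1.7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("n_patients: 50\nbogus_key: 1", path)
  expect_error(read_sim_config(path), "unknown configuration keys")
})

test_that("generate_map_trace realizes the stated signal model", {
  # no episodes, no noise: flat baseline
  tr <- generate_map_trace(10, 80, interval_s = 30, noise_sd = 0)
  expect_true(all(tr$map_mmHg == 80))
  expect_equal(length(tr$t), 20)

  # one episode reaches exactly baseline - depth on its plateau
  eps <- data.frame(start_s = 300, duration_s = 120, depth_mmHg = 25)
  tr1 <- generate_map_trace(20, 80, eps, interval_s = 30, noise_sd = 0)
  expect_equal(min(tr1$map_mmHg), 55)
  inside <- tr1$t >= 300 & tr1$t <= 420
  expect_equal(min(tr1$map_mmHg[!inside]), 80)

  # overlapping episodes: deepest deficit wins per sample
  eps2 <- data.frame(start_s = c(300, 360), duration_s = c(300, 300),
                     depth_mmHg = c(10, 20))
  tr2 <- generate_map_trace(20, 80, eps2, interval_s = 30, noise_sd = 0)
  overlap <- tr2$t >= 420 & tr2$t <= 600   # both plateaus active
  expect_true(all(tr2$map_mmHg[overlap] == 60))

  expect_error(generate_map_trace(10, 80,
    data.frame(start_s = 100, duration_s = 60, depth_mmHg = -2)),
    "positive")
  expect_error(generate_map_trace(10, 80,
    data.frame(start_s = 1e5, duration_s = 60, depth_mmHg = 5)),
    "within the case")
})

test_that("the generator is bit-reproducible for a fixed configuration", {
  cfg <- quick_config(n = 40, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$traces, b$traces)
  c2 <- generate_cohort(quick_config(n = 40, seed = 124))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("traces are uniformly spaced and span the case duration", {
  sim <- generate_cohort(quick_config(n = 30, seed = 2))
  for (tr in sim$traces) {
    dt <- diff(tr$t)
    expect_true(all(abs(dt - 30) < 1e-9))
    i <- match(tr$patient_id, sim$cohort$patient_id)
    expect_equal(length(tr$t) * 30 / 60, sim$cohort$duration_min[i],
                 tolerance = 0.01)
    expect_true(all(tr$map_mmHg >= 20 & tr$map_mmHg <= 200))
  }
})

test_that("patient records respect the inclusion invariants", {
  sim <- generate_cohort(quick_config(n = 200, seed = 4))
  co <- sim$cohort
  expect_true(all(co$duration_min > 30))
  expect_true(all(co$asa_class %in% 2:4))
  expect_true(all(co$preop_creatinine > 0))
  expect_true(all(co$group %in% c("HPI", "non-HPI")))
  expect_setequal(names(sim$traces), co$patient_id)
  # index channel present exactly in the treated arm
  has_idx <- vapply(sim$traces, function(t) !is.null(t$hpi_index),
                    logical(1))
  expect_equal(unname(has_idx[co$patient_id]), co$group == "HPI")
})

test_that("zero assignment coefficients give a near-even split", {
  cfg <- sim_config(
    n_patients = 1000, seed = 31,
    assignment_coefficients = list(intercept = 0, emergency = 0,
                                   epidural = 0, duration_min = 0,
                                   asa_class = 0))
  sim <- generate_cohort(cfg)
  p_hat <- mean(sim$cohort$group == "HPI")
  # binomial 99.9% band around 0.5 at n = 1000
  expect_lt(abs(p_hat - 0.5), 3.3 * sqrt(0.25 / 1000))
})

test_that("extreme assignment raises the degenerate-cohort error", {
  cfg <- quick_config(n = 30, seed = 5)
  cfg$assignment_coefficients$intercept <- 30
  expect_error(generate_cohort(cfg), "degenerate cohort")
})

test_that("default confounding pushes emergency and epidural imbalance
           past the 0.2 balance criterion", {
  sim <- generate_cohort(sim_config(n_patients = 800, seed = 6))
  bal <- balance_table(sim$cohort[, matching_covariates()],
                       sim$cohort$group == "HPI")
  smd_of <- function(nm) bal$abs_smd[bal$covariate == nm & bal$level == ""]
  expect_gt(smd_of("emergency"), 0.2)
  expect_gt(smd_of("epidural"), 0.2)
  expect_gt(smd_of("duration_min"), 0.2)
})

test_that("treated hypotension burden is non-increasing in the aversion
           probability", {
  means <- vapply(c(0, 0.5, 1), function(av) {
    sim <- generate_cohort(sim_config(
      n_patients = 500, seed = 77, alarm_aversion_prob = av,
      treatment_effect_multiplier = 1))
    ep <- summarize_cohort(sim$traces)
    mean(ep$twa_65[sim$cohort$group == "HPI"])
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_gt(means[1], means[3])   # effect is material, not a tie
})

test_that("with the effect switched off the arms share the TWA law", {
  cfg <- sim_config(
    n_patients = 500, seed = 8,
    treatment_effect_multiplier = 1, alarm_aversion_prob = 0,
    assignment_coefficients = list(intercept = 0, emergency = 0,
                                   epidural = 0, duration_min = 0,
                                   asa_class = 0))
  sim <- generate_cohort(cfg)
  ep <- summarize_cohort(sim$traces)
  p <- rank_sum_test(ep$twa_65[sim$cohort$group == "HPI"],
                     ep$twa_65[sim$cohort$group == "non-HPI"])
  expect_gt(p, 0.001)
})

test_that("alarm/event bookkeeping reproduces the prevented-events
           calibration (about 8 alarms, 2 realized events)", {
  # rate tuned so a mean-duration case accrues ~8 incipient episodes,
  # three quarters of which are averted
  cfg <- sim_config(
    n_patients = 500, seed = 99,
    episode_rate_per_hour = 2.12, treatment_effect_multiplier = 1,
    alarm_aversion_prob = 0.75, episode_depth_mean = 22,
    assignment_coefficients = list(intercept = 0))
  sim <- generate_cohort(cfg)
  ep <- summarize_cohort(sim$traces)
  hpi <- sim$cohort$group == "HPI"
  prevented <- prevented_events(ep$n_alarms_ge85[hpi],
                                ep$n_events_65[hpi])
  expect_lt(abs(mean(prevented) - 6), 1.0)
})

test_that("creatinine generator hits its base rate and responds to
           hypotension burden", {
  cfg <- quick_config(aki_twa_slope = 0, aki_base_prob = 0.08)
  rec <- list(preop_creatinine = 1.0)
  set.seed(10)
  hits <- vapply(1:1000, function(i) {
    attr(generate_creatinine_series(rec, 0.5, cfg), "aki_drawn")
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.08), 3.3 * sqrt(0.08 * 0.92 / 1000))

  cfg2 <- quick_config(aki_twa_slope = 1.5, aki_base_prob = 0.08)
  set.seed(11)
  lo <- mean(vapply(1:2000, function(i)
    attr(generate_creatinine_series(rec, 0, cfg2), "aki_drawn"),
    logical(1)))
  hi <- mean(vapply(1:2000, function(i)
    attr(generate_creatinine_series(rec, 1.0, cfg2), "aki_drawn"),
    logical(1)))
  expect_gt(hi, lo)
})

test_that("emitted creatinine series agree with the AKI classifier by
           construction", {
  cfg <- quick_config(aki_base_prob = 0.5, aki_twa_slope = 2)
  set.seed(12)
  for (k in 1:100) {
    b <- runif(1, 0.5, 1.6)
    ser <- generate_creatinine_series(list(preop_creatinine = b),
                                      runif(1, 0, 0.8), cfg)
    expect_equal(classify_aki(b, ser)$aki, attr(ser, "aki_drawn"))
  }
})

test_that("cohort and trace tables round-trip through CSV", {
  sim <- generate_cohort(quick_config(n = 20, seed = 13))
  cpath <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, cpath)
  write_traces_csv(sim$traces, tpath)
  co <- read_cohort_csv(cpath)
  expect_equal(co$patient_id, sim$cohort$patient_id)
  expect_equal(co$duration_min, sim$cohort$duration_min)
  expect_equal(co$surgical_approach, sim$cohort$surgical_approach)
  trs <- read_traces_csv(tpath)
  expect_equal(names(trs), names(sim$traces))
  one <- sim$cohort$patient_id[sim$cohort$group == "HPI"][1]
  expect_equal(trs[[one]]$map_mmHg, sim$traces[[one]]$map_mmHg,
               tolerance = 1e-9)
  expect_false(is.null(trs[[one]]$hpi_index))
  ctrl <- sim$cohort$patient_id[sim$cohort$group == "non-HPI"][1]
  expect_null(trs[[ctrl]]$hpi_index)
})
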