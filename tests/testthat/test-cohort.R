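# Synthetic cohort generator: determinism, sampled parameter ranges, the
# titration policy, the measurement model and event injection.

test_that("the same seed reproduces the identical patient and records", {
  p1 <- synthesize_records(sample_patient(13), noise_cv = 0.03,
                           dmu = 0.5, dmu_ery = 2)
  p2 <- synthesize_records(sample_patient(13), noise_cv = 0.03,
                           dmu = 0.5, dmu_ery = 2)
  expect_identical(p1$true_params, p2$true_params)
  expect_identical(p1$records, p2$records)
  p3 <- sample_patient(14)
  expect_false(identical(p1$true_params, p3$true_params))
})

test_that("sampled lifespans stay in the published range with the right mean", {
  draws <- vapply(1:400, function(i) sample_patient(i)$true_params$T_RBC,
                  numeric(1))
  expect_true(all(draws >= 33 & draws <= 137))
  # truncated Normal(73, 20) on [33, 137] has mean ~74; Monte-Carlo check
  expect_equal(mean(draws), 74.1, tolerance = 0.03)
  halves <- vapply(1:400, function(i) sample_patient(i)$true_params$t_half,
                   numeric(1))
  expect_true(all(halves >= 3.8 & halves <= 13.6))
  endo <- vapply(1:400, function(i) sample_patient(i)$true_params$E_endo,
                 numeric(1))
  expect_true(all(endo >= 1))
})

test_that("persistently low hemoglobin escalates the dose to its cap", {
  pol <- dosing_config()
  doses <- numeric(40)
  for (i in seq_len(40)) {
    pol$day <- i * 7
    step <- dosing_policy(9.0, 80, pol)
    doses[i] <- step$dose
    pol <- step$config
  }
  expect_true(all(diff(doses) >= 0))
  expect_equal(doses[40], 100 * 80)   # max_per_kg * weight
})

test_that("high hemoglobin steps the dose down to nothing", {
  pol <- dosing_config()
  doses <- numeric(30)
  for (i in seq_len(30)) {
    pol$day <- i * 7
    step <- dosing_policy(12.4, 80, pol)
    doses[i] <- step$dose
    pol <- step$config
  }
  expect_true(all(diff(doses) <= 0))
  expect_equal(doses[30], 0)
  # above the hold threshold no dose is given at all
  expect_equal(dosing_policy(13.2, 80, dosing_config())$dose, 0)
})

test_that("the measurement model reproduces truth without noise and drops sessions", {
  set.seed(1)
  truth <- runif(65, 9, 13)
  m0 <- measure_sessions(truth, noise_cv = 0, missing_prob = 0)
  expect_equal(m0$post_hgb, truth)
  expect_true(all(m0$pre_hgb < m0$post_hgb))
  expect_true(all(m0$post_hgb / m0$pre_hgb >= 1.02 &
                    m0$post_hgb / m0$pre_hgb <= 1.12))
  # missingness: Binomial(650, 0.2) observed count within 5 sd of the mean
  m1 <- measure_sessions(rep(truth, 10), noise_cv = 0, missing_prob = 0.2)
  expect_equal(sum(m1$missing), 130, tolerance = 0.4)
  # noise: sample CV of record/truth near the nominal 3%
  m2 <- measure_sessions(rep(11, 1e4), noise_cv = 0.03, missing_prob = 0)
  expect_equal(stats::sd(m2$post_hgb / 11), 0.03, tolerance = 0.05)
})

test_that("generated adaptation windows usually satisfy the eligibility filter", {
  ok <- vapply(c(31, 62, 205, 407, 509), function(s) {
    pat <- cached_patient(s, noise_cv = 0.03)
    filter_eligible(pat$records)$eligible
  }, logical(1))
  expect_gte(sum(ok), 4)
  # measured sessions in the adaptation window on the 53 +- 7 scale
  n_meas <- vapply(c(31, 62, 205, 407, 509), function(s) {
    pat <- cached_patient(s, noise_cv = 0.03)
    mf <- split_adaptation_prediction(pat$records)$adaptation
    sum(!is.na(mf$post_hgb))
  }, numeric(1))
  expect_true(all(n_meas >= 40 & n_meas <= 65))
})

test_that("injecting no events leaves the patient untouched", {
  pat <- cached_patient(31, noise_cv = 0)
  expect_identical(inject_events(pat, NULL), pat)
})

test_that("a bleed episode dips hemoglobin and the transfusion restores cells", {
  pat <- sample_patient(31)
  episode <- list(start_day = 85, duration_days = 5, daily_volume_ml = 150,
               transfusion_units = 2)
  pat_ev <- inject_events(pat, episode)
  expect_gt(length(pat_ev$events), 1)
  kinds <- vapply(pat_ev$events, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "transfusion"), 1)
  # bleed volumes aggregate to the full episode loss
  vols <- vapply(pat_ev$events[kinds == "bleed"], `[[`, numeric(1),
                 "volume_ml")
  expect_equal(sum(vols), 150 * 5, tolerance = 1e-10)

  pat0 <- synthesize_records(pat, noise_cv = 0, missing_prob = 0,
                             dmu = 0.5, dmu_ery = 2)
  pat1 <- synthesize_records(inject_events(pat, episode), noise_cv = 0,
                             missing_prob = 0, dmu = 0.5, dmu_ery = 2)
  t_sess <- pat$schedule$end_day - pat$schedule$end_day[1]
  during <- which(t_sess >= 85 & t_sess <= 95)
  before <- which(t_sess < 85)
  # hemoglobin drops below the no-event trajectory during the episode
  expect_lt(min(pat1$truth[during] - pat0$truth[during]), -0.5)
  expect_equal(pat1$truth[before], pat0$truth[before], tolerance = 1e-8)
  # partial recovery after the transfusion
  tr_time <- pat_ev$events[[length(pat_ev$events)]]$time
  after_tr <- which(t_sess > tr_time)[1]
  expect_gt(pat1$truth[after_tr], min(pat1$truth[during]))
})

test_that("event injection regenerates records deterministically", {
  episode <- list(start_day = 60, duration_days = 3, daily_volume_ml = 200,
               transfusion_units = 1)
  a <- inject_events(synthesize_records(sample_patient(17), noise_cv = 0.02,
                                        dmu = 0.5, dmu_ery = 2), episode)
  b <- inject_events(synthesize_records(sample_patient(17), noise_cv = 0.02,
                                        dmu = 0.5, dmu_ery = 2), episode)
  expect_identical(a$records, b$records)
  expect_true(any(a$records$event_kind == "transfusion"))
  expect_true(any(a$records$event_kind == "bleed"))
})
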