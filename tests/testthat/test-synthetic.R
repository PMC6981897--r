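test_that("the default cohort is 20 + 20, stratified with cell counts in range", {
  subj <- generate_subjects(seed = 11)
  expect_equal(nrow(subj), 40L)
  expect_equal(sum(subj$sex == "M"), 20L)
  expect_equal(sum(subj$sex == "F"), 20L)
  for (s in c(3L, 7L, 19L)) {
    counts <- table(generate_subjects(seed = s)[, c("sex", "decade")])
    expect_true(all(counts >= 4L & counts <= 6L))
  }
  expect_true(all(subj$age >= 20 & subj$age < 60))
  expect_equal(subj$bmi, subj$weight / (subj$height / 100)^2)
  expect_equal(subj$predicted_hrmax, 208 - 0.7 * subj$age)
  expect_true(all(subj$resting_hr < subj$predicted_hrmax))
  expect_error(generate_subjects(n_per_cell = c(0, 30), seed = 1), "range")
  expect_error(generate_subjects(seed = 1, n_per_sex = 100), "split")
})

test_that("cohort generation is a pure function of the seed", {
  expect_identical(generate_subjects(seed = 5), generate_subjects(seed = 5))
  subj <- generate_subjects(seed = 5)
  expect_identical(
    generate_observations(subj, missing_pattern = "table2", seed = 6),
    generate_observations(subj, missing_pattern = "table2", seed = 6))
  expect_identical(generate_rr_series(80, 60, artifact_rate = 0.05, seed = 7),
                   generate_rr_series(80, 60, artifact_rate = 0.05, seed = 7))
})

test_that("cohort anthropometrics are calibrated to the configured stratum means", {
  means <- vapply(1:200, function(s) {
    subj <- generate_subjects(seed = 1000 + s)
    mean(subj$height[subj$sex == "M"])
  }, numeric(1))
  # configured male mixture: mean 171.2-ish, SD about 5.5; 200 x 20 draws
  strata <- cohort_strata()
  male <- strata[strata$sex == "M", ]
  target <- sum(male$n * male$height_mean) / sum(male$n)
  sd_mix <- sqrt(sum(male$n * (male$height_sd^2 +
                                 (male$height_mean - target)^2)) / sum(male$n))
  se <- sd_mix / sqrt(200 * 20)
  expect_lt(abs(mean(means) - target), 2 * se + 0.05)
})

test_that("observations follow the generating model and the published missing pattern", {
  subj <- generate_subjects(seed = 21)
  truth0 <- true_model_spec(residual_sd = 0)
  obs <- generate_observations(subj, truth = truth0, seed = 22)
  expect_equal(nrow(obs), 40L * 20L)
  fr <- model_frame(obs, subj)
  lp <- truth0$intercept + truth0$coef_pct_hrr * fr$pct_hrr +
    truth0$coef_resting_hr * fr$resting_hr + truth0$coef_height * fr$height
  expect_equal(fr$mets, lp, tolerance = 1e-12)
  # synthetic heart rates are internally consistent with the %HRR definition
  hrmax <- subj$predicted_hrmax[match(obs$subject_id, subj$subject_id)]
  rest <- subj$resting_hr[match(obs$subject_id, subj$subject_id)]
  expect_equal(percent_hrr(obs$mean_hr, rest, hrmax), obs$pct_hrr,
               tolerance = 1e-9)

  obs2 <- generate_observations(subj, missing_pattern = "table2", seed = 23)
  expect_equal(nrow(obs2), 673L)
  expect_true(all(obs2$mets > 0))  # METs are a ratio of positive EEs
  tab <- table(obs2$activity)
  cat <- activity_catalog()
  expect_equal(as.integer(tab[cat$activity]), cat$n_observed)
  expect_error(generate_observations(subj[0, ], seed = 1), "empty")
})

test_that("per-activity %HRR draws are calibrated to the catalog", {
  subj <- generate_subjects(seed = 31)
  pct <- unlist(lapply(1:30, function(s) {
    obs <- generate_observations(subj, missing_pattern = "table2",
                                 seed = 3000 + s)
    obs$pct_hrr[obs$activity == "jogging (130 m/min)"]
  }))
  se <- 12.6 / sqrt(length(pct))
  expect_lt(abs(mean(pct) - 73.4), 3 * se)
  expect_true(all(pct >= -5))
})

test_that("the generator's population R-squared matches the published fit and is calibratable", {
  # default truth (published three-predictor equation at its SEE)
  expect_lt(abs(expected_r2()$r2 - 0.890), 0.02)
  # calibrated mode: analytic R2 of the rescaled generator equals the target
  subj <- generate_subjects(seed = 41)
  obs <- generate_observations(subj, missing_pattern = "table2", seed = 42,
                               calibrate_r2 = 0.80)
  sp <- candidate_spec("pct_hrr", c("resting_hr", "height"), "A")
  fit <- fit_ols(obs, sp, subj)
  expect_lt(abs(fit$r2 - 0.80), 0.04)
})

test_that("R-R series are constant without jitter and span the requested duration", {
  rr <- generate_rr_series(60, 10, jitter = 0, seed = 1)
  expect_true(all(rr$rr_seconds == 1.0))
  expect_gte(max(rr$t_seconds), 10)
  rr2 <- generate_rr_series(120, 30, jitter = 0, seed = 1)
  expect_true(all(abs(rr2$rr_seconds - 0.5) < 1e-12))
  expect_error(generate_rr_series(10, 60, seed = 1), "target_hr")
  expect_error(generate_rr_series(60, -5, seed = 1), "duration")
  expect_error(generate_rr_series(60, 60, artifact_rate = 0.5, seed = 1),
               "artifact_rate")
})

test_that("round-trip through preprocessing recovers the target heart rate", {
  err <- vapply(1:50, function(s) {
    target <- c(60, 80, 110, 140)[(s %% 4) + 1]
    rr <- generate_rr_series(target, 180, jitter = 0.05, seed = 7000 + s)
    ep <- remove_epoch_outliers(rr_to_epoch_hr(rr), k_sd = 3)
    activity_mean_hr(ep) - target
  }, numeric(1))
  expect_lt(max(abs(err)), 1)
})

test_that("inserted artifacts are caught by the SD screen in nearly all runs", {
  flagged <- vapply(1:50, function(s) {
    rr <- generate_rr_series(80, 120, jitter = 0.02, artifact_rate = 0.05,
                             seed = 8000 + s)
    ep <- remove_epoch_outliers(rr_to_epoch_hr(rr), k_sd = 3)
    ep$n_removed >= 1L
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})

test_that("tables round-trip through the CSV interfaces", {
  subj <- generate_subjects(seed = 51)
  obs <- generate_observations(subj, missing_pattern = "table2", seed = 52)
  rr <- generate_rr_series(70, 20, seed = 53)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "cohort.csv")
  p2 <- file.path(td, "obs.csv")
  p3 <- file.path(td, "rr.csv")
  write_cohort_csv(subj, p1)
  write_observations_csv(obs, p2)
  write_rr_csv(rr, p3)
  expect_equal(as.data.frame(read_cohort_csv(p1)), as.data.frame(subj),
               tolerance = 1e-12)
  expect_equal(as.data.frame(read_observations_csv(p2)), as.data.frame(obs),
               tolerance = 1e-12)
  expect_equal(read_rr_csv(p3)$rr_seconds, rr$rr_seconds, tolerance = 1e-12)
})
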