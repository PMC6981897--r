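# Independent oracles and tiny fixture builders used across the suite.

# Normal-equations OLS, independent of the package's lm-based path.
oracle_ols <- function(x, y) {
  drop(solve(t(x) %*% x, t(x) %*% y))
}

# Brute-force epoch HR: loop epochs, loop beats, accumulate overlap weights.
oracle_epoch_hr <- function(series, epoch_length) {
  rr <- series$rr_seconds
  tt <- series$t_seconds
  beat_start <- tt - rr
  t0 <- min(beat_start)
  beat_start <- beat_start - t0
  beat_end <- tt - t0
  n_epochs <- ceiling(max(beat_end) / epoch_length - 1e-9)
  hr <- rep(NA_real_, n_epochs)
  for (j in seq_len(n_epochs)) {
    lo <- (j - 1) * epoch_length
    hi <- j * epoch_length
    wsum <- 0
    wrr <- 0
    for (i in seq_along(rr)) {
      w <- min(beat_end[i], hi) - max(beat_start[i], lo)
      if (w > 0) {
        wsum <- wsum + w
        wrr <- wrr + w * rr[i]
      }
    }
    if (wsum > 1e-9) hr[j] <- 60 / (wrr / wsum)
  }
  hr
}

# Brute-force per-minute averaging of an epoch HR vector.
oracle_minute_mean <- function(hr, epoch_length, min_trailing_s = 15) {
  per_min <- round(60 / epoch_length)
  idx <- (seq_along(hr) - 1) %/% per_min + 1
  last <- max(idx)
  if (last > 1 && sum(idx == last) * epoch_length < min_trailing_s) {
    hr <- hr[idx < last]
    idx <- idx[idx < last]
  }
  means <- c()
  for (m in unique(idx)) {
    v <- hr[idx == m]
    if (any(!is.na(v))) means <- c(means, mean(v, na.rm = TRUE))
  }
  mean(means)
}

# Wrap a bare HR vector as an epoch series object.
make_epochs <- function(hr, epoch_length = 0.4) {
  structure(list(epoch_length = epoch_length, hr = hr, n_removed = 0L),
            class = "hrmets_epochs")
}

# Minimal cohort + observation tables carrying arbitrary predictor values;
# one observation per subject unless mets/pct_hrr are longer.
make_tiny_data <- function(pct_hrr, mets, resting_hr = NULL, height = NULL,
                           sex_code = NULL, age = NULL, weight = NULL) {
  n <- length(pct_hrr)
  default <- function(v, fallback) if (is.null(v)) fallback else v
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = "M",
    sex_code = default(sex_code, rep(1, n)),
    decade = 20L,
    age = default(age, rep(30, n)),
    height = default(height, rep(170, n)),
    weight = default(weight, rep(65, n)),
    bmi = default(weight, rep(65, n)) / (default(height, rep(170, n)) / 100)^2,
    resting_hr = default(resting_hr, rep(65, n)),
    stringsAsFactors = FALSE
  )
  subjects$predicted_hrmax <- 208 - 0.7 * subjects$age
  class(subjects) <- c("hrmets_subjects", "data.frame")
  observations <- data.frame(
    subject_id = subjects$subject_id,
    activity = "bench",
    classification = "exercise",
    mean_hr = subjects$resting_hr +
      pct_hrr / 100 * (subjects$predicted_hrmax - subjects$resting_hr),
    pct_hrr = pct_hrr,
    mets = mets,
    stringsAsFactors = FALSE
  )
  class(observations) <- c("hrmets_observations", "data.frame")
  list(subjects = subjects, observations = observations)
}

# Fabricated fitted-model stub for unit tests of the selection logic.
make_fake_fit <- function(predictors, coefficients, marginal_r, vif, aic) {
  structure(
    list(spec = structure(list(predictors = predictors), class = "hrmets_spec"),
         coefficients = stats::setNames(coefficients, predictors),
         marginal_r = stats::setNames(marginal_r, predictors),
         vif = stats::setNames(vif, predictors),
         aic = aic),
    class = "hrmets_fit"
  )
}
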