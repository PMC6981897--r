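# Stratified synthetic-cohort generator: subjects, subject-activity MET
# observations, and raw R-R interval traces with the statistical structure
# the downstream analysis assumes.

# Truncated-normal draws by rejection; bounds are wide (+/- 3 SD) so the
# acceptance rate is ~0.997 and the loop terminates almost immediately.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  if (lower >= upper) stop("empty truncation interval", call. = FALSE)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generating model for synthetic MET observations
#'
#' Specifies the linear model from which synthetic METs are drawn:
#' METs = intercept + coef_pct_hrr x %HRR + coef_resting_hr x resting HR +
#' coef_height x height + coef_sex x sex + N(0, residual_sd). The default is
#' the published three-predictor equation (%HRR, resting HR, height) with
#' residual SD equal to its published SEE; the sex coefficient defaults to 0
#' because sex is absent from that model.
#'
#' @param intercept Intercept, METs.
#' @param coef_pct_hrr METs per %HRR point.
#' @param coef_resting_hr METs per bpm of resting heart rate.
#' @param coef_height METs per cm.
#' @param coef_sex METs per sex unit (male = 1, female = 0).
#' @param residual_sd Residual standard deviation, METs (>= 0).
#' @return A `"hrmets_truth"` object.
#' @seealso [true_model_from_published()] to build the spec from any
#'   published %HRR-family equation.
#' @export
true_model_spec <- function(intercept = -0.176,
                            coef_pct_hrr = 0.106,
                            coef_resting_hr = -0.017,
                            coef_height = 0.014,
                            coef_sex = 0,
                            residual_sd = 0.623) {
  stopifnot(residual_sd >= 0)
  structure(
    list(intercept = intercept,
         coef_pct_hrr = coef_pct_hrr,
         coef_resting_hr = coef_resting_hr,
         coef_height = coef_height,
         coef_sex = coef_sex,
         residual_sd = residual_sd),
    class = "hrmets_truth"
  )
}

#' Build a generating model from a published equation
#'
#' Maps a %HRR-family published equation onto a [true_model_spec()], setting
#' absent coefficients to zero and the residual SD to the equation's
#' published SEE.
#'
#' @param model_id One of `"HRR"`, `"HRR+RHR"`, `"HRR+RHR+SEX"`,
#'   `"HRR+RHR+HT"`.
#' @return A `"hrmets_truth"` object.
#' @export
true_model_from_published <- function(model_id = "HRR+RHR+HT") {
  eq <- published_models()[[model_id]]
  if (is.null(eq)) stop("unknown model_id: ", model_id, call. = FALSE)
  if ("hr" %in% names(eq$coefficients)) {
    stop("only %HRR-family equations can act as generating truth",
         call. = FALSE)
  }
  cf <- function(nm) if (nm %in% names(eq$coefficients)) eq$coefficients[[nm]] else 0
  true_model_spec(intercept = eq$intercept,
                  coef_pct_hrr = cf("pct_hrr"),
                  coef_resting_hr = cf("resting_hr"),
                  coef_height = cf("height"),
                  coef_sex = cf("sex"),
                  residual_sd = eq$see)
}

# Sample one sex's per-cell counts, each in [lo, hi], constrained to sum to
# n_total (rejection over uniform cell draws).
sample_cell_counts <- function(lo, hi, n_cells, n_total) {
  if (n_total < lo * n_cells || n_total > hi * n_cells) {
    stop(sprintf("total of %d cannot be split into %d cells of [%d, %d]",
                 n_total, n_cells, lo, hi), call. = FALSE)
  }
  for (i in seq_len(100000L)) {
    counts <- sample(lo:hi, n_cells, replace = TRUE)
    if (sum(counts) == n_total) return(counts)
  }
  stop("failed to sample stratum counts", call. = FALSE)
}

#' Generate a stratified synthetic cohort
#'
#' Draws a cohort stratified by sex and 10-year age decade (20s-50s).
#' Per-cell counts are sampled uniformly within `n_per_cell` and, when
#' `n_per_sex` is given (default 20 per sex, matching the study cohort of
#' 40), constrained to sum to it. Within each cell, age, height, weight and
#' resting heart rate are drawn from independent Gaussians parameterized by
#' the cell's configured means/SDs, truncated at +/- 3 SD (ages additionally
#' to their decade); BMI and predicted maximal heart rate are derived.
#'
#' @param n_per_cell Length-2 integer range of subjects per sex-decade cell,
#'   within \[1, 20\].
#' @param n_per_sex Target number of subjects of each sex, or `NULL` to
#'   leave cell counts unconstrained.
#' @param strata Stratum definition table; see [cohort_strata()].
#' @param seed Integer seed; mandatory so cohorts are reproducible.
#' @return A data frame of class `"hrmets_subjects"` with columns
#'   `subject_id`, `sex` (`"M"`/`"F"`), `sex_code` (M = 1, F = 0), `decade`,
#'   `age`, `height` (cm), `weight` (kg), `bmi`, `resting_hr` (bpm),
#'   `predicted_hrmax` (bpm).
#' @examples
#' subj <- generate_subjects(seed = 1)
#' table(subj$sex)
#' @export
generate_subjects <- function(n_per_cell = c(4L, 6L), n_per_sex = 20L,
                              strata = cohort_strata(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_per_cell <- as.integer(round(n_per_cell))
  if (length(n_per_cell) != 2L || any(n_per_cell < 1L) ||
      any(n_per_cell > 20L) || n_per_cell[1] > n_per_cell[2]) {
    stop("`n_per_cell` must be an increasing range within [1, 20]",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- list()
  for (sx in unique(strata$sex)) {
    cells <- strata[strata$sex == sx, , drop = FALSE]
    if (is.null(n_per_sex)) {
      counts <- sample(n_per_cell[1]:n_per_cell[2], nrow(cells),
                       replace = TRUE)
    } else {
      counts <- sample_cell_counts(n_per_cell[1], n_per_cell[2],
                                   nrow(cells), as.integer(n_per_sex))
    }
    for (j in seq_len(nrow(cells))) {
      cl <- cells[j, ]
      m <- counts[j]
      if (m == 0L) next
      age <- rtruncnorm(m, cl$age_mean, cl$age_sd,
                        lower = max(cl$decade, cl$age_mean - 3 * cl$age_sd),
                        upper = min(cl$decade + 9.99,
                                    cl$age_mean + 3 * cl$age_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx,
        sex_code = as.numeric(sx == "M"),
        decade = cl$decade,
        age = age,
        height = rtruncnorm(m, cl$height_mean, cl$height_sd,
                            cl$height_mean - 3 * cl$height_sd,
                            cl$height_mean + 3 * cl$height_sd),
        weight = rtruncnorm(m, cl$weight_mean, cl$weight_sd,
                            cl$weight_mean - 3 * cl$weight_sd,
                            cl$weight_mean + 3 * cl$weight_sd),
        resting_hr = rtruncnorm(m, cl$resting_hr_mean, cl$resting_hr_sd,
                                cl$resting_hr_mean - 3 * cl$resting_hr_sd,
                                cl$resting_hr_mean + 3 * cl$resting_hr_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  subj <- do.call(rbind, rows)
  subj$subject_id <- sprintf("S%02d", seq_len(nrow(subj)))
  subj$bmi <- subj$weight / (subj$height / 100)^2
  subj$predicted_hrmax <- predict_hrmax(subj$age)
  stopifnot(all(subj$resting_hr < subj$predicted_hrmax))
  subj <- subj[, c("subject_id", "sex", "sex_code", "decade", "age",
                   "height", "weight", "bmi", "resting_hr",
                   "predicted_hrmax")]
  class(subj) <- c("hrmets_subjects", "data.frame")
  subj
}

# Mixture mean/covariance of (resting_hr, height, sex_code) over the strata
# cells (within-cell independence; between-cell spread and the sex-height
# association arise from the mixing). Used for analytic R2 calibration.
predictor_moments <- function(strata = cohort_strata()) {
  w <- strata$n / sum(strata$n)
  mu_cell <- cbind(resting_hr = strata$resting_hr_mean,
                   height = strata$height_mean,
                   sex = as.numeric(strata$sex == "M"))
  mu <- colSums(w * mu_cell)
  sigma <- matrix(0, 3, 3, dimnames = list(colnames(mu_cell),
                                           colnames(mu_cell)))
  for (j in seq_along(w)) {
    d <- mu_cell[j, ] - mu
    within <- diag(c(strata$resting_hr_sd[j]^2, strata$height_sd[j]^2, 0))
    sigma <- sigma + w[j] * (within + tcrossprod(d))
  }
  list(mean = mu, cov = sigma)
}

# Pooled mean/variance of %HRR over the activity catalog, weighted by
# per-activity retention counts (mixture of the per-activity Gaussians).
pct_hrr_moments <- function(catalog = activity_catalog(),
                            weights = catalog$n_observed) {
  w <- weights / sum(weights)
  mu <- sum(w * catalog$pct_hrr_mean)
  v <- sum(w * (catalog$pct_hrr_sd^2 + (catalog$pct_hrr_mean - mu)^2))
  c(mean = mu, var = v)
}

#' Expected population R-squared of the synthetic generator
#'
#' Computes analytically, from the configured predictor distributions, the
#' population R-squared of a generating model: R2 = var(lp) / (var(lp) +
#' residual_sd^2), where the linear-predictor variance combines the pooled
#' %HRR mixture variance (activities weighted by their retention counts,
#' independent of the anthropometrics) with the mixture covariance of
#' resting HR, height and sex over the cohort strata.
#'
#' @param truth A [true_model_spec()].
#' @param catalog Activity catalog; see [activity_catalog()].
#' @param strata Stratum table; see [cohort_strata()].
#' @return A list with `r2`, `var_lp` and `var_residual`.
#' @export
expected_r2 <- function(truth = true_model_spec(),
                        catalog = activity_catalog(),
                        strata = cohort_strata()) {
  stopifnot(inherits(truth, "hrmets_truth"))
  pm <- predictor_moments(strata)
  b <- c(truth$coef_resting_hr, truth$coef_height, truth$coef_sex)
  var_lp <- truth$coef_pct_hrr^2 * pct_hrr_moments(catalog)[["var"]] +
    drop(t(b) %*% pm$cov %*% b)
  list(r2 = var_lp / (var_lp + truth$residual_sd^2),
       var_lp = var_lp,
       var_residual = truth$residual_sd^2)
}

#' Generate subject-activity MET observations
#'
#' For each retained subject-activity pair, draws %HRR from the activity's
#' configured Gaussian (truncated below at -5%), back-computes the activity
#' heart rate from the subject's own resting HR and predicted HRmax (so the
#' synthetic heart rates are internally consistent with the %HRR
#' definition), and sets METs to the generating model's linear predictor
#' plus Gaussian noise at `truth$residual_sd`.
#'
#' Measured METs are strictly positive (a ratio of positive energy
#' expenditures), so by default residuals that would push a light activity
#' to zero or below are redrawn (`positive_mets = TRUE`), a truncation that
#' touches only the lower tail of the lightest activities. Truncation
#' slightly biases the generating model's coefficients out of the data, so
#' calibration-recovery experiments that need the exactly unbiased Gaussian
#' design should set `positive_mets = FALSE` and accept occasional
#' non-physical METs.
#'
#' With `missing_pattern = "table2"` the per-activity retention counts equal
#' the study's published per-activity sample sizes (673 pooled observations
#' for a 40-subject cohort); the subjects dropped for each activity are
#' chosen uniformly at random, as the identity of the real dropouts is
#' unknown. With `"none"` every subject contributes every activity.
#'
#' `calibrate_r2`, when given, rescales the spread of the linear predictor
#' about its analytic mean so the generator's population R-squared (see
#' [expected_r2()]) equals the target; used for fit-statistic recovery
#' experiments where the real predictor covariances are unknown.
#'
#' @param subjects Cohort from [generate_subjects()].
#' @param catalog Activity catalog; see [activity_catalog()].
#' @param truth Generating model; see [true_model_spec()].
#' @param missing_pattern `"none"` or `"table2"`.
#' @param seed Integer seed; mandatory.
#' @param calibrate_r2 Optional target population R-squared in (0, 1).
#' @param positive_mets Redraw residuals that would yield METs <= 0
#'   (default `TRUE`).
#' @param strata Stratum table used only for analytic calibration moments.
#' @return A data frame of class `"hrmets_observations"` with columns
#'   `subject_id`, `activity`, `classification`, `mean_hr` (bpm), `pct_hrr`,
#'   `mets`.
#' @examples
#' subj <- generate_subjects(seed = 1)
#' obs <- generate_observations(subj, missing_pattern = "table2", seed = 2)
#' nrow(obs)  # 673
#' @export
generate_observations <- function(subjects,
                                  catalog = activity_catalog(),
                                  truth = true_model_spec(),
                                  missing_pattern = c("none", "table2"),
                                  seed,
                                  calibrate_r2 = NULL,
                                  positive_mets = TRUE,
                                  strata = cohort_strata()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  missing_pattern <- match.arg(missing_pattern)
  stopifnot(inherits(truth, "hrmets_truth"))
  if (nrow(subjects) == 0L) stop("`subjects` is empty", call. = FALSE)
  if (nrow(catalog) == 0L) stop("`catalog` is empty", call. = FALSE)

  set.seed(as.integer(seed))
  rows <- vector("list", nrow(catalog))
  for (a in seq_len(nrow(catalog))) {
    act <- catalog[a, ]
    keep <- subjects
    if (missing_pattern == "table2" && act$n_observed < nrow(subjects)) {
      keep <- subjects[sort(sample.int(nrow(subjects), act$n_observed)), ]
    }
    m <- nrow(keep)
    pct <- rtruncnorm(m, act$pct_hrr_mean, act$pct_hrr_sd, lower = -5)
    rows[[a]] <- data.frame(
      subject_id = keep$subject_id,
      activity = act$activity,
      classification = act$classification,
      mean_hr = hrr_to_hr(pct, keep$resting_hr, keep$predicted_hrmax),
      pct_hrr = pct,
      lp = truth$intercept +
        truth$coef_pct_hrr * pct +
        truth$coef_resting_hr * keep$resting_hr +
        truth$coef_height * keep$height +
        truth$coef_sex * keep$sex_code,
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, rows)

  if (!is.null(calibrate_r2)) {
    stopifnot(calibrate_r2 > 0, calibrate_r2 < 1)
    base <- expected_r2(truth, catalog, strata)
    pm <- predictor_moments(strata)
    mean_lp <- truth$intercept +
      truth$coef_pct_hrr * pct_hrr_moments(catalog)[["mean"]] +
      sum(c(truth$coef_resting_hr, truth$coef_height, truth$coef_sex) *
            pm$mean)
    s <- truth$residual_sd * sqrt(calibrate_r2 / (1 - calibrate_r2)) /
      sqrt(base$var_lp)
    obs$lp <- mean_lp + s * (obs$lp - mean_lp)
  }

  obs$mets <- obs$lp + stats::rnorm(nrow(obs), 0, truth$residual_sd)
  if (positive_mets) {
    # resample the residual where noise pushed a light activity below zero
    # (a few percent of the lightest activities at most)
    bad <- which(obs$mets <= 0)
    while (length(bad)) {
      obs$mets[bad] <- obs$lp[bad] +
        stats::rnorm(length(bad), 0, truth$residual_sd)
      bad <- bad[obs$mets[bad] <= 0]
    }
  }
  obs$lp <- NULL
  rownames(obs) <- NULL
  class(obs) <- c("hrmets_observations", "data.frame")
  obs
}

#' Simulate an R-R interval recording
#'
#' Emulates a beat-to-beat R-R interval log at a target heart rate:
#' intervals fluctuate multiplicatively around 60/target_hr with relative
#' jitter `jitter`, and detection artifacts are inserted at rate
#' `artifact_rate` as either missed beats (a doubled interval) or spurious
#' detections (an interval shrunk to 35%), each with probability 1/2.
#' Intervals accumulate until the cumulative time spans `duration`.
#'
#' @param target_hr Target mean heart rate, bpm, in (30, 220).
#' @param duration Recording length, s (> 0).
#' @param jitter Relative SD of beat-to-beat fluctuation (default 0.05,
#'   a typical normalized beat-to-beat variability at rest).
#' @param artifact_rate Fraction of beats replaced by artifacts, in
#'   \[0, 0.2\].
#' @param seed Integer seed; mandatory.
#' @param subject_id,activity Optional labels carried as attributes.
#' @return A data frame of class `"hrmets_rr"` with columns `t_seconds`
#'   (cumulative time at each beat) and `rr_seconds`.
#' @examples
#' rr <- generate_rr_series(60, 10, jitter = 0, seed = 1)
#' rr$rr_seconds[1:3]  # all 1.0
#' @export
generate_rr_series <- function(target_hr, duration, jitter = 0.05,
                               artifact_rate = 0, seed,
                               subject_id = NULL, activity = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.numeric(target_hr) || target_hr <= 30 || target_hr >= 220) {
    stop("`target_hr` must lie in (30, 220) bpm", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (artifact_rate < 0 || artifact_rate > 0.2) {
    stop("`artifact_rate` must lie in [0, 0.2]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  base <- 60 / target_hr
  n_guess <- ceiling(duration / base * 1.5) + 10L
  rr <- numeric(0)
  while (sum(rr) < duration) {
    new <- base * pmax(0.2, 1 + stats::rnorm(n_guess, 0, jitter))
    if (artifact_rate > 0) {
      is_art <- stats::runif(n_guess) < artifact_rate
      kind <- stats::runif(n_guess) < 0.5
      new[is_art & kind] <- new[is_art & kind] * 2    # missed beat
      new[is_art & !kind] <- new[is_art & !kind] * 0.35  # spurious beat
    }
    rr <- c(rr, new)
  }
  tt <- cumsum(rr)
  keep <- seq_len(which(tt >= duration)[1])
  out <- data.frame(t_seconds = tt[keep], rr_seconds = rr[keep])
  attr(out, "subject_id") <- subject_id
  attr(out, "activity") <- activity
  attr(out, "target_hr") <- target_hr
  class(out) <- c("hrmets_rr", "data.frame")
  out
}

#' Read and write the pipeline's delimited-text formats
#'
#' Plain CSV (header row, UTF-8, "." decimal): cohort tables, observation
#' tables, and two-column R-R logs (`t_seconds`, `rr_seconds`).
#'
#' @param x Object to write.
#' @param path File path.
#' @return The read data frame (readers) or `path`, invisibly (writers).
#' @name hrmets_io
NULL

#' @rdname hrmets_io
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname hrmets_io
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("hrmets_subjects", "data.frame")
  x
}

#' @rdname hrmets_io
#' @export
write_observations_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname hrmets_io
#' @export
read_observations_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("hrmets_observations", "data.frame")
  x
}

#' @rdname hrmets_io
#' @export
write_rr_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("t_seconds", "rr_seconds")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname hrmets_io
#' @export
read_rr_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t_seconds", "rr_seconds") %in% names(x)))
  class(x) <- c("hrmets_rr", "data.frame")
  x
}
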