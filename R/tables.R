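#' Activity catalog of the motivating study
#'
#' The 20 daily activities used to develop the MET prediction equations, with
#' the per-activity measured METs and percent heart-rate reserve (%HRR)
#' means and standard deviations, the number of subjects with usable data for
#' each activity (the `n_observed` column; these sum to 673 pooled
#' observations over the 40-subject cohort), the minutes of activity and of
#' gas-exchange measurement, and the epoch-outlier screening multiplier
#' (`outlier_k`; 4 SD for radio calisthenics, whose rhythmic whole-body
#' movement produces heavier-tailed heart-rate epochs, 3 SD for all other
#' activities).
#'
#' @return A data frame with one row per activity and columns `activity`,
#'   `classification` (`"exercise"` or `"household"`), `n_observed`,
#'   `minutes_activity`, `minutes_measured`, `mets_mean`, `mets_sd`,
#'   `pct_hrr_mean`, `pct_hrr_sd`, `outlier_k`.
#' @examples
#' cat <- activity_catalog()
#' sum(cat$n_observed)  # 673
#' @export
activity_catalog <- function() {
  df <- data.frame(
    activity = c(
      "radio calisthenics",
      "walking (55 m/min)",
      "walking (70 m/min)",
      "walking (100 m/min)",
      "jogging (130 m/min)",
      "operating a mobile phone",
      "PC work",
      "document arrangement while sitting",
      "stretch exercising",
      "document arrangement while standing",
      "washing dishes",
      "hanging and bringing in clothes",
      "repeated sitting and standing",
      "wiping tables",
      "descending stairs",
      "vacuuming the room",
      "moving load (5 kg bag of rice)",
      "walking with load (5 kg for 55 m/min)",
      "walking with load (3 kg for 70 m/min)",
      "ascending stairs"
    ),
    classification = c(rep("exercise", 5L), rep("household", 15L)),
    n_observed = c(25L, 33L, 29L, 30L, 21L,
                   36L, 38L, 39L, 30L, 40L, 37L, 38L, 38L, 39L, 36L, 35L,
                   37L, 33L, 29L, 30L),
    minutes_activity = c(8, 5, 5, 5, 4,
                         7, 7, 5, 12, 5, 5, 5, 4, 5, 5, 3, 5, 5, 5, 5),
    minutes_measured = c(3, 2, 2, 2, 1,
                         5, 5, 3, 5, 3, 3, 2, 2, 2, 1.5, 2, 2, 2, 2, 1),
    mets_mean = c(3.1, 3.3, 3.7, 5.1, 9.5,
                  1.1, 1.1, 1.5, 2.1, 2.1, 2.1, 2.4, 2.5, 2.6, 2.7, 2.9,
                  3.7, 4.0, 4.2, 7.4),
    mets_sd = c(0.4, 0.5, 0.5, 0.9, 1.5,
                0.1, 0.1, 0.3, 0.3, 0.4, 0.4, 0.4, 0.3, 0.5, 0.4, 0.6,
                0.6, 0.5, 0.6, 0.9),
    pct_hrr_mean = c(21.6, 21.8, 26.0, 36.5, 73.4,
                     1.1, 2.3, 6.5, 8.0, 10.2, 11.7, 14.5, 12.9, 15.0,
                     17.8, 17.7, 25.4, 29.7, 30.1, 54.0),
    pct_hrr_sd = c(5.3, 8.0, 8.0, 10.8, 12.6,
                   3.7, 3.4, 3.4, 4.5, 4.6, 5.5, 5.7, 5.1, 5.8, 6.3, 6.4,
                   8.2, 8.3, 9.5, 7.7),
    stringsAsFactors = FALSE
  )
  df$outlier_k <- ifelse(df$activity == "radio calisthenics", 4, 3)
  df
}

#' Cohort strata of the motivating study
#'
#' Anthropometric and resting heart-rate summaries of the 40-subject cohort,
#' stratified by sex and 10-year age group (20s through 50s). Values are the
#' per-cell means and standard deviations; `n` is the number of participants
#' in each cell after two of the 42 recruits were excluded.
#'
#' @return A data frame with 8 rows (sex x decade) and columns `sex`
#'   (`"M"`/`"F"`), `decade` (20, 30, 40, 50), `n`, `age_mean`, `age_sd`,
#'   `height_mean`, `height_sd` (cm), `weight_mean`, `weight_sd` (kg),
#'   `bmi_mean`, `bmi_sd`, `resting_hr_mean`, `resting_hr_sd` (bpm).
#' @export
cohort_strata <- function() {
  data.frame(
    sex = rep(c("M", "F"), each = 4L),
    decade = rep(c(20L, 30L, 40L, 50L), 2L),
    n = c(6L, 3L, 6L, 5L, 5L, 5L, 5L, 5L),
    age_mean = c(26.2, 37.3, 43.2, 52.2, 23.0, 33.0, 43.0, 52.8),
    age_sd = c(3.1, 2.1, 3.9, 1.8, 2.3, 3.5, 4.2, 1.3),
    height_mean = c(169.0, 171.2, 173.1, 171.5, 157.3, 165.3, 155.9, 158.1),
    height_sd = c(7.2, 3.8, 6.2, 2.3, 4.5, 10.6, 5.7, 2.2),
    weight_mean = c(66.3, 65.1, 73.1, 68.4, 49.1, 62.2, 52.8, 59.4),
    weight_sd = c(10.6, 18.6, 12.1, 13.1, 5.1, 14.1, 17.1, 8.0),
    bmi_mean = c(23.1, 22.1, 24.4, 23.2, 19.8, 22.7, 21.6, 23.8),
    bmi_sd = c(2.0, 5.3, 3.6, 3.9, 1.5, 4.3, 6.4, 3.2),
    resting_hr_mean = c(67.0, 61.4, 72.8, 67.3, 64.0, 70.8, 66.8, 67.6),
    resting_hr_sd = c(5.9, 5.4, 6.1, 5.9, 12.8, 5.8, 13.7, 12.1),
    stringsAsFactors = FALSE
  )
}

#' Published MET prediction equations
#'
#' The six multiple-regression equations of the motivating study, fitted on
#' 673 pooled subject-activity observations (dependent variable METs). Two
#' use absolute heart rate (`HR`, `HR+RHR`) and four use percent heart-rate
#' reserve (`HRR`, `HRR+RHR`, `HRR+RHR+SEX`, `HRR+RHR+HT`). Each entry
#' stores the intercept, the unstandardized coefficients (units: METs per
#' %HRR point, per bpm, per cm, or per sex unit with male = 1 / female = 0),
#' the standardized coefficients, and the published fit statistics (multiple
#' correlation r, R-squared, and SEE, the standard error of the estimate, in
#' METs).
#'
#' Height enters in centimetres; passing metres would silently corrupt
#' predictions by two orders of magnitude.
#'
#' @return A named list of `"hrmets_equation"` objects with elements
#'   `model_id`, `intercept`, `coefficients` (named numeric),
#'   `std_beta` (named numeric), `r`, `r2`, `see`.
#' @seealso [predict_mets()]
#' @examples
#' published_models()[["HRR"]]$intercept  # 1.053
#' @export
published_models <- function() {
  eqs <- list(
    list(model_id = "HR",
         intercept = -4.030,
         coefficients = c(hr = 0.080),
         std_beta = c(hr = 0.852),
         r = 0.852, r2 = 0.725, see = 0.983),
    list(model_id = "HR+RHR",
         intercept = 0.679,
         coefficients = c(hr = 0.095, resting_hr = -0.089),
         std_beta = c(hr = 1.009, resting_hr = -0.415),
         r = 0.934, r2 = 0.873, see = 0.669),
    list(model_id = "HRR",
         intercept = 1.053,
         coefficients = c(pct_hrr = 0.105),
         std_beta = c(pct_hrr = 0.938),
         r = 0.938, r2 = 0.880, see = 0.648),
    list(model_id = "HRR+RHR",
         intercept = 2.123,
         coefficients = c(pct_hrr = 0.105, resting_hr = -0.016),
         std_beta = c(pct_hrr = 0.942, resting_hr = -0.074),
         r = 0.941, r2 = 0.886, see = 0.634),
    list(model_id = "HRR+RHR+SEX",
         intercept = 2.046,
         coefficients = c(pct_hrr = 0.106, resting_hr = -0.016, sex = 0.184),
         std_beta = c(pct_hrr = 0.944, resting_hr = -0.075, sex = 0.049),
         r = 0.942, r2 = 0.888, see = 0.628),
    list(model_id = "HRR+RHR+HT",
         intercept = -0.176,
         coefficients = c(pct_hrr = 0.106, resting_hr = -0.017, height = 0.014),
         std_beta = c(pct_hrr = 0.944, resting_hr = -0.078, height = 0.065),
         r = 0.943, r2 = 0.890, see = 0.623)
  )
  eqs <- lapply(eqs, function(e) structure(e, class = "hrmets_equation"))
  names(eqs) <- vapply(eqs, `[[`, character(1), "model_id")
  eqs
}

#' @export
print.hrmets_equation <- function(x, ...) {
  cat("Published MET equation:", x$model_id, "\n")
  cat("  METs =", format(x$intercept),
      paste(sprintf("%+g x %s", x$coefficients, names(x$coefficients)),
            collapse = " "), "\n")
  cat(sprintf("  r = %.3f, R2 = %.3f, SEE = %.3f METs\n", x$r, x$r2, x$see))
  invisible(x)
}
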