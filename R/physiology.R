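#' Age-predicted maximal heart rate
#'
#' Predicts maximal heart rate from age by the Tanaka equation,
#' HRmax = 208 - 0.7 x age. Direct HRmax measurement is not feasible for
#' sedentary or older participants, so the age-based prediction is used
#' throughout the pipeline.
#'
#' @param age Age in years; must lie in \[18, 80\] (the equation was
#'   validated on adults).
#' @return Predicted maximal heart rate in bpm.
#' @examples
#' predict_hrmax(20)   # 194
#' predict_hrmax(55)   # 169.5
#' @export
predict_hrmax <- function(age) {
  stopifnot(is.numeric(age))
  if (any(!is.finite(age)) || any(age < 18) || any(age > 80)) {
    stop("`age` must be finite and within [18, 80] years", call. = FALSE)
  }
  208 - 0.7 * age
}

#' Percent heart-rate reserve
#'
#' Computes %HRR = (HR - resting HR) / (HRmax - resting HR) x 100. The value
#' is 0 at resting heart rate and 100 at maximal heart rate. It is not
#' clamped: sedentary activities can yield slightly negative values (the
#' study's lightest activity averaged 1.1% with SD 3.7, implying negative
#' individual values were retained), and supramaximal heart rates yield
#' values above 100.
#'
#' @param hr Activity heart rate, bpm (> 0).
#' @param resting_hr Resting heart rate, bpm.
#' @param hrmax Maximal heart rate, bpm; must exceed `resting_hr`.
#' @return %HRR (percentage points).
#' @seealso [hrr_to_hr()] for the inverse transform.
#' @examples
#' percent_hrr(150.39, 67.7, 180.35)  # 73.4
#' @export
percent_hrr <- function(hr, resting_hr, hrmax) {
  stopifnot(is.numeric(hr), is.numeric(resting_hr), is.numeric(hrmax))
  if (any(hrmax <= resting_hr)) {
    stop("`hrmax` must exceed `resting_hr`", call. = FALSE)
  }
  if (any(hr <= 0)) stop("`hr` must be positive", call. = FALSE)
  (hr - resting_hr) / (hrmax - resting_hr) * 100
}

#' Heart rate at a given percent heart-rate reserve
#'
#' Inverse of [percent_hrr()]: HR = resting HR + %HRR/100 x (HRmax -
#' resting HR). Used by the cohort simulator to back-compute internally
#' consistent activity heart rates from sampled %HRR values.
#'
#' @inheritParams percent_hrr
#' @param pct_hrr Percent heart-rate reserve.
#' @return Heart rate in bpm.
#' @export
hrr_to_hr <- function(pct_hrr, resting_hr, hrmax) {
  stopifnot(is.numeric(pct_hrr))
  if (any(hrmax <= resting_hr)) {
    stop("`hrmax` must exceed `resting_hr`", call. = FALSE)
  }
  resting_hr + pct_hrr / 100 * (hrmax - resting_hr)
}

#' Energy expenditure by the abbreviated Weir equation
#'
#' EE (kcal/min) = 3.941 x VO2 + 1.106 x VCO2, with gas volumes in L/min.
#' The abbreviated form neglects protein oxidation (urinary nitrogen), the
#' standard practice for short activity protocols. Inputs are screened on
#' the respiratory exchange ratio VCO2/VO2, which must be physiologically
#' plausible (0.6 to 1.3).
#'
#' @param vo2 Oxygen uptake, L/min (> 0).
#' @param vco2 Carbon-dioxide output, L/min (> 0).
#' @return Energy expenditure in kcal/min.
#' @examples
#' weir_ee(0.250, 0.200)  # 1.206
#' @export
weir_ee <- function(vo2, vco2) {
  stopifnot(is.numeric(vo2), is.numeric(vco2))
  if (any(vo2 <= 0) || any(vco2 <= 0)) {
    stop("gas volumes must be positive", call. = FALSE)
  }
  rer <- vco2 / vo2
  if (any(rer <= 0.6) || any(rer >= 1.3)) {
    stop("respiratory exchange ratio vco2/vo2 outside (0.6, 1.3)",
         call. = FALSE)
  }
  3.941 * vo2 + 1.106 * vco2
}

#' Metabolic equivalents of an activity
#'
#' METs = EE of the activity divided by EE at seated rest; 1 MET is seated
#' rest by definition. Scale-invariant: multiplying both energy expenditures
#' by a constant leaves the MET value unchanged.
#'
#' @param ee_activity Activity energy expenditure, kcal/min (> 0).
#' @param ee_rest_sitting Seated resting energy expenditure, kcal/min (> 0).
#' @return METs (dimensionless).
#' @export
compute_mets <- function(ee_activity, ee_rest_sitting) {
  stopifnot(is.numeric(ee_activity), is.numeric(ee_rest_sitting))
  if (any(ee_rest_sitting <= 0)) {
    stop("`ee_rest_sitting` must be positive", call. = FALSE)
  }
  if (any(ee_activity <= 0)) {
    stop("`ee_activity` must be positive", call. = FALSE)
  }
  ee_activity / ee_rest_sitting
}

#' Energy expenditure from METs
#'
#' Recovers absolute energy expenditure from a MET value and the subject's
#' seated resting energy expenditure: EE = METs x resting EE. Inverse of
#' [compute_mets()].
#'
#' @param mets MET value (> 0).
#' @param ee_rest_sitting Seated resting energy expenditure, kcal/min (> 0).
#' @return Energy expenditure in kcal/min.
#' @export
mets_to_ee <- function(mets, ee_rest_sitting) {
  stopifnot(is.numeric(mets), is.numeric(ee_rest_sitting))
  if (any(mets <= 0) || any(ee_rest_sitting <= 0)) {
    stop("`mets` and `ee_rest_sitting` must be positive", call. = FALSE)
  }
  mets * ee_rest_sitting
}

#' Seated resting energy expenditure from replicate measurements
#'
#' The resting metabolic rate (1 MET) is measured at least twice over
#' seated 7-min intervals and the replicates are checked for stability
#' before averaging. Stability rule: if the relative spread
#' (max - min) / mean across replicates is within `tolerance`, the mean of
#' all replicates is returned. Otherwise, with three or more replicates, the
#' closest pair is used if that pair alone is stable; failing that an
#' instability error (condition class `"hrmets_unstable_rest"`) is signalled
#' so the caller can collect a further replicate.
#'
#' @param replicates A data frame of seated gas-exchange replicates with
#'   columns `vo2` and `vco2` (L/min), or a numeric vector of replicate EE
#'   values in kcal/min.
#' @param tolerance Maximum allowed relative spread (default 0.10).
#' @return Mean EE of the stable replicates, kcal/min.
#' @examples
#' resting_ee(c(1.20, 1.26))  # 1.23
#' @export
resting_ee <- function(replicates, tolerance = 0.10) {
  if (is.data.frame(replicates)) {
    ee <- weir_ee(replicates$vo2, replicates$vco2)
  } else {
    ee <- as.numeric(replicates)
  }
  if (length(ee) < 2L) {
    stop("at least two resting replicates are required", call. = FALSE)
  }
  if (any(ee <= 0)) stop("replicate EE must be positive", call. = FALSE)
  spread <- (max(ee) - min(ee)) / mean(ee)
  if (spread <= tolerance) return(mean(ee))
  if (length(ee) >= 3L) {
    ee_sorted <- sort(ee)
    gaps <- diff(ee_sorted)
    i <- which.min(gaps)
    pair <- ee_sorted[c(i, i + 1L)]
    if ((pair[2] - pair[1]) / mean(pair) <= tolerance) return(mean(pair))
  }
  stop(structure(
    class = c("hrmets_unstable_rest", "error", "condition"),
    list(message = sprintf(
      "resting replicates unstable: relative spread %.3f exceeds tolerance %.3f; supply a further replicate",
      spread, tolerance),
      call = NULL)
  ))
}
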