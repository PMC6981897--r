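#' Predict METs from a published equation
#'
#' Evaluates one of the published multiple-regression equations (see
#' [published_models()]): METs = intercept + sum(coefficient x feature).
#' Features must match the model's predictor set exactly — a missing or
#' extra feature is an error, so unit mistakes and silently ignored inputs
#' cannot slip through. Predictions are not clamped (the source equations
#' apply no floor at 1 MET).
#'
#' Feature names and units: `pct_hrr` (%HRR points), `hr` (bpm),
#' `resting_hr` (bpm), `height` (cm — not metres), `sex` (male = 1,
#' female = 0).
#'
#' @param model_id One of `"HR"`, `"HR+RHR"`, `"HRR"`, `"HRR+RHR"`,
#'   `"HRR+RHR+SEX"`, `"HRR+RHR+HT"`.
#' @param features Named list or named numeric vector supplying exactly the
#'   model's predictors; each element may be a vector (all the same length)
#'   for vectorized prediction.
#' @return Predicted METs.
#' @examples
#' predict_mets("HRR", c(pct_hrr = 73.4))  # 8.760
#' @export
predict_mets <- function(model_id, features) {
  eq <- published_models()[[model_id]]
  if (is.null(eq)) stop("unknown model_id: ", model_id, call. = FALSE)
  features <- as.list(features)
  need <- names(eq$coefficients)
  have <- names(features)
  if (length(setdiff(need, have))) {
    stop("missing feature(s): ", paste(setdiff(need, have), collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(have, need))) {
    stop("unexpected feature(s): ", paste(setdiff(have, need), collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(features[need], as.numeric)
  lens <- vapply(vals, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("features must have equal lengths", call. = FALSE)
  }
  x <- do.call(cbind, vals)
  drop(eq$intercept + x %*% eq$coefficients[need])
}
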