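# Model development: exhaustive enumeration of candidate predictor subsets,
# OLS fitting with the full fit-statistic panel, sign-consistency and VIF
# screening, and minimum-AIC selection.

#' Candidate model specification
#'
#' A candidate is one heart-rate variable (`"pct_hrr"` or `"hr"` — the two
#' are too strongly correlated to co-occur) plus a subset of covariates from
#' one of two families: family `"A"` allows weight and height but excludes
#' BMI, family `"B"` allows BMI but excludes weight and height (BMI is
#' strongly correlated with weight, so the families are fitted separately).
#'
#' @param hr_variable `"pct_hrr"` or `"hr"`.
#' @param covariates Character subset of the family's covariates (possibly
#'   empty): family A — `resting_hr`, `sex`, `age`, `height`, `weight`;
#'   family B — `resting_hr`, `sex`, `age`, `bmi`.
#' @param family `"A"` or `"B"`.
#' @return A `"hrmets_spec"` object with element `predictors`
#'   (hr variable first, covariates sorted).
#' @export
candidate_spec <- function(hr_variable = c("pct_hrr", "hr"),
                           covariates = character(),
                           family = c("A", "B")) {
  hr_variable <- match.arg(hr_variable)
  family <- match.arg(family)
  allowed <- family_covariates(family)
  bad <- setdiff(covariates, allowed)
  if (length(bad)) {
    stop("covariate(s) not allowed in family ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(covariates)) {
    stop("duplicated covariates", call. = FALSE)
  }
  structure(
    list(hr_variable = hr_variable,
         covariates = sort(unique(covariates)),
         family = family,
         predictors = c(hr_variable, sort(unique(covariates)))),
    class = "hrmets_spec"
  )
}

family_covariates <- function(family) {
  switch(family,
         A = c("resting_hr", "sex", "age", "height", "weight"),
         B = c("resting_hr", "sex", "age", "bmi"),
         stop("unknown family: ", family, call. = FALSE))
}

#' Enumerate all candidate models of a family
#'
#' Brute-force enumeration: every subset of the family's covariates (2^5 =
#' 32 for family A, 2^4 = 16 for family B), each combined with the
#' mandatory heart-rate variable. Setting `force_hr = FALSE` additionally
#' enumerates subsets without the heart-rate variable.
#'
#' @inheritParams candidate_spec
#' @param force_hr Keep the heart-rate variable in every candidate
#'   (default `TRUE`; every published model contains one).
#' @return A list of [candidate_spec()] objects.
#' @export
enumerate_candidates <- function(hr_variable = c("pct_hrr", "hr"),
                                 family = c("A", "B"),
                                 force_hr = TRUE) {
  hr_variable <- match.arg(hr_variable)
  family <- match.arg(family)
  covs <- family_covariates(family)
  subsets <- list(character())
  for (v in covs) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, v)))
  }
  specs <- lapply(subsets, candidate_spec,
                  hr_variable = hr_variable, family = family)
  if (!force_hr) {
    no_hr <- lapply(subsets[lengths(subsets) > 0L], function(s) {
      sp <- candidate_spec(hr_variable, s, family)
      sp$hr_variable <- NA_character_
      sp$predictors <- sp$covariates
      sp
    })
    specs <- c(specs, no_hr)
  }
  specs
}

#' Assemble the regression frame from observations and subjects
#'
#' Joins the subject-activity observations with the cohort table to a flat
#' modelling frame: response `mets` plus the candidate predictors
#' `pct_hrr`, `hr` (the activity mean HR), `resting_hr`, `sex` (M = 1,
#' F = 0), `age`, `height`, `weight`, `bmi`.
#'
#' @param observations An `"hrmets_observations"` data frame.
#' @param subjects An `"hrmets_subjects"` data frame.
#' @return A data frame with one row per observation.
#' @export
model_frame <- function(observations, subjects) {
  stopifnot(all(c("subject_id", "mets", "pct_hrr", "mean_hr") %in%
                  names(observations)))
  df <- merge(as.data.frame(observations), as.data.frame(subjects),
              by = "subject_id", sort = FALSE)
  data.frame(
    subject_id = df$subject_id,
    activity = df$activity,
    mets = df$mets,
    pct_hrr = df$pct_hrr,
    hr = df$mean_hr,
    resting_hr = df$resting_hr,
    sex = df$sex_code,
    age = df$age,
    height = df$height,
    weight = df$weight,
    bmi = df$bmi,
    stringsAsFactors = FALSE
  )
}

# intercept-first design matrix for a predictor set
design_matrix <- function(frame, predictors) {
  x <- as.matrix(frame[, predictors, drop = FALSE])
  cbind(`(Intercept)` = 1, x)
}

# minimal OLS for resampling loops: coefficients only
fast_ols_coef <- function(x, y) {
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    stop("rank-deficient design in resampling fit", call. = FALSE)
  }
  fit$coefficients
}

#' Fit a candidate model by ordinary least squares
#'
#' Fits METs on the candidate's predictors over the pooled observations and
#' computes the study's full fit-statistic panel: coefficients with standard
#' errors and p-values, standardized coefficients (coef x SD(x)/SD(y)),
#' multiple correlation r = sqrt(R2), R2, adjusted R2, SEE =
#' sqrt(RSS/(n - k - 1)), AIC in the least-squares Gaussian profile form
#' n log(RSS/n) + 2(k + 2) (slopes + intercept + error variance), variance
#' inflation factors from auxiliary regressions of each predictor on the
#' others (VIF = 1 for a single-predictor model), and each predictor's
#' marginal Pearson correlation with METs (used by the sign-consistency
#' screen).
#'
#' @param observations An `"hrmets_observations"` data frame.
#' @param spec A [candidate_spec()].
#' @param subjects An `"hrmets_subjects"` data frame.
#' @return An object of class `"hrmets_fit"`.
#' @export
fit_ols <- function(observations, spec, subjects) {
  stopifnot(inherits(spec, "hrmets_spec"))
  frame <- model_frame(observations, subjects)
  preds <- spec$predictors
  k <- length(preds)
  n <- nrow(frame)
  if (n <= k + 2) stop("too few observations for ", k, " predictors",
                       call. = FALSE)
  x <- design_matrix(frame, preds)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; offending predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(preds, response = "mets")
  fit <- stats::lm(fml, data = frame)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  see <- sqrt(rss / (n - k - 1))
  r2 <- sm$r.squared
  sy <- stats::sd(frame$mets)
  std_beta <- vapply(preds, function(p) {
    coefs[[p]] * stats::sd(frame[[p]]) / sy
  }, numeric(1))
  marginal_r <- vapply(preds, function(p) {
    stats::cor(frame[[p]], frame$mets)
  }, numeric(1))
  vif <- if (k == 1L) {
    stats::setNames(1, preds)
  } else {
    vapply(preds, function(p) {
      aux <- stats::lm(stats::reformulate(setdiff(preds, p), response = p),
                       data = frame)
      1 / (1 - summary(aux)$r.squared)
    }, numeric(1))
  }
  structure(
    list(spec = spec,
         intercept = coefs[["(Intercept)"]],
         coefficients = coefs[preds],
         standard_errors = sm$coefficients[, "Std. Error"],
         p_values = sm$coefficients[, "Pr(>|t|)"],
         standardized_betas = std_beta,
         marginal_r = marginal_r,
         r = sqrt(r2),
         r2 = r2,
         adj_r2 = sm$adj.r.squared,
         see = see,
         rss = rss,
         aic = if (rss > 0) n * log(rss / n) + 2 * (k + 2) else -Inf,
         vif = vif,
         n_obs = n,
         lm_fit = fit),
    class = "hrmets_fit"
  )
}

#' Predict from a fitted candidate model
#'
#' @param object An `"hrmets_fit"`.
#' @param newdata A modelling frame (see [model_frame()]) holding the
#'   model's predictors.
#' @param ... Unused.
#' @return Predicted METs.
#' @export
predict.hrmets_fit <- function(object, newdata, ...) {
  x <- design_matrix(newdata, object$spec$predictors)
  drop(x %*% c(object$intercept, object$coefficients))
}

#' @export
print.hrmets_fit <- function(x, ...) {
  cat("OLS MET model (", x$spec$family, "family ):",
      paste(x$spec$predictors, collapse = " + "), "\n")
  tab <- data.frame(
    beta = c(x$intercept, x$coefficients),
    se = x$standard_errors,
    p = x$p_values,
    std_beta = c(NA, x$standardized_betas),
    vif = c(NA, x$vif)
  )
  rownames(tab) <- c("(Intercept)", names(x$coefficients))
  print(round(tab, 4))
  cat(sprintf("n = %d, r = %.3f, R2 = %.3f, adj R2 = %.3f, SEE = %.3f, AIC = %.1f\n",
              x$n_obs, x$r, x$r2, x$adj_r2, x$see, x$aic))
  invisible(x)
}

#' Sign-consistency screen for multicollinearity
#'
#' A fitted coefficient whose sign differs from the sign of its predictor's
#' marginal correlation with METs indicates a suppressor/collinearity
#' artifact. Each predictor passes when sign(coefficient) equals
#' sign(marginal r); an exactly zero coefficient or correlation passes by
#' convention.
#'
#' @param model An `"hrmets_fit"`.
#' @return Named logical vector, `TRUE` = consistent.
#' @export
sign_consistency_check <- function(model) {
  stopifnot(inherits(model, "hrmets_fit"))
  b <- model$coefficients
  r <- model$marginal_r[names(b)]
  b == 0 | r == 0 | sign(b) == sign(r)
}

#' Select the best candidate by minimum AIC
#'
#' Screens the fitted candidates — those failing the sign-consistency check
#' or containing any predictor with VIF at or above `vif_exclude` are
#' excluded — then returns the minimum-AIC survivor. Ties are broken toward
#' fewer predictors, then lexicographically on the predictor names. Models
#' with zero residual sum of squares (AIC undefined at -Inf) are compared by
#' predictor count alone. Survivors with any VIF above `vif_flag` are noted
#' in the returned model's `vif_flagged` field (the study observed all VIFs
#' below 1.1 but used that as a check, not an exclusion rule).
#'
#' @param models List of `"hrmets_fit"` objects fitted on the same
#'   observations.
#' @param vif_exclude Hard VIF exclusion threshold (default 10).
#' @param vif_flag Report-only VIF flag threshold (default 1.1).
#' @return The selected `"hrmets_fit"`, with `vif_flagged` added.
#' @export
select_best <- function(models, vif_exclude = 10, vif_flag = 1.1) {
  if (length(models) == 0L) stop("no candidate models", call. = FALSE)
  ok <- vapply(models, function(m) {
    all(sign_consistency_check(m)) && all(m$vif < vif_exclude)
  }, logical(1))
  if (!any(ok)) {
    info <- vapply(models, function(m) {
      sprintf("%s (sign ok: %s, max VIF: %.2f)",
              paste(m$spec$predictors, collapse = "+"),
              all(sign_consistency_check(m)), max(m$vif))
    }, character(1))
    stop("every candidate was screened out:\n",
         paste(" ", info, collapse = "\n"), call. = FALSE)
  }
  survivors <- models[ok]
  aic <- vapply(survivors, `[[`, numeric(1), "aic")
  npred <- vapply(survivors, function(m) length(m$spec$predictors),
                  integer(1))
  keynames <- vapply(survivors, function(m) {
    paste(m$spec$predictors, collapse = "|")
  }, character(1))
  ord <- order(aic, npred, keynames)
  best <- survivors[[ord[1L]]]
  best$vif_flagged <- any(best$vif > vif_flag)
  best
}
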