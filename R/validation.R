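# Validation: leave-one-subject-out prediction, MPE/RMSE summaries with
# Wilcoxon comparisons, modified Bland-Altman agreement, and repeated 2:1
# hold-out RMSE.

#' Leave-one-subject-out predictions
#'
#' For each subject in turn, fits the candidate specification on every other
#' subject's observations and predicts the held-out subject's observations.
#' The leave-out unit is the subject, never the observation: all of a
#' subject's activities leave together, so no model ever sees data from the
#' subject it predicts. Every observation is predicted exactly once.
#'
#' @param observations An `"hrmets_observations"` data frame.
#' @param subjects An `"hrmets_subjects"` data frame (>= 3 subjects).
#' @param spec A [candidate_spec()].
#' @return A data frame with columns `subject_id`, `activity`, `measured`,
#'   `estimated`.
#' @export
loso_predict <- function(observations, subjects, spec) {
  stopifnot(inherits(spec, "hrmets_spec"))
  frame <- model_frame(observations, subjects)
  ids <- unique(frame$subject_id)
  if (length(ids) < 3L) stop("need at least 3 subjects", call. = FALSE)
  preds <- spec$predictors
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    test <- frame$subject_id == ids[i]
    train <- frame[!test, , drop = FALSE]
    cf <- tryCatch(
      fast_ols_coef(design_matrix(train, preds), train$mets),
      error = function(e) {
        stop("leave-one-out fit failed on fold for subject ", ids[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
    xt <- design_matrix(frame[test, , drop = FALSE], preds)
    out[[i]] <- data.frame(
      subject_id = frame$subject_id[test],
      activity = frame$activity[test],
      measured = frame$mets[test],
      estimated = drop(xt %*% cf),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean percent error
#'
#' MPE (%) = (estimated - measured) / measured x 100, per observation.
#'
#' @param measured Measured METs (> 0).
#' @param estimated Estimated METs.
#' @return Percent errors (same length as the inputs).
#' @export
mpe <- function(measured, estimated) {
  stopifnot(is.numeric(measured), is.numeric(estimated),
            length(measured) == length(estimated))
  if (any(measured <= 0)) stop("`measured` must be positive", call. = FALSE)
  (estimated - measured) / measured * 100
}

#' Root mean square error
#'
#' @param measured Measured METs.
#' @param estimated Estimated METs.
#' @return sqrt(mean((estimated - measured)^2)), METs.
#' @export
rmse <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated))
  if (length(measured) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((estimated - measured)^2))
}

#' Per-activity validation report
#'
#' Summarizes (measured, estimated) prediction pairs per activity and in
#' total: MPE mean and SD over the pooled predictions, RMSE, and a
#' two-sided Wilcoxon signed-rank test of measured vs estimated (exact for
#' fewer than 25 pairs, normal approximation otherwise; groups with fewer
#' than 2 pairs, or with all differences zero, get `NA` with a flag).
#'
#' @param pairs Data frame with columns `activity`, `measured`, `estimated`
#'   (e.g. from [loso_predict()]).
#' @return An object of class `"hrmets_validation"`: a data frame with
#'   columns `activity`, `n`, `mpe_mean`, `mpe_sd`, `rmse`, `wilcoxon_p`,
#'   `flag`, ending with a `"Total"` row.
#' @export
activity_report <- function(pairs) {
  stopifnot(all(c("activity", "measured", "estimated") %in% names(pairs)))
  summarize <- function(m, e, label) {
    pe <- mpe(m, e)
    n <- length(m)
    flag <- ""
    p <- NA_real_
    if (n < 2L) {
      flag <- "too few pairs for test"
    } else if (all(e - m == 0)) {
      flag <- "degenerate: all differences zero"
    } else {
      # ties or zero differences make the exact test unavailable; wilcox.test
      # then falls back to the normal approximation, which is accepted quietly
      p <- tryCatch(
        suppressWarnings(
          stats::wilcox.test(e, m, paired = TRUE, exact = n < 25)$p.value),
        error = function(err) NA_real_)
      if (is.na(p)) flag <- "test failed"
    }
    data.frame(activity = label, n = n,
               mpe_mean = mean(pe), mpe_sd = stats::sd(pe),
               rmse = rmse(m, e), wilcoxon_p = p, flag = flag,
               stringsAsFactors = FALSE)
  }
  acts <- unique(pairs$activity)
  rows <- lapply(acts, function(a) {
    g <- pairs[pairs$activity == a, ]
    summarize(g$measured, g$estimated, a)
  })
  rows[[length(rows) + 1L]] <-
    summarize(pairs$measured, pairs$estimated, "Total")
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("hrmets_validation", "data.frame")
  rep
}

#' @export
print.hrmets_validation <- function(x, digits = 2, ...) {
  cat("Validation report (MPE %, RMSE in METs):\n")
  y <- as.data.frame(x)
  y$mpe <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                   y$mpe_mean, y$mpe_sd)
  y$rmse <- round(y$rmse, digits)
  y$p <- signif(y$wilcoxon_p, 2)
  print(y[, c("activity", "n", "mpe", "rmse", "p")], row.names = FALSE)
  invisible(x)
}

#' Modified Bland-Altman agreement analysis
#'
#' Differences are estimated minus measured METs. Reports the bias (mean
#' difference), the half-width of the 95% limits of agreement (1.96 x SD of
#' the differences), the limits themselves, and the trend of the
#' differences against the magnitude axis (Pearson r and its p-value). The
#' "modified" axis is the measured METs — the reference method — rather
#' than the pair mean; set `axis = "mean"` for the classic plot.
#'
#' @param measured Measured METs (>= 3 values).
#' @param estimated Estimated METs.
#' @param axis `"measured"` (default) or `"mean"`.
#' @return An object of class `"hrmets_bland_altman"`: list with `bias`,
#'   `loa_half_width`, `loa_lower`, `loa_upper`, `trend_r`, `trend_p`,
#'   `axis`, `n`, `flag`.
#' @export
bland_altman <- function(measured, estimated, axis = c("measured", "mean")) {
  axis <- match.arg(axis)
  stopifnot(length(measured) == length(estimated))
  if (length(measured) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- estimated - measured
  xax <- if (axis == "measured") measured else (measured + estimated) / 2
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  flag <- ""
  trend_r <- NA_real_
  trend_p <- NA_real_
  if (stats::sd(xax) == 0) {
    flag <- "zero variance on magnitude axis; trend undefined"
  } else if (stats::sd(d) == 0) {
    flag <- "zero variance of differences; trend undefined"
  } else {
    ct <- stats::cor.test(d, xax)
    trend_r <- unname(ct$estimate)
    trend_p <- ct$p.value
  }
  structure(
    list(bias = bias, loa_half_width = half,
         loa_lower = bias - half, loa_upper = bias + half,
         trend_r = trend_r, trend_p = trend_p,
         axis = axis, n = length(d), flag = flag),
    class = "hrmets_bland_altman"
  )
}

#' @export
print.hrmets_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d, axis = %s): bias %.3f METs, 95%% LoA %.3f to %.3f (half-width %.3f)\n",
    x$n, x$axis, x$bias, x$loa_lower, x$loa_upper, x$loa_half_width))
  if (!is.na(x$trend_r)) {
    cat(sprintf("  trend of differences vs magnitude: r = %.3f (p = %.3g)\n",
                x$trend_r, x$trend_p))
  }
  if (nzchar(x$flag)) cat(" ", x$flag, "\n")
  invisible(x)
}

#' Repeated 2:1 hold-out validation
#'
#' Repeatedly splits the subjects (never the observations) at random into a
#' development group of round(2n/3) subjects and a validation group of the
#' rest, fits the candidate on the development group, and computes the
#' per-activity RMSE on the validation group. Per-activity RMSEs are
#' averaged across the repetitions in which the activity appears in the
#' validation split.
#'
#' @param observations An `"hrmets_observations"` data frame.
#' @param subjects An `"hrmets_subjects"` data frame.
#' @param spec A [candidate_spec()].
#' @param n_reps Number of repetitions (default 10000, the study protocol;
#'   a few hundred suffice for stable averages at desk scale).
#' @param seed Integer seed; mandatory.
#' @return An object of class `"hrmets_holdout"`: list with `per_activity`
#'   (data frame `activity`, `rmse`, `n_reps_contributing`), `total_rmse`,
#'   `n_reps`, `n_dev`, `n_val`, `seed`.
#' @export
holdout_rmse <- function(observations, subjects, spec, n_reps = 10000L,
                         seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(spec, "hrmets_spec"), n_reps >= 1L)
  frame <- model_frame(observations, subjects)
  ids <- unique(frame$subject_id)
  n <- length(ids)
  n_dev <- round(2 * n / 3)
  if (n_dev < 2L || n_dev >= n) stop("too few subjects to split",
                                     call. = FALSE)
  preds <- spec$predictors
  acts <- unique(frame$activity)
  sums <- stats::setNames(numeric(length(acts)), acts)
  cnts <- stats::setNames(integer(length(acts)), acts)
  tot_sum <- 0
  set.seed(as.integer(seed))
  subj_of_row <- match(frame$subject_id, ids)
  x_all <- design_matrix(frame, preds)
  for (r in seq_len(n_reps)) {
    dev <- sample.int(n, n_dev)
    in_dev <- subj_of_row %in% dev
    cf <- fast_ols_coef(x_all[in_dev, , drop = FALSE], frame$mets[in_dev])
    est <- drop(x_all[!in_dev, , drop = FALSE] %*% cf)
    meas <- frame$mets[!in_dev]
    act_val <- frame$activity[!in_dev]
    err2 <- (est - meas)^2
    for (a in unique(act_val)) {
      sel <- act_val == a
      sums[a] <- sums[a] + sqrt(mean(err2[sel]))
      cnts[a] <- cnts[a] + 1L
    }
    tot_sum <- tot_sum + sqrt(mean(err2))
  }
  per <- data.frame(activity = acts,
                    rmse = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_),
                    n_reps_contributing = cnts,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(
    list(per_activity = per, total_rmse = tot_sum / n_reps,
         n_reps = as.integer(n_reps), n_dev = n_dev, n_val = n - n_dev,
         seed = as.integer(seed)),
    class = "hrmets_holdout"
  )
}

#' @export
print.hrmets_holdout <- function(x, ...) {
  cat(sprintf(
    "Repeated hold-out: %d reps, %d development / %d validation subjects\n",
    x$n_reps, x$n_dev, x$n_val))
  y <- x$per_activity
  y$rmse <- round(y$rmse, 3)
  print(y, row.names = FALSE)
  cat(sprintf("Total RMSE (mean over reps): %.3f METs\n", x$total_rmse))
  invisible(x)
}
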