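# R-R interval preprocessing: fixed-length epochs, SD-based artifact
# screening, and per-minute averaging to a single activity heart rate.

#' Convert an R-R interval series to epoch heart rates
#'
#' Partitions the recording into fixed epochs (default 0.4 s) and assigns
#' each epoch the heart rate 60 / (overlap-weighted mean R-R of the beats
#' covering it). A beat with interval `rr` ending at time `t` occupies
#' `[t - rr, t]`; its contribution to an epoch is weighted by the length of
#' the overlap. Epochs with no beat coverage are missing (`NA`).
#'
#' @param series A data frame with columns `t_seconds` (cumulative time at
#'   each beat, monotone non-decreasing) and `rr_seconds` (> 0); see
#'   [generate_rr_series()] and [read_rr_csv()].
#' @param epoch_length Epoch length in seconds (> 0), default 0.4.
#' @return An object of class `"hrmets_epochs"`: a list with
#'   `epoch_length`, `hr` (bpm per epoch, `NA` where uncovered) and
#'   `n_removed` (0 until outlier screening).
#' @export
rr_to_epoch_hr <- function(series, epoch_length = 0.4) {
  stopifnot(is.data.frame(series),
            all(c("t_seconds", "rr_seconds") %in% names(series)))
  if (nrow(series) == 0L) stop("`series` is empty", call. = FALSE)
  if (!is.numeric(epoch_length) || epoch_length <= 0) {
    stop("`epoch_length` must be positive", call. = FALSE)
  }
  rr <- series$rr_seconds
  tt <- series$t_seconds
  if (any(rr <= 0)) stop("non-positive R-R intervals present", call. = FALSE)
  if (is.unsorted(tt)) stop("timestamps must be non-decreasing", call. = FALSE)

  beat_end <- tt
  beat_start <- tt - rr
  t0 <- min(beat_start)
  beat_start <- beat_start - t0
  beat_end <- beat_end - t0
  total <- max(beat_end)
  n_epochs <- ceiling(total / epoch_length - 1e-9)

  # split each beat into its per-epoch overlap segments (a beat spans few
  # epochs, so the expansion stays small)
  j_start <- pmax(0L, floor(beat_start / epoch_length))
  j_end <- pmin(n_epochs - 1L, floor((beat_end - 1e-12) / epoch_length))
  span <- j_end - j_start + 1L
  beat_idx <- rep.int(seq_along(rr), span)
  epoch_idx <- unlist(lapply(seq_along(rr),
                             function(i) j_start[i]:j_end[i]),
                      use.names = FALSE)
  seg_lo <- pmax(beat_start[beat_idx], epoch_idx * epoch_length)
  seg_hi <- pmin(beat_end[beat_idx], (epoch_idx + 1) * epoch_length)
  w <- pmax(seg_hi - seg_lo, 0)

  wsum <- rep(0, n_epochs)
  wrr <- rep(0, n_epochs)
  pos <- epoch_idx + 1L
  wsum_agg <- tapply(w, pos, sum)
  wrr_agg <- tapply(w * rr[beat_idx], pos, sum)
  ids <- as.integer(names(wsum_agg))
  wsum[ids] <- wsum_agg
  wrr[ids] <- wrr_agg

  hr <- rep(NA_real_, n_epochs)
  covered <- wsum > 1e-9
  hr[covered] <- 60 / (wrr[covered] / wsum[covered])
  structure(list(epoch_length = epoch_length, hr = hr, n_removed = 0L),
            class = "hrmets_epochs")
}

#' Screen epoch heart rates for artifacts
#'
#' Marks missing every epoch whose heart rate lies outside
#' mean +/- `k_sd` x SD, with the mean and SD taken over the recording's
#' non-missing epochs in a single pass (the convention used here: 4 SD for
#' radio calisthenics, 3 SD for other activities). A constant trace
#' (SD = 0) is artifact-free by construction, so nothing is removed. Already
#' missing epochs stay missing.
#'
#' @param epochs An `"hrmets_epochs"` object.
#' @param k_sd Positive SD multiplier (3 or 4 in the study protocol).
#' @return The cleaned `"hrmets_epochs"` object; `n_removed` counts the
#'   epochs newly set missing.
#' @export
remove_epoch_outliers <- function(epochs, k_sd = 3) {
  stopifnot(inherits(epochs, "hrmets_epochs"))
  if (!is.numeric(k_sd) || k_sd <= 0) {
    stop("`k_sd` must be positive", call. = FALSE)
  }
  hr <- epochs$hr
  ok <- !is.na(hr)
  if (!any(ok)) stop("all epochs are missing", call. = FALSE)
  mu <- mean(hr[ok])
  sdev <- stats::sd(hr[ok])
  if (is.na(sdev) || sdev == 0) {
    epochs$n_removed <- 0L
    return(epochs)
  }
  out <- ok & (hr < mu - k_sd * sdev | hr > mu + k_sd * sdev)
  hr[out] <- NA_real_
  epochs$hr <- hr
  epochs$n_removed <- sum(out)
  epochs
}

# minute index (1-based) for each epoch, plus the per-minute epoch counts
minute_index <- function(epochs) {
  per_min <- round(60 / epochs$epoch_length)
  (seq_along(epochs$hr) - 1L) %/% per_min + 1L
}

#' Mean activity heart rate by per-minute averaging
#'
#' The activity heart rate is the unweighted mean of per-minute means: each
#' minute's heart rate is the mean over its non-missing epochs, and minutes
#' with no surviving epoch are dropped. A partial trailing minute is kept if
#' it holds at least 15 s of epochs, otherwise dropped.
#'
#' @param epochs An `"hrmets_epochs"` object (screened or not).
#' @return Mean heart rate, bpm.
#' @export
activity_mean_hr <- function(epochs) {
  stopifnot(inherits(epochs, "hrmets_epochs"))
  idx <- minute_index(epochs)
  last <- max(idx)
  n_last <- sum(idx == last)
  if (last > 1L && n_last * epochs$epoch_length < 15) {
    keep <- idx < last
    idx <- idx[keep]
    hr <- epochs$hr[keep]
  } else {
    hr <- epochs$hr
  }
  mins <- tapply(hr, idx, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  mins <- mins[!is.na(mins)]
  if (length(mins) == 0L) stop("no usable minutes", call. = FALSE)
  mean(mins)
}

#' Resting heart rate from a seated window
#'
#' Applies the per-minute averaging of [activity_mean_hr()] to the opening
#' seated window of the recording (default 7 min, the study's resting
#' protocol).
#'
#' @param epochs An `"hrmets_epochs"` object covering at least `window`
#'   seconds.
#' @param window Window length in seconds, default 420 (7 min).
#' @return Resting heart rate, bpm.
#' @export
resting_hr_from_window <- function(epochs, window = 420) {
  stopifnot(inherits(epochs, "hrmets_epochs"))
  n_window <- round(window / epochs$epoch_length)
  if (n_window > length(epochs$hr)) {
    stop("`window` exceeds the recording length", call. = FALSE)
  }
  sub <- epochs
  sub$hr <- epochs$hr[seq_len(n_window)]
  activity_mean_hr(sub)
}

#' @export
print.hrmets_epochs <- function(x, ...) {
  n <- length(x$hr)
  cat(sprintf(
    "Epoch HR series: %d epochs of %.1f s (%.1f s), %d missing, %d removed as outliers\n",
    n, x$epoch_length, n * x$epoch_length, sum(is.na(x$hr)), x$n_removed))
  invisible(x)
}
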