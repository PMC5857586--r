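#' Combine the two eyes' pupil traces
#'
#' Per sample: the mean of the valid eyes' pupil diameters, the single valid
#' eye's value when only one eye was tracked, and missing when neither was.
#'
#' @param samples a `gz_recording` or data frame of samples.
#' @return Numeric vector of pupil diameters (mm) on the recording grid,
#'   `NA` where no eye was tracked.
#' @export
combine_eyes <- function(samples) {
  s <- .as_samples(samples)
  pl <- s$pupil_left
  pr <- s$pupil_right
  pl[!s$valid_left] <- NA_real_
  pr[!s$valid_right] <- NA_real_
  out <- pl
  only_r <- is.na(pl) & !is.na(pr)
  out[only_r] <- pr[only_r]
  both <- !is.na(pl) & !is.na(pr)
  out[both] <- (pl[both] + pr[both]) / 2
  out
}

#' Four-step pupil preprocessing
#'
#' Applies, strictly in order:
#' 1. range clamp: values outside `range_mm` (default 2.5-5.5 mm) become
#'    missing (the bounds themselves are retained);
#' 2. step rejection: a value whose absolute difference from the previous
#'    retained value exceeds `max_step_mm` (default 1 mm) becomes missing;
#'    the reference is the previous retained value, so a removed spike does
#'    not cascade rejections (a difference of exactly 1 mm is retained);
#' 3. gap interpolation: interior runs of missing values shorter than
#'    `max_gap_samples` (default 10; i.e. 9-sample gaps are filled,
#'    10-sample gaps are not) are linearly interpolated between the flanking
#'    retained values; longer runs and runs touching either edge stay
#'    missing;
#' 4. smoothing: a moving average of width `ma_window` (default 10) samples.
#'    A width of 10 cannot be centered exactly; the window covers 5 samples
#'    before through 4 after the current one and is truncated at the edges of
#'    each contiguous retained segment; output is missing where the input is.
#'
#' A constant trace passes through all four steps unchanged; an all-missing
#' trace passes through all-missing.
#'
#' @param values numeric pupil trace (mm) on a uniform sample grid,
#'   `NA` = missing.
#' @param range_mm length-2 numeric, plausible pupil-diameter range in mm.
#' @param max_step_mm maximum physiologically plausible inter-sample change.
#' @param max_gap_samples gaps of this length or longer are not interpolated.
#' @param ma_window moving-average width in samples.
#' @return Cleaned numeric trace, same length as `values`.
#' @export
#' @examples
#' clean_pupil(c(3.0, 6.0, 3.1))   # spike removed, then interpolated: 3.05
clean_pupil <- function(values, range_mm = c(2.5, 5.5), max_step_mm = 1.0,
                        max_gap_samples = 10L, ma_window = 10L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n == 0) return(x)
  # step 1: range clamp
  x[!is.na(x) & (x < range_mm[1] | x > range_mm[2])] <- NA_real_
  # step 2: inter-sample step rejection
  x[!step_reject_cpp(x, max_step_mm)] <- NA_real_
  # step 3: linear interpolation of short interior gaps
  x <- interpolate_gaps_cpp(x, max_gap_samples)
  # step 4: moving average
  back <- ma_window %/% 2L
  fwd <- as.integer(ma_window) - 1L - back
  moving_average_cpp(x, back, fwd)
}

#' Score one evaluation trial's pupil dilation
#'
#' The baseline window is the 1000 ms immediately before the giver grasps the
#' block; the analysis window starts at the grasp and lasts 3000 ms. The
#' trial change score is the mean cleaned pupil diameter in the analysis
#' window minus the baseline-window mean. A trial is valid only when both
#' windows lie within the trace and each retains at least
#' `min_valid_fraction` of its samples after cleaning.
#'
#' @param values cleaned pupil trace from [clean_pupil()].
#' @param t sample times (seconds), same length as `values`.
#' @param grasp_t time the giver grasped the block.
#' @param baseline_s baseline window length (seconds).
#' @param analysis_s analysis window length (seconds).
#' @param min_valid_fraction minimum retained fraction per window.
#' @param trial_id,condition carried through to the result.
#' @return A list `trial_id, condition, baseline_mean, analysis_mean, change,
#'   valid, reason`.
#' @export
score_dilation_trial <- function(values, t, grasp_t, baseline_s = 1.0,
                                 analysis_s = 3.0, min_valid_fraction = 0.5,
                                 trial_id = NA_character_,
                                 condition = NA_character_) {
  eps <- 1e-9
  res <- list(trial_id = trial_id, condition = condition,
              baseline_mean = NA_real_, analysis_mean = NA_real_,
              change = NA_real_, valid = FALSE, reason = NA_character_)
  if (length(t) == 0) {
    res$reason <- "empty_trace"
    return(res)
  }
  n <- length(t)
  dt <- if (n > 1) (t[n] - t[1]) / (n - 1) else 1
  if (t[1] > grasp_t - baseline_s + eps ||
      t[n] < grasp_t + analysis_s - dt - eps) {
    res$reason <- "window_outside_trace"
    return(res)
  }
  # half-open windows resolved by index arithmetic on the uniform grid
  u <- (grasp_t - baseline_s - t[1]) / dt
  v <- (grasp_t - t[1]) / dt
  w <- (grasp_t + analysis_s - t[1]) / dt
  b_lo <- max(1L, as.integer(ceiling(u - 1e-6)) + 1L)
  b_hi <- min(n, as.integer(ceiling(v - 1e-6)))
  a_lo <- max(1L, as.integer(ceiling(v - 1e-6)) + 1L)
  a_hi <- min(n, as.integer(ceiling(w - 1e-6)))
  if (b_hi < b_lo || a_hi < a_lo) {
    res$reason <- "window_outside_trace"
    return(res)
  }
  bv <- values[b_lo:b_hi]
  av <- values[a_lo:a_hi]
  fb <- mean(!is.na(bv))
  fa <- mean(!is.na(av))
  if (fb < min_valid_fraction || fa < min_valid_fraction) {
    res$reason <- "insufficient_valid_samples"
    return(res)
  }
  res$baseline_mean <- mean(bv, na.rm = TRUE)
  res$analysis_mean <- mean(av, na.rm = TRUE)
  res$change <- res$analysis_mean - res$baseline_mean
  res$valid <- TRUE
  res
}

#' Aggregate trial dilations to one participant difference score
#'
#' Condition means of the valid trials' change scores; the participant's
#' dependent variable is the inappropriate-condition mean minus the
#' appropriate-condition mean, so positive values index surprise at the
#' inappropriate interaction. Participants need at least `min_per_condition`
#' valid trials in *each* condition (published rule: three) to be included.
#'
#' @param trial_dilations list of results from [score_dilation_trial()] (or a
#'   data frame with `condition`, `change`, `valid` columns).
#' @param min_per_condition minimum valid trials per condition.
#' @return A list `n_valid_appropriate, n_valid_inappropriate,
#'   mean_change_appropriate, mean_change_inappropriate, difference, included`.
#' @export
aggregate_dilation <- function(trial_dilations, min_per_condition = 3L) {
  if (!is.data.frame(trial_dilations)) {
    trial_dilations <- data.frame(
      condition = vapply(trial_dilations, function(d) d$condition, ""),
      change = vapply(trial_dilations, function(d) d$change, 1),
      valid = vapply(trial_dilations, function(d) isTRUE(d$valid), TRUE)
    )
  }
  ok <- trial_dilations[trial_dilations$valid, , drop = FALSE]
  app <- ok$change[ok$condition == "appropriate"]
  inapp <- ok$change[ok$condition == "inappropriate"]
  included <- length(app) >= min_per_condition &&
    length(inapp) >= min_per_condition
  m_app <- if (length(app) > 0) mean(app) else NA_real_
  m_inapp <- if (length(inapp) > 0) mean(inapp) else NA_real_
  list(n_valid_appropriate = length(app),
       n_valid_inappropriate = length(inapp),
       mean_change_appropriate = m_app,
       mean_change_inappropriate = m_inapp,
       difference = if (included) m_inapp - m_app else NA_real_,
       included = included)
}
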