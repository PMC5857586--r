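#' Score one coded reaching trial
#'
#' The motor dependent variable is the reach-onset time relative to the
#' moment the moving object crossed the infant's midline; negative values
#' mean the reach started before the object arrived (a predictive reach).
#' A trial is valid only if the infant attended at trial start (coding
#' criterion 1) and the coders judged the movement a reach (3 cm toward the
#' object plus a qualifying follow event); both judgements are coder inputs,
#' not computed here.
#'
#' @param row one coded reach row (list or one-row data frame with
#'   `attended_ok, reach_valid, reach_onset_t, midline_t`).
#' @return A list `valid, latency_s, reason` (`latency_s` present iff valid).
#' @export
score_reach_trial <- function(row) {
  row <- as.list(row)
  if (!isTRUE(row$attended_ok)) {
    return(list(valid = FALSE, latency_s = NA_real_, reason = "not_attending"))
  }
  if (!isTRUE(row$reach_valid)) {
    return(list(valid = FALSE, latency_s = NA_real_, reason = "no_valid_reach"))
  }
  list(valid = TRUE, latency_s = row$reach_onset_t - row$midline_t,
       reason = NA_character_)
}

#' Aggregate coded reach trials to one participant score
#'
#' Averages valid-trial latencies over trials whose toy speed is in
#' `use_speeds`. By default only fast trials contribute: the slow trials do
#' not load on the other measures (insufficient task demands) and are removed
#' from the analysis. A single valid fast trial suffices for inclusion,
#' matching the analyzed range of 1-2 contributed trials.
#'
#' @param rows data frame of coded reach rows for one participant.
#' @param use_speeds character vector of speeds to analyze.
#' @param min_trials minimum number of valid trials for inclusion.
#' @return A list `n_valid_trials, mean_latency_s, included, classification`.
#' @export
aggregate_reach <- function(rows, use_speeds = "fast", min_trials = 1L) {
  use <- rows$speed %in% use_speeds & rows$attended_ok & rows$reach_valid
  lat <- rows$reach_onset_t[use] - rows$midline_t[use]
  lat <- lat[!is.na(lat)]
  n <- length(lat)
  included <- n >= min_trials
  mean_lat <- if (included) mean(lat) else NA_real_
  list(n_valid_trials = n,
       mean_latency_s = mean_lat,
       included = included,
       classification = if (!included) "excluded"
       else if (mean_lat < 0) "predictive" else "reactive")
}
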