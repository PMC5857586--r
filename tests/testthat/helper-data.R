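# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests themselves write.

make_samples <- function(x, y, valid = TRUE, sr = 60, pupil = 3.5) {
  n <- length(x)
  data.frame(t = (seq_len(n) - 1) / sr, gaze_x = x, gaze_y = y,
             pupil_left = rep(pupil, n), pupil_right = rep(pupil, n),
             valid_left = rep_len(valid, n), valid_right = rep_len(valid, n))
}

# a gaze trace wandering between dwell clusters, with occasional tracking
# loss: exercises run detection, boundary assignment, merging, invalid gaps
random_trace <- function(n, seed) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  i <- 1L
  while (i <= n) {
    len <- sample(2:25, 1)
    # occasionally revisit a nearby cluster so that merges actually happen
    cx <- if (runif(1) < 0.3 && i > 1) x[i - 1] + runif(1, -30, 30)
          else runif(1, 100, 1820)
    cy <- if (runif(1) < 0.3 && i > 1) y[i - 1] + runif(1, -30, 30)
          else runif(1, 100, 980)
    idx <- i:min(n, i + len - 1L)
    sdj <- runif(1, 0.3, 9)
    x[idx] <- cx + rnorm(length(idx), 0, sdj)
    y[idx] <- cy + rnorm(length(idx), 0, sdj)
    i <- max(idx) + 1L
  }
  valid <- rep(TRUE, n)
  for (b in seq_len(rpois(1, 2))) {
    s <- sample.int(n, 1)
    valid[s:min(n, s + sample(1:8, 1))] <- FALSE
  }
  df <- make_samples(x, y)
  df$valid_left <- valid
  df$valid_right <- valid
  df$gaze_x[!valid] <- NA_real_
  df$gaze_y[!valid] <- NA_real_
  df
}

make_recording <- function(samples, pid = "p001", age = "6mo", sr = 60) {
  new_recording(samples, participant_id = pid, age_group = age,
                sample_rate = sr)
}

# noiseless, artifact-free generator settings used by the recovery tests:
# identical study structure, all stochastic nuisance terms at zero
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(latency_sd_ms = 0, pupil_noise_sd_mm = 0, gaze_jitter_px = 0,
         blink_rate_hz = 0, spike_rate_hz = 0, dropout_prediction = 0,
         dropout_evaluation = 0, dropout_reach = 0, pupil_baseline_sd_mm = 0),
    list(...))
  do.call(cohort_config, args)
}
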