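#' Synthetic cohort configuration
#'
#' Describes a simulated infant cohort: per-participant latent traits
#' (prediction-gaze latency in ms, pupil dilation amplitude in mm, reach
#' latency in ms) drawn from a trivariate normal with a configurable
#' correlation structure, plus trial counts, per-trial noise, and artifact
#' rates. The trait correlations are specified on the *performance-oriented*
#' scale (predictive skill positive, larger surprise positive); internally
#' the latency traits, which are negative-is-better in raw ms, receive the
#' matching sign flip, so the configured prediction-evaluation correlation is
#' exactly what the oriented statistics layer should recover.
#'
#' Default trait means follow the published 6-month group effects
#' (-40 ms prediction latency, 0.063 mm dilation difference, -380 ms reach
#' latency); trait SDs are set from the corresponding group SEs times
#' sqrt(n); the default prediction-evaluation correlation is 0.34.
#'
#' @param n_participants cohort size.
#' @param seed integer seed; every random draw in the cohort flows from it
#'   (per-participant streams are derived deterministically, so any subset of
#'   participants regenerates identically).
#' @param age_group cohort age label.
#' @param n_prediction_trials,n_evaluation_trials,n_reach_slow,n_reach_fast
#'   trial counts (defaults: 6 eating actions, 6 + 6 evaluation trials,
#'   3 slow + 3 fast reach trials).
#' @param trait_means,trait_sds named numeric vectors
#'   (`prediction_ms`, `evaluation_mm`, `motor_ms`).
#' @param trait_correlations 3x3 symmetric positive-semidefinite matrix on
#'   the oriented scale, order (prediction, evaluation, motor).
#' @param latency_sd_ms per-trial timing noise for gaze and reach latencies.
#' @param pupil_noise_sd_mm additive per-sample pupil noise.
#' @param gaze_jitter_px fixational jitter SD (kept below the velocity
#'   threshold).
#' @param blink_rate_hz,blink_mean_samples blink events per second and mean
#'   blink length (geometric).
#' @param spike_rate_hz rate of single-sample pupil artifacts (out-of-range
#'   values or >1 mm steps, exercising the cleaning chain).
#' @param dropout_prediction,dropout_evaluation,dropout_reach per-trial
#'   probabilities that a trial yields no usable data.
#' @param pupil_peak_s,pupil_shape gamma-shaped pupil response kernel: peak
#'   latency in seconds and gamma shape (> 1).
#' @param pupil_baseline_mean_mm,pupil_baseline_sd_mm per-trial tonic pupil
#'   level.
#' @param catch_prob probability a valid reach catches the toy.
#' @param sample_rate Hz.
#' @param geometry a [default_geometry()] list.
#' @param bowl_center,mouth_center stimulus AOI centers in pixels.
#' @return A list with class `gz_cohort_config`.
#' @export
cohort_config <- function(n_participants = 118L, seed = 1L, age_group = "6mo",
                          n_prediction_trials = 6L, n_evaluation_trials = 12L,
                          n_reach_slow = 3L, n_reach_fast = 3L,
                          trait_means = c(prediction_ms = -40, evaluation_mm = 0.063,
                                          motor_ms = -380),
                          trait_sds = c(prediction_ms = 400, evaluation_mm = 0.14,
                                        motor_ms = 350),
                          trait_correlations = matrix(c(1, 0.34, 0.33,
                                                        0.34, 1, 0.12,
                                                        0.33, 0.12, 1), 3, 3),
                          latency_sd_ms = 150, pupil_noise_sd_mm = 0.05,
                          gaze_jitter_px = 2,
                          blink_rate_hz = 0.2, blink_mean_samples = 5,
                          spike_rate_hz = 0.05,
                          dropout_prediction = 0.35, dropout_evaluation = 0.08,
                          dropout_reach = 0.5,
                          pupil_peak_s = 1.2, pupil_shape = 3,
                          pupil_baseline_mean_mm = 3.5, pupil_baseline_sd_mm = 0.2,
                          catch_prob = 0.57,
                          sample_rate = 60, geometry = default_geometry(),
                          bowl_center = c(660, 700), mouth_center = c(660, 260)) {
  R <- trait_correlations
  if (!isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(unname(diag(R)), rep(1, 3)))) {
    stop("trait_correlations must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("trait_correlations must be positive semidefinite", call. = FALSE)
  }
  probs <- c(dropout_prediction, dropout_evaluation, dropout_reach)
  stopifnot(all(probs >= 0 & probs <= 1), all(trait_sds >= 0),
            pupil_shape > 1, pupil_peak_s > 0, sample_rate > 0,
            n_participants >= 1)
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_group = age_group,
    n_prediction_trials = as.integer(n_prediction_trials),
    n_evaluation_trials = as.integer(n_evaluation_trials),
    n_reach_slow = as.integer(n_reach_slow),
    n_reach_fast = as.integer(n_reach_fast),
    trait_means = trait_means, trait_sds = trait_sds,
    trait_correlations = R,
    latency_sd_ms = latency_sd_ms, pupil_noise_sd_mm = pupil_noise_sd_mm,
    gaze_jitter_px = gaze_jitter_px,
    blink_rate_hz = blink_rate_hz, blink_mean_samples = blink_mean_samples,
    spike_rate_hz = spike_rate_hz,
    dropout_prediction = dropout_prediction,
    dropout_evaluation = dropout_evaluation, dropout_reach = dropout_reach,
    pupil_peak_s = pupil_peak_s, pupil_shape = pupil_shape,
    pupil_baseline_mean_mm = pupil_baseline_mean_mm,
    pupil_baseline_sd_mm = pupil_baseline_sd_mm,
    catch_prob = catch_prob,
    sample_rate = sample_rate, geometry = geometry,
    bowl_center = bowl_center, mouth_center = mouth_center,
    # emulated stimulus timelines (seconds from trial start); shorter than
    # the full movies, covering exactly the analyzed events
    pred_timeline = c(pickup = 0.4, leaves = 1.6, arrival = 3.2, duration = 4.5),
    eval_timeline = c(grasp = 1.5, duration = 5.0),
    # reach task geometry: 65 cm trajectory, midline at half, 30 / 42 cm/s
    reach_midline_s = c(slow = 32.5 / 30, fast = 32.5 / 42)
  ), class = "gz_cohort_config")
}

# raw-scale latent covariance: latency traits are negative-is-better, so the
# oriented correlation matrix gets sign-flipped rows/columns for them
.raw_sigma <- function(config) {
  D <- diag(c(-1, 1, -1))
  S <- diag(config$trait_sds)
  S %*% (D %*% config$trait_correlations %*% D) %*% S
}

#' Draw latent traits for a cohort
#'
#' Samples each participant's (prediction ms, evaluation mm, motor ms) trait
#' vector from the configured trivariate normal. Deterministic under the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return Tibble `participant_id, theta_pred_ms, theta_eval_mm,
#'   theta_motor_ms` -- the cohort's ground truth.
#' @export
sample_traits <- function(config) {
  set.seed(config$seed)
  th <- MASS::mvrnorm(config$n_participants, mu = unname(config$trait_means),
                      Sigma = .raw_sigma(config))
  th <- matrix(th, ncol = 3)
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(config$n_participants)),
    theta_pred_ms = th[, 1], theta_eval_mm = th[, 2], theta_motor_ms = th[, 3]
  )
}

#' Gamma-shaped pupil response kernel
#'
#' The generator's event-related pupil response: a gamma-shaped impulse
#' response `t^(shape-1) exp(-t / scale)` with its peak at `peak_s` seconds
#' after the event, scaled so that its *mean over the analysis window*
#' (`[0, analysis_s]`) equals 1. With that scaling a trial generated with
#' amplitude A has a noiseless window-mean change of exactly A, making the
#' latent trait directly comparable to the scored dependent variable. The
#' kernel is a generator-side assumption only; the scoring side never uses it.
#'
#' @param t seconds since the event (values `<= 0` map to 0).
#' @param peak_s kernel peak latency in seconds.
#' @param shape gamma shape parameter (> 1).
#' @param analysis_s normalization window length in seconds.
#' @return Kernel values at `t`.
#' @export
pupil_response_kernel <- function(t, peak_s = 1.2, shape = 3, analysis_s = 3) {
  stopifnot(shape > 1, peak_s > 0)
  b <- peak_s / (shape - 1)
  k <- ifelse(t > 0, t^(shape - 1) * exp(-t / b), 0)
  norm <- gamma(shape) * b^shape * pgamma(analysis_s, shape, scale = b)
  k * analysis_s / norm
}

# ---- per-trial simulators (internal fast paths return plain vectors) ----

.sim_pred_trial <- function(theta_pred_ms, config) {
  sr <- config$sample_rate
  tl <- config$pred_timeline
  n <- round(tl[["duration"]] * sr)
  t_local <- (seq_len(n) - 1) / sr
  L <- theta_pred_ms / 1000 + rnorm(1, 0, config$latency_sd_ms / 1000)
  onset_idx <- as.integer(round((tl[["arrival"]] + L) * sr)) + 1L
  onset_idx <- min(max(onset_idx, as.integer(round(tl[["leaves"]] * sr)) + 4L),
                   n - 6L)
  gx <- rep(config$mouth_center[1], n)
  gy <- rep(config$mouth_center[2], n)
  bowl_end <- onset_idx - 3L
  gx[1:bowl_end] <- config$bowl_center[1]
  gy[1:bowl_end] <- config$bowl_center[2]
  # 2-sample saccade at 1/3 and 2/3 of the way to the mouth
  for (s in 1:2) {
    gx[bowl_end + s] <- config$bowl_center[1] +
      (config$mouth_center[1] - config$bowl_center[1]) * s / 3
    gy[bowl_end + s] <- config$bowl_center[2] +
      (config$mouth_center[2] - config$bowl_center[2]) * s / 3
  }
  if (config$gaze_jitter_px > 0) {
    gx <- gx + rnorm(n, 0, config$gaze_jitter_px)
    gy <- gy + rnorm(n, 0, config$gaze_jitter_px)
  }
  valid <- rep(TRUE, n)
  if (runif(1) < config$dropout_prediction) {
    lost <- t_local >= tl[["leaves"]]
    valid[lost] <- FALSE
    gx[lost] <- NA_real_
    gy[lost] <- NA_real_
  }
  pupil <- config$pupil_baseline_mean_mm + rnorm(n, 0, config$pupil_noise_sd_mm)
  pupil[!valid] <- NA_real_
  list(n = n, gx = gx, gy = gy, pupil = pupil, valid = valid,
       food_pickup_t = tl[["pickup"]], spoon_leaves_bowl_t = tl[["leaves"]],
       spoon_reaches_mouth_t = tl[["arrival"]])
}

.sim_eval_trial <- function(theta_eval_mm, condition, config) {
  sr <- config$sample_rate
  tl <- config$eval_timeline
  n <- round(tl[["duration"]] * sr)
  t_local <- (seq_len(n) - 1) / sr
  b <- rnorm(1, config$pupil_baseline_mean_mm, config$pupil_baseline_sd_mm)
  amp <- if (condition == "inappropriate") theta_eval_mm else 0
  ker <- config$.eval_kernel
  if (is.null(ker)) {
    ker <- pupil_response_kernel(t_local - tl[["grasp"]],
                                 config$pupil_peak_s, config$pupil_shape)
  }
  pupil <- b + amp * ker + rnorm(n, 0, config$pupil_noise_sd_mm)
  gx <- config$geometry$screen_px[1] / 2 + rnorm(n, 0, config$gaze_jitter_px)
  gy <- config$geometry$screen_px[2] / 2 + rnorm(n, 0, config$gaze_jitter_px)
  valid <- rep(TRUE, n)
  # single-sample artifacts: out-of-range values and large steps
  n_spike <- rpois(1, config$spike_rate_hz * tl[["duration"]])
  if (n_spike > 0) {
    idx <- sample.int(n, min(n_spike, n))
    pupil[idx] <- pupil[idx] +
      sample(c(-1, 1), length(idx), replace = TRUE) * runif(length(idx), 1.2, 3.2)
  }
  # blinks: missing runs of geometric length
  n_blink <- rpois(1, config$blink_rate_hz * tl[["duration"]])
  if (n_blink > 0) {
    starts <- sample.int(n, min(n_blink, n))
    lens <- 1L + rgeom(length(starts), 1 / config$blink_mean_samples)
    for (j in seq_along(starts)) {
      run <- starts[j]:min(n, starts[j] + lens[j] - 1L)
      valid[run] <- FALSE
    }
  }
  if (runif(1) < config$dropout_evaluation) valid[] <- FALSE
  pupil[!valid] <- NA_real_
  gx[!valid] <- NA_real_
  gy[!valid] <- NA_real_
  list(n = n, gx = gx, gy = gy, pupil = pupil, valid = valid,
       grasp_t = tl[["grasp"]], condition = condition)
}

#' Simulate one action-prediction trial
#'
#' Emulates the gaze structure of an eating-action trial: a fixation on the
#' bowl from trial start through the spoon's departure, a 2-sample saccade,
#' then a fixation in the mouth AOI whose onset is the spoon's mouth-arrival
#' time plus the participant's latent prediction latency plus timing noise.
#' With probability `dropout_prediction` gaze is lost for the scoring window.
#' Draws from the current RNG state (see [simulate_cohort()] for the seeded
#' per-participant streams).
#'
#' @param theta_pred_ms latent prediction latency (ms; negative = predictive).
#' @param config a [cohort_config()].
#' @param t0 recording-clock offset of the trial start (seconds).
#' @param trial_id annotation id.
#' @return List with `samples` (data frame in the recording dialect) and
#'   `annotation` (list of event times on the recording clock).
#' @export
simulate_prediction_trial <- function(theta_pred_ms, config = cohort_config(),
                                      t0 = 0, trial_id = "pred1") {
  tr <- .sim_pred_trial(theta_pred_ms, config)
  t <- t0 + (seq_len(tr$n) - 1) / config$sample_rate
  list(samples = data.frame(t = t, gaze_x = tr$gx, gaze_y = tr$gy,
                            pupil_left = tr$pupil, pupil_right = tr$pupil,
                            valid_left = tr$valid, valid_right = tr$valid),
       annotation = list(trial_id = trial_id, task = "prediction",
                         condition = NA_character_,
                         food_pickup_t = t0 + tr$food_pickup_t,
                         spoon_leaves_bowl_t = t0 + tr$spoon_leaves_bowl_t,
                         spoon_reaches_mouth_t = t0 + tr$spoon_reaches_mouth_t,
                         grasp_t = NA_real_))
}

#' Simulate one action-evaluation trial
#'
#' Emulates an event-related pupil trace around the giver's block grasp: a
#' per-trial tonic baseline plus, on inappropriate trials, the gamma-shaped
#' response kernel scaled by the participant's latent dilation amplitude,
#' plus per-sample noise, blinks (missing runs), and single-sample artifacts
#' that exercise the cleaning chain. Appropriate trials carry no response.
#'
#' @param theta_eval_mm latent dilation amplitude (mm).
#' @param condition `"appropriate"` or `"inappropriate"`.
#' @inheritParams simulate_prediction_trial
#' @return List with `samples` and `annotation`, as in
#'   [simulate_prediction_trial()].
#' @export
simulate_evaluation_trial <- function(theta_eval_mm, condition,
                                      config = cohort_config(), t0 = 0,
                                      trial_id = "eval1") {
  tr <- .sim_eval_trial(theta_eval_mm, condition, config)
  t <- t0 + (seq_len(tr$n) - 1) / config$sample_rate
  list(samples = data.frame(t = t, gaze_x = tr$gx, gaze_y = tr$gy,
                            pupil_left = tr$pupil, pupil_right = tr$pupil,
                            valid_left = tr$valid, valid_right = tr$valid),
       annotation = list(trial_id = trial_id, task = "evaluation",
                         condition = condition,
                         food_pickup_t = NA_real_,
                         spoon_leaves_bowl_t = NA_real_,
                         spoon_reaches_mouth_t = NA_real_,
                         grasp_t = t0 + tr$grasp_t))
}

#' Simulate a participant's coded reach table
#'
#' Slow trials first, then fast trials. Valid fast-trial reach onsets are the
#' midline-crossing time plus the latent motor latency plus timing noise;
#' with probability `dropout_reach` a trial is invalid (split between
#' not-attending and no-valid-reach codes). Draws from the current RNG state.
#'
#' @param theta_motor_ms latent reach latency (ms; negative = predictive).
#' @param config a [cohort_config()].
#' @param participant_id id column value.
#' @return Data frame in the coded-reach dialect.
#' @export
simulate_reach_table <- function(theta_motor_ms, config = cohort_config(),
                                 participant_id = "p001") {
  n_trials <- config$n_reach_slow + config$n_reach_fast
  speed <- c(rep("slow", config$n_reach_slow), rep("fast", config$n_reach_fast))
  object_start_t <- (seq_len(n_trials) - 1) * 8
  midline_t <- object_start_t + unname(config$reach_midline_s[speed])
  onset <- midline_t + theta_motor_ms / 1000 +
    rnorm(n_trials, 0, config$latency_sd_ms / 1000)
  invalid <- runif(n_trials) < config$dropout_reach
  not_attending <- invalid & runif(n_trials) < 0.5
  attended_ok <- !not_attending
  reach_valid <- !invalid
  onset[!reach_valid] <- NA_real_
  caught <- reach_valid & runif(n_trials) < config$catch_prob
  .fast_df(list(participant_id = rep(participant_id, n_trials),
                trial_index = seq_len(n_trials), speed = speed,
                attended_ok = attended_ok, object_start_t = object_start_t,
                reach_onset_t = onset, midline_t = midline_t,
                reach_valid = reach_valid, caught = caught), n_trials)
}

.participant_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 9973) %% 2147483629)
}

.simulate_participant <- function(pid, theta, config) {
  sr <- config$sample_rate
  n_pred <- round(config$pred_timeline[["duration"]] * sr)
  n_eval <- round(config$eval_timeline[["duration"]] * sr)
  n_total <- config$n_prediction_trials * n_pred +
    config$n_evaluation_trials * n_eval
  gx <- numeric(n_total); gy <- numeric(n_total)
  pupil <- numeric(n_total); valid <- logical(n_total)
  ann <- vector("list", config$n_prediction_trials + config$n_evaluation_trials)
  pos <- 0L
  for (k in seq_len(config$n_prediction_trials)) {
    tr <- .sim_pred_trial(theta$theta_pred_ms, config)
    idx <- pos + seq_len(tr$n)
    gx[idx] <- tr$gx; gy[idx] <- tr$gy
    pupil[idx] <- tr$pupil; valid[idx] <- tr$valid
    t0 <- pos / sr
    ann[[k]] <- list(trial_id = paste0("pred", k), task = "prediction",
                     condition = NA_character_,
                     food_pickup_t = t0 + tr$food_pickup_t,
                     spoon_leaves_bowl_t = t0 + tr$spoon_leaves_bowl_t,
                     spoon_reaches_mouth_t = t0 + tr$spoon_reaches_mouth_t,
                     grasp_t = NA_real_)
    pos <- pos + tr$n
  }
  conditions <- rep(c("appropriate", "inappropriate"),
                    length.out = config$n_evaluation_trials)
  for (k in seq_len(config$n_evaluation_trials)) {
    tr <- .sim_eval_trial(theta$theta_eval_mm, conditions[k], config)
    idx <- pos + seq_len(tr$n)
    gx[idx] <- tr$gx; gy[idx] <- tr$gy
    pupil[idx] <- tr$pupil; valid[idx] <- tr$valid
    t0 <- pos / sr
    ann[[config$n_prediction_trials + k]] <-
      list(trial_id = paste0("eval", k), task = "evaluation",
           condition = conditions[k],
           food_pickup_t = NA_real_, spoon_leaves_bowl_t = NA_real_,
           spoon_reaches_mouth_t = NA_real_, grasp_t = t0 + tr$grasp_t)
    pos <- pos + tr$n
  }
  samples <- .fast_df(list(t = (seq_len(n_total) - 1) / sr,
                           gaze_x = gx, gaze_y = gy,
                           pupil_left = pupil, pupil_right = pupil,
                           valid_left = valid, valid_right = valid), n_total)
  n_ann <- length(ann)
  trials <- .fast_df(list(
    participant_id = rep(pid, n_ann),
    trial_id = vapply(ann, `[[`, "", "trial_id"),
    task = vapply(ann, `[[`, "", "task"),
    condition = vapply(ann, `[[`, "", "condition"),
    food_pickup_t = vapply(ann, `[[`, 1, "food_pickup_t"),
    spoon_leaves_bowl_t = vapply(ann, `[[`, 1, "spoon_leaves_bowl_t"),
    spoon_reaches_mouth_t = vapply(ann, `[[`, 1, "spoon_reaches_mouth_t"),
    grasp_t = vapply(ann, `[[`, 1, "grasp_t")
  ), n_ann)
  reaches <- simulate_reach_table(theta$theta_motor_ms, config, pid)
  rec <- new_recording(samples, participant_id = pid,
                       age_group = config$age_group,
                       sample_rate = sr, geometry = config$geometry)
  list(recording = rec, trials = trials, reaches = reaches)
}

#' Simulate a complete synthetic cohort
#'
#' Draws latent traits, then generates every participant's raw recording
#' (prediction trials followed by evaluation trials on one continuous 60 Hz
#' clock), trial annotations, and coded reach table. All randomness flows
#' from `config$seed`: traits use the seed directly and each participant uses
#' a seed derived deterministically from it, so regenerating the cohort (or
#' any subset of participants) is reproducible.
#'
#' @param config a [cohort_config()].
#' @return A list with class `gz_cohort`: `recordings` (named list of
#'   `gz_recording`), `trials`, `reaches`, `truth` (latent traits), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  truth <- sample_traits(config)
  n <- config$n_participants
  # the response kernel on the trial grid is identical for every trial
  n_eval <- round(config$eval_timeline[["duration"]] * config$sample_rate)
  config$.eval_kernel <- pupil_response_kernel(
    (seq_len(n_eval) - 1) / config$sample_rate - config$eval_timeline[["grasp"]],
    config$pupil_peak_s, config$pupil_shape)
  recordings <- vector("list", n)
  trials <- vector("list", n)
  reaches <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.participant_seed(config$seed, i))
    p <- .simulate_participant(truth$participant_id[i],
                               list(theta_pred_ms = truth$theta_pred_ms[i],
                                    theta_eval_mm = truth$theta_eval_mm[i],
                                    theta_motor_ms = truth$theta_motor_ms[i]),
                               config)
    recordings[[i]] <- p$recording
    trials[[i]] <- p$trials
    reaches[[i]] <- p$reaches
  }
  names(recordings) <- truth$participant_id
  structure(list(recordings = recordings,
                 trials = tibble::as_tibble(do.call(rbind, trials)),
                 reaches = dplyr::bind_rows(reaches),
                 truth = truth, config = config),
            class = "gz_cohort")
}

#' @export
print.gz_cohort <- function(x, ...) {
  cat(sprintf("<gz_cohort> %d participants (%s), seed %d\n",
              x$config$n_participants, x$config$age_group, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one `recording_<id>.tsv` per participant plus shared `trials.tsv`,
#' `reaches.tsv`, and `truth.tsv` (the latent traits; the analysis pipeline
#' consumes only the first three).
#'
#' @param cohort a `gz_cohort`.
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  for (pid in names(cohort$recordings)) {
    write_recording(cohort$recordings[[pid]],
                    file.path(directory, paste0("recording_", pid, ".tsv")))
  }
  write_trials(cohort$trials, file.path(directory, "trials.tsv"))
  write_reaches(cohort$reaches, file.path(directory, "reaches.tsv"))
  readr::write_tsv(cohort$truth, file.path(directory, "truth.tsv"),
                   na = "", progress = FALSE)
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory cohort directory.
#' @param config a [cohort_config()] supplying geometry, sample rate, and age
#'   group for the recordings.
#' @return A `gz_cohort` (without `truth` unless `truth.tsv` is present).
#' @export
read_cohort <- function(directory, config = cohort_config()) {
  trials <- read_trials(file.path(directory, "trials.tsv"))
  reaches <- read_reaches(file.path(directory, "reaches.tsv"))
  pids <- unique(trials$participant_id)
  recordings <- lapply(pids, function(pid) {
    read_recording(file.path(directory, paste0("recording_", pid, ".tsv")),
                   geometry = config$geometry, participant_id = pid,
                   age_group = config$age_group,
                   sample_rate = config$sample_rate)
  })
  names(recordings) <- pids
  truth_path <- file.path(directory, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(recordings = recordings, trials = trials, reaches = reaches,
                 truth = truth, config = config),
            class = "gz_cohort")
}
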