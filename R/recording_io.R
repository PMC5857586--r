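#' Screen and viewing geometry
#'
#' Bundles the physical description of the display needed to convert visual
#' degrees to pixels: screen resolution, physical screen size, and the
#' eye-to-screen viewing distance. The defaults describe a 23-inch 1920 x 1080
#' research monitor viewed at 600 mm; they are package assumptions, to be
#' overridden when the true geometry of a setup is known.
#'
#' @param screen_px integer length-2, screen width and height in pixels.
#' @param screen_mm numeric length-2, physical width and height in mm.
#' @param viewing_distance numeric, eye-to-screen distance in mm.
#' @return A list with class `gz_geometry`.
#' @export
#' @examples
#' default_geometry()
default_geometry <- function(screen_px = c(1920L, 1080L),
                             screen_mm = c(509, 286),
                             viewing_distance = 600) {
  stopifnot(length(screen_px) == 2, length(screen_mm) == 2,
            all(screen_px > 0), all(screen_mm > 0), viewing_distance > 0)
  structure(list(screen_px = as.numeric(screen_px),
                 screen_mm = as.numeric(screen_mm),
                 viewing_distance = as.numeric(viewing_distance)),
            class = "gz_geometry")
}

#' Construct a gaze recording
#'
#' A recording is one participant's raw sample stream (60 Hz by default)
#' together with the screen geometry. Gaze is in screen pixels with the origin
#' at the top-left corner (x rightward, y downward); pupil diameters are in mm
#' and absent (`NA`) whenever the corresponding eye was not tracked; `t` is
#' seconds from recording onset, shared with the trial annotations.
#'
#' @param samples data frame with columns
#'   `t, gaze_x, gaze_y, pupil_left, pupil_right, valid_left, valid_right`.
#' @param participant_id opaque participant identifier.
#' @param age_group `"6mo"` or `"10mo"`.
#' @param sample_rate sampling rate in Hz.
#' @param geometry a [default_geometry()] list.
#' @return An object of class `gz_recording`.
#' @export
new_recording <- function(samples, participant_id, age_group = "6mo",
                          sample_rate = 60, geometry = default_geometry()) {
  stopifnot(sample_rate > 0)
  samples <- as.data.frame(samples)
  missing_cols <- setdiff(.recording_cols, names(samples))
  if (length(missing_cols) > 0) {
    stop("recording is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- structure(list(participant_id = as.character(participant_id),
                        age_group = as.character(age_group),
                        sample_rate = sample_rate,
                        geometry = geometry,
                        samples = samples[.recording_cols],
                        n_rejected_rows = 0L),
                   class = "gz_recording")
  validate_recording(rec)
}

#' @export
print.gz_recording <- function(x, ...) {
  cat(sprintf("<gz_recording> %s (%s), %d samples @ %g Hz\n",
              x$participant_id, x$age_group, nrow(x$samples), x$sample_rate))
  invisible(x)
}

#' Validate a recording's invariants
#'
#' Checks that timestamps increase strictly and that the median inter-sample
#' interval is within 10% of the nominal sampling period.
#'
#' @param rec a `gz_recording`.
#' @return `rec`, invisibly-checked (errors on violation).
#' @export
validate_recording <- function(rec) {
  t <- rec$samples$t
  if (length(t) >= 2) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad) > 0) {
      stop(sprintf("timestamps are not strictly increasing at row %d",
                   bad[1] + 1L), call. = FALSE)
    }
    nominal <- 1 / rec$sample_rate
    if (abs(median(dt) - nominal) > 0.1 * nominal) {
      stop(sprintf(paste0("median inter-sample interval %.6f s deviates more ",
                          "than 10%% from nominal %.6f s"),
                   median(dt), nominal), call. = FALSE)
    }
  }
  rec
}

.parse_num <- function(x) suppressWarnings(as.numeric(x))

.parse_flag <- function(x) {
  up <- toupper(trimws(x))
  out <- up %in% c("TRUE", "T", "1")
  out[is.na(x)] <- FALSE
  out
}

.read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

.require_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

#' Read a raw gaze recording
#'
#' Reads the tab-delimited recording dialect (UTF-8, fixed header
#' `t gaze_x gaze_y pupil_left pupil_right valid_left valid_right`; missing
#' values encoded as empty fields, never 0). Rows whose gaze or pupil fields
#' fail to parse become invalid samples; only rows with an unparseable
#' timestamp are rejected (and counted, so no row is ever silently dropped).
#'
#' @param path path to a `recording.tsv`-dialect file.
#' @param geometry a [default_geometry()] list.
#' @param participant_id,age_group,sample_rate recording metadata (the file
#'   carries only samples).
#' @return A `gz_recording`; the number of rejected rows is available as
#'   `$n_rejected_rows`.
#' @export
read_recording <- function(path, geometry = default_geometry(),
                           participant_id = basename(path), age_group = "6mo",
                           sample_rate = 60) {
  raw <- .read_tsv_chr(path)
  .require_cols(raw, .recording_cols, "recording file")
  n_in <- nrow(raw)
  t <- .parse_num(raw$t)
  keep <- !is.na(t)
  raw <- raw[keep, , drop = FALSE]
  gaze_x <- .parse_num(raw$gaze_x)
  gaze_y <- .parse_num(raw$gaze_y)
  pupil_left <- .parse_num(raw$pupil_left)
  pupil_right <- .parse_num(raw$pupil_right)
  valid_left <- .parse_flag(raw$valid_left) & !is.na(pupil_left)
  valid_right <- .parse_flag(raw$valid_right) & !is.na(pupil_right)
  # gaze unparseable on a nominally valid row -> invalid sample, not a failure
  gaze_bad <- is.na(gaze_x) | is.na(gaze_y)
  valid_left[gaze_bad & is.na(pupil_left)] <- FALSE
  valid_right[gaze_bad & is.na(pupil_right)] <- FALSE
  samples <- data.frame(t = t[keep], gaze_x = gaze_x, gaze_y = gaze_y,
                        pupil_left = pupil_left, pupil_right = pupil_right,
                        valid_left = valid_left, valid_right = valid_right)
  rec <- new_recording(samples, participant_id = participant_id,
                       age_group = age_group, sample_rate = sample_rate,
                       geometry = geometry)
  rec$n_rejected_rows <- n_in - nrow(samples)
  if (rec$n_rejected_rows > 0) {
    message(sprintf("read_recording: rejected %d row(s) with unparseable timestamps in %s",
                    rec$n_rejected_rows, path))
  }
  rec
}

#' Write a recording to the TSV dialect
#'
#' The inverse of [read_recording()]: full-precision text round trip, so
#' `read_recording(write_recording(rec))` reproduces every sample value
#' exactly, and re-writing the re-read file is byte-identical.
#'
#' @param recording a `gz_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gz_recording"))
  readr::write_tsv(recording$samples, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read trial annotations
#'
#' Trial annotations carry the per-trial stimulus event times driving both
#' scoring tasks, on the same clock as the recording: for prediction trials
#' the times at which the model picked up food, the spoon left the bowl
#' region, and the spoon reached the mouth region; for evaluation trials the
#' time at which the giver grasped the block, plus the condition label
#' (`appropriate` / `inappropriate`).
#'
#' @param path path to a `trials.tsv`-dialect file.
#' @return A tibble with one row per trial.
#' @export
read_trials <- function(path) {
  raw <- .read_tsv_chr(path)
  .require_cols(raw, .trial_cols, "trials file")
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    trial_id = raw$trial_id,
    task = raw$task,
    condition = ifelse(raw$condition == "" | is.na(raw$condition),
                       NA_character_, raw$condition),
    food_pickup_t = .parse_num(raw$food_pickup_t),
    spoon_leaves_bowl_t = .parse_num(raw$spoon_leaves_bowl_t),
    spoon_reaches_mouth_t = .parse_num(raw$spoon_reaches_mouth_t),
    grasp_t = .parse_num(raw$grasp_t)
  )
  validate_trials(out)
}

#' Validate trial annotations
#'
#' Enforces the event-time ordering of prediction trials
#' (`food_pickup_t < spoon_leaves_bowl_t < spoon_reaches_mouth_t`), the
#' presence of a condition label on evaluation trials, and that evaluation
#' `grasp_t` leaves room for a 1 s baseline.
#'
#' @param trials a tibble as returned by [read_trials()].
#' @return `trials`, unchanged (errors on violation).
#' @export
validate_trials <- function(trials) {
  bad_task <- !trials$task %in% c("prediction", "evaluation")
  if (any(bad_task)) {
    stop("unknown task label(s): ",
         paste(unique(trials$task[bad_task]), collapse = ", "), call. = FALSE)
  }
  pred <- trials[trials$task == "prediction", ]
  if (nrow(pred) > 0) {
    ok <- !is.na(pred$food_pickup_t) & !is.na(pred$spoon_leaves_bowl_t) &
      !is.na(pred$spoon_reaches_mouth_t) &
      pred$food_pickup_t < pred$spoon_leaves_bowl_t &
      pred$spoon_leaves_bowl_t < pred$spoon_reaches_mouth_t
    if (any(!ok)) {
      stop(sprintf("prediction trial %s: event times must satisfy food_pickup_t < spoon_leaves_bowl_t < spoon_reaches_mouth_t",
                   pred$trial_id[which(!ok)[1]]), call. = FALSE)
    }
  }
  ev <- trials[trials$task == "evaluation", ]
  if (nrow(ev) > 0) {
    if (any(is.na(ev$condition))) {
      stop(sprintf("evaluation trial %s: missing field 'condition'",
                   ev$trial_id[which(is.na(ev$condition))[1]]), call. = FALSE)
    }
    bad_cond <- !ev$condition %in% c("appropriate", "inappropriate")
    if (any(bad_cond)) {
      stop(sprintf("evaluation trial %s: condition must be 'appropriate' or 'inappropriate'",
                   ev$trial_id[which(bad_cond)[1]]), call. = FALSE)
    }
    if (any(is.na(ev$grasp_t))) {
      stop(sprintf("evaluation trial %s: missing field 'grasp_t'",
                   ev$trial_id[which(is.na(ev$grasp_t))[1]]), call. = FALSE)
    }
    too_early <- ev$grasp_t < 1.0
    if (any(too_early)) {
      stop(sprintf("evaluation trial %s: grasp_t must be at least 1.0 s after data start so the baseline window fits",
                   ev$trial_id[which(too_early)[1]]), call. = FALSE)
    }
  }
  trials
}

#' Write trial annotations
#' @param trials tibble of trial annotations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials[.trial_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a coded motor (reach) table
#'
#' One row per reaching trial as produced by human video coding: whether the
#' infant attended at trial start (coding criterion 1), the object-motion
#' onset, the reach onset (absent when no valid reach occurred), the time the
#' object crossed the infant's midline, the coder's reach-validity flag
#' (3 cm movement plus a qualifying follow event), catch success, and the
#' trial's toy speed (`slow`/`fast`).
#'
#' @param path path to a `reaches.tsv`-dialect file.
#' @return A tibble with one row per coded trial.
#' @export
read_reaches <- function(path) {
  raw <- .read_tsv_chr(path)
  .require_cols(raw, .reach_cols, "reaches file")
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    trial_index = as.integer(.parse_num(raw$trial_index)),
    speed = raw$speed,
    attended_ok = .parse_flag(raw$attended_ok),
    object_start_t = .parse_num(raw$object_start_t),
    reach_onset_t = .parse_num(raw$reach_onset_t),
    midline_t = .parse_num(raw$midline_t),
    reach_valid = .parse_flag(raw$reach_valid),
    caught = .parse_flag(raw$caught)
  )
  bad_speed <- !out$speed %in% c("slow", "fast")
  if (any(bad_speed)) {
    stop("reach speed must be 'slow' or 'fast' (row ",
         which(bad_speed)[1], ")", call. = FALSE)
  }
  orphan <- out$reach_valid & is.na(out$reach_onset_t)
  if (any(orphan)) {
    stop("reach coded valid but reach_onset_t missing (row ",
         which(orphan)[1], ")", call. = FALSE)
  }
  out
}

#' Write a coded motor (reach) table
#' @param reaches tibble of coded reach rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaches <- function(reaches, path) {
  readr::write_tsv(reaches[.reach_cols], path, na = "", progress = FALSE)
  invisible(path)
}
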