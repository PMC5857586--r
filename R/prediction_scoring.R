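#' Define a rectangular area of interest
#'
#' AOIs are centered on a screen location in pixels with extents given in
#' visual degrees (the published AOI size is 6.3 x 3.8 degrees for both the
#' bowl and the mouth region).
#'
#' @param name AOI label (e.g. `"bowl"`, `"mouth"`).
#' @param center_x,center_y AOI center in screen pixels.
#' @param width_deg,height_deg AOI extent in visual degrees.
#' @return A list with class `gz_aoi`.
#' @export
aoi <- function(name, center_x, center_y, width_deg = 6.3, height_deg = 3.8) {
  stopifnot(width_deg >= 0, height_deg >= 0)
  structure(list(name = name, center_x = center_x, center_y = center_y,
                 width_deg = width_deg, height_deg = height_deg),
            class = "gz_aoi")
}

#' Default AOIs for the synthetic feeding stimulus
#'
#' The synthetic eating-action stimulus places the bowl low-center and the
#' mouth high-center on the screen; these AOIs match the generator's layout.
#' Real stimuli supply their own centers via [aoi()].
#'
#' @return Named list with `bowl` and `mouth` AOIs.
#' @export
default_aois <- function() {
  list(bowl = aoi("bowl", 660, 700), mouth = aoi("mouth", 660, 260))
}

#' Convert an AOI from visual degrees to a pixel rectangle
#'
#' The pixel extent along each axis is `2 * distance * tan(deg / 2)` converted
#' through that axis' mm-per-pixel factor; the result is the half-open
#' axis-aligned rectangle `[x0, x1) x [y0, y1)` centered on the AOI center.
#'
#' @param a a [aoi()].
#' @param geometry a [default_geometry()] list.
#' @return Named numeric vector `c(x0, x1, y0, y1)` in pixels.
#' @export
#' @examples
#' aoi_to_pixels(aoi("mouth", 660, 260), default_geometry())
aoi_to_pixels <- function(a, geometry = default_geometry()) {
  stopifnot(all(geometry$screen_px > 0), all(geometry$screen_mm > 0))
  mm_per_px <- geometry$screen_mm / geometry$screen_px
  half_w <- geometry$viewing_distance * tan(a$width_deg / 2 * pi / 180) / mm_per_px[1]
  half_h <- geometry$viewing_distance * tan(a$height_deg / 2 * pi / 180) / mm_per_px[2]
  c(x0 = a$center_x - half_w, x1 = a$center_x + half_w,
    y0 = a$center_y - half_h, y1 = a$center_y + half_h)
}

.in_rect <- function(x, y, rect) {
  x >= rect[["x0"]] & x < rect[["x1"]] & y >= rect[["y0"]] & y < rect[["y1"]]
}

# fast path: AOIs already converted to pixel rectangles
.score_prediction_trial_rect <- function(fixations, annotation,
                                         bowl_rect, mouth_rect,
                                         post_arrival_window_s = 1.0) {
  pickup <- annotation$food_pickup_t
  leaves <- annotation$spoon_leaves_bowl_t
  arrival <- annotation$spoon_reaches_mouth_t
  w_end <- arrival + post_arrival_window_s
  res <- list(trial_id = annotation$trial_id, status = "no_data",
              latency_ms = NA_real_)
  if (nrow(fixations) == 0) return(res)
  on <- fixations$onset_t
  off <- fixations$offset_t
  span <- off >= pickup & on <= w_end
  if (!any(span)) return(res)
  in_bowl <- .in_rect(fixations$centroid_x, fixations$centroid_y, bowl_rect)
  in_mouth <- .in_rect(fixations$centroid_x, fixations$centroid_y, mouth_rect)
  # step 1: a bowl fixation during [food pickup, spoon leaves bowl]
  if (!any(in_bowl & off >= pickup & on <= leaves)) {
    res$status <- "no_bowl_fixation"
    return(res)
  }
  # step 2: bowl then mouth within [spoon leaves bowl, arrival + window]
  in_win <- off >= leaves & on <= w_end
  bowl_on <- on[in_bowl & in_win]
  mouth_on <- on[in_mouth & in_win]
  if (length(bowl_on) == 0 || length(mouth_on) == 0) {
    res$status <- "no_mouth_fixation"
    return(res)
  }
  qualifying <- mouth_on[mouth_on > min(bowl_on)]
  if (length(qualifying) == 0) {
    res$status <- "no_mouth_fixation"
    return(res)
  }
  # step 3: latency from the first qualifying mouth fixation's onset
  res$status <- "scored"
  res$latency_ms <- (min(qualifying) - arrival) * 1000
  res
}

#' Score one action-prediction trial
#'
#' Implements the trial inclusion rules and the latency dependent variable:
#' the trial is scorable only if (1) a fixation whose centroid lies in the
#' bowl AOI overlaps the period from food pickup until the spoon leaves the
#' bowl, and (2) within the scoring window from spoon-leaves-bowl until
#' `post_arrival_window_s` after the spoon reaches the mouth, a bowl-AOI
#' fixation is followed (strict onset ordering; intervening fixations
#' elsewhere are ignored) by a mouth-AOI fixation. The latency is the onset
#' of that first qualifying mouth fixation minus the spoon's mouth-arrival
#' time, in ms; negative values mean the gaze arrived before the spoon
#' (a predictive gaze shift). A fixation that began before the scoring window
#' but persists into it counts, with latency measured from its onset.
#'
#' AOI membership is decided by the fixation centroid, because AOI entry is
#' defined through the fixation filter rather than raw samples.
#'
#' @param fixations data frame from [detect_fixations()], sorted by onset.
#' @param annotation one prediction-trial annotation (list or one-row data
#'   frame with `trial_id, food_pickup_t, spoon_leaves_bowl_t,
#'   spoon_reaches_mouth_t`).
#' @param bowl_aoi,mouth_aoi [aoi()] objects.
#' @param geometry a [default_geometry()] list.
#' @param post_arrival_window_s seconds after spoon arrival during which a
#'   mouth fixation still counts.
#' @return A list `trial_id, status, latency_ms` where `status` is one of
#'   `scored, no_bowl_fixation, no_mouth_fixation, no_data` and `latency_ms`
#'   is present iff `status == "scored"`.
#' @export
score_prediction_trial <- function(fixations, annotation, bowl_aoi, mouth_aoi,
                                   geometry = default_geometry(),
                                   post_arrival_window_s = 1.0) {
  .score_prediction_trial_rect(fixations, as.list(annotation),
                               aoi_to_pixels(bowl_aoi, geometry),
                               aoi_to_pixels(mouth_aoi, geometry),
                               post_arrival_window_s)
}

#' Aggregate prediction-trial scores to one participant score
#'
#' Averages the scored trials' latencies; participants with fewer than
#' `min_trials` scored trials are excluded (the published rule removes
#' infants with fewer than two data points). Included participants are
#' classified `predictive` when the mean latency is negative and `reactive`
#' otherwise.
#'
#' @param trial_scores list of results from [score_prediction_trial()] (or a
#'   data frame with `status` and `latency_ms` columns).
#' @param min_trials minimum number of scored trials for inclusion.
#' @return A list `n_valid_trials, mean_latency_ms, included, classification`.
#' @export
aggregate_prediction <- function(trial_scores, min_trials = 2L) {
  if (is.data.frame(trial_scores)) {
    lat <- trial_scores$latency_ms[trial_scores$status == "scored"]
  } else {
    lat <- unlist(lapply(trial_scores, function(s) {
      if (identical(s$status, "scored")) s$latency_ms else NULL
    }))
  }
  n <- length(lat)
  included <- n >= min_trials
  mean_lat <- if (included) mean(lat) else NA_real_
  list(n_valid_trials = n,
       mean_latency_ms = mean_lat,
       included = included,
       classification = if (!included) "excluded"
       else if (mean_lat < 0) "predictive" else "reactive")
}
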