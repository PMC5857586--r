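#' Pipeline parameters
#'
#' Collects every stage's tunables with the published analysis values as
#' defaults: fixation-filter parameters, AOI definitions and screen geometry,
#' the post-arrival scoring window, the four pupil-cleaning parameters and
#' the baseline/analysis windows, and the inclusion thresholds (2 scored
#' prediction trials; 3 valid trials per pupil condition; fast reach trials
#' only, 1 trial minimum).
#'
#' @param filter a [filter_params()].
#' @param geometry a [default_geometry()].
#' @param bowl_aoi,mouth_aoi [aoi()] objects.
#' @param post_arrival_window_s seconds after spoon arrival during which a
#'   mouth fixation still counts.
#' @param min_prediction_trials inclusion threshold for the prediction score.
#' @param range_mm,max_step_mm,max_gap_samples,ma_window pupil-cleaning
#'   parameters, see [clean_pupil()].
#' @param baseline_s,analysis_s,min_valid_fraction dilation-scoring windows,
#'   see [score_dilation_trial()].
#' @param min_dilation_trials minimum valid trials per pupil condition.
#' @param reach_speeds toy speeds analyzed for the motor score.
#' @param min_reach_trials inclusion threshold for the reach score.
#' @return A list with class `gz_pipeline_params`.
#' @export
pipeline_params <- function(filter = filter_params(),
                            geometry = default_geometry(),
                            bowl_aoi = default_aois()$bowl,
                            mouth_aoi = default_aois()$mouth,
                            post_arrival_window_s = 1.0,
                            min_prediction_trials = 2L,
                            range_mm = c(2.5, 5.5), max_step_mm = 1.0,
                            max_gap_samples = 10L, ma_window = 10L,
                            baseline_s = 1.0, analysis_s = 3.0,
                            min_valid_fraction = 0.5,
                            min_dilation_trials = 3L,
                            reach_speeds = "fast", min_reach_trials = 1L) {
  structure(list(filter = filter, geometry = geometry,
                 bowl_aoi = bowl_aoi, mouth_aoi = mouth_aoi,
                 post_arrival_window_s = post_arrival_window_s,
                 min_prediction_trials = as.integer(min_prediction_trials),
                 range_mm = range_mm, max_step_mm = max_step_mm,
                 max_gap_samples = as.integer(max_gap_samples),
                 ma_window = as.integer(ma_window),
                 baseline_s = baseline_s, analysis_s = analysis_s,
                 min_valid_fraction = min_valid_fraction,
                 min_dilation_trials = as.integer(min_dilation_trials),
                 reach_speeds = reach_speeds,
                 min_reach_trials = as.integer(min_reach_trials)),
            class = "gz_pipeline_params")
}

#' Score one participant on all three tasks
#'
#' Runs the fixation filter and AOI latency scoring over the participant's
#' prediction trials, the pupil cleaning and baseline-corrected dilation
#' scoring over the evaluation trials, and the reach aggregation over the
#' coded motor table.
#'
#' @param recording the participant's `gz_recording`.
#' @param trials that participant's trial annotations.
#' @param reaches that participant's coded reach rows (may have zero rows).
#' @param params a [pipeline_params()].
#' @return A one-row data frame of the participant's summary measures.
#' @export
score_participant <- function(recording, trials, reaches,
                              params = pipeline_params()) {
  bowl_rect <- aoi_to_pixels(params$bowl_aoi, params$geometry)
  mouth_rect <- aoi_to_pixels(params$mouth_aoi, params$geometry)
  fix <- detect_fixations(recording, params$filter)

  trials <- as.data.frame(trials)
  is_pred <- trials$task == "prediction"
  pred_scores <- lapply(which(is_pred), function(i) {
    .score_prediction_trial_rect(
      fix,
      list(trial_id = trials$trial_id[i],
           food_pickup_t = trials$food_pickup_t[i],
           spoon_leaves_bowl_t = trials$spoon_leaves_bowl_t[i],
           spoon_reaches_mouth_t = trials$spoon_reaches_mouth_t[i]),
      bowl_rect, mouth_rect, params$post_arrival_window_s)
  })
  pred <- aggregate_prediction(pred_scores, params$min_prediction_trials)

  trace <- clean_pupil(combine_eyes(recording), params$range_mm,
                       params$max_step_mm, params$max_gap_samples,
                       params$ma_window)
  t <- recording$samples$t
  dil_scores <- lapply(which(!is_pred), function(i) {
    score_dilation_trial(trace, t, trials$grasp_t[i],
                         params$baseline_s, params$analysis_s,
                         params$min_valid_fraction,
                         trial_id = trials$trial_id[i],
                         condition = trials$condition[i])
  })
  dil <- aggregate_dilation(dil_scores, params$min_dilation_trials)

  reach <- aggregate_reach(reaches, params$reach_speeds,
                           params$min_reach_trials)

  .fast_df(list(
    participant_id = recording$participant_id,
    age_group = recording$age_group,
    prediction_latency_ms = pred$mean_latency_ms,
    prediction_n_trials = pred$n_valid_trials,
    prediction_included = pred$included,
    prediction_class = pred$classification,
    dilation_difference_mm = dil$difference,
    dilation_n_appropriate = dil$n_valid_appropriate,
    dilation_n_inappropriate = dil$n_valid_inappropriate,
    dilation_included = dil$included,
    reach_latency_s = reach$mean_latency_s,
    reach_n_trials = reach$n_valid_trials,
    reach_included = reach$included,
    reach_class = reach$classification,
    vineland_motor = NA_real_
  ), 1L)
}

#' Score a cohort and run the statistics layer
#'
#' Applies [score_participant()] to every participant, then computes the
#' oriented pairwise-complete correlation matrix, the per-measure one-sample
#' t-tests against zero (on included participants, in the measures' raw
#' units), the per-measure predictive/reactive/excluded classification
#' counts, and each measure's skewness.
#'
#' @param cohort a `gz_cohort` (from [simulate_cohort()] or [read_cohort()]),
#'   or a list with `recordings`, `trials`, `reaches`.
#' @param params a [pipeline_params()].
#' @return A list `summary, oriented, correlations, ttests, classification,
#'   skewness`.
#' @export
score_cohort <- function(cohort, params = pipeline_params()) {
  pids <- names(cohort$recordings)
  trials_by <- split(as.data.frame(cohort$trials),
                     factor(cohort$trials$participant_id, levels = pids))
  reaches_by <- split(as.data.frame(cohort$reaches),
                      factor(cohort$reaches$participant_id, levels = pids))
  rows <- lapply(pids, function(pid) {
    score_participant(cohort$recordings[[pid]], trials_by[[pid]],
                      reaches_by[[pid]], params)
  })
  summary <- tibble::as_tibble(do.call(rbind, rows))
  measures <- c("prediction_latency_ms", "dilation_difference_mm",
                "reach_latency_s")
  if (any(!is.na(summary$vineland_motor))) {
    measures <- c(measures, "vineland_motor")
  }
  oriented <- orient_variables(summary)
  correlations <- correlation_matrix(oriented, measures)

  tt <- list()
  for (m in measures) {
    x <- summary[[m]]
    x <- x[!is.na(x)]
    if (length(x) >= 2 && sd(x) > 0) {
      row <- one_sample_t(x, mu = 0)
      row$measure <- m
      tt[[length(tt) + 1L]] <- row
    }
  }
  ttests <- if (length(tt) > 0) {
    dplyr::bind_rows(tt)[, c("measure", "kind", "t", "df", "p", "mean", "se", "n")]
  } else {
    tibble::tibble(measure = character(0), kind = character(0), t = numeric(0),
                   df = numeric(0), p = numeric(0), mean = numeric(0),
                   se = numeric(0), n = integer(0))
  }

  cls <- dplyr::bind_rows(
    dplyr::mutate(classify_cohort(summary$prediction_class),
                  measure = "prediction", .before = 1),
    dplyr::mutate(classify_cohort(ifelse(summary$dilation_included,
                                         ifelse(summary$dilation_difference_mm > 0,
                                                "predictive", "reactive"),
                                         "excluded")),
                  measure = "evaluation", .before = 1),
    dplyr::mutate(classify_cohort(summary$reach_class),
                  measure = "motor", .before = 1)
  )

  skew <- vapply(measures, function(m) {
    x <- summary[[m]]
    x <- x[!is.na(x)]
    if (length(x) >= 3 && sd(x) > 0) skewness(x) else NA_real_
  }, 1)

  list(summary = summary, oriented = oriented, correlations = correlations,
       ttests = ttests, classification = cls,
       skewness = tibble::tibble(measure = measures, skewness = unname(skew)))
}

#' Run the full pipeline on a cohort directory
#'
#' Reads `recording_<id>.tsv`, `trials.tsv`, and `reaches.tsv` from
#' `input_dir`, scores every participant, runs the statistics layer, and
#' writes `summary.tsv`, `correlations.tsv`, `ttests.tsv`,
#' `classification.tsv`, and `provenance.json` (parameters and versions
#' sufficient to rerun the result exactly) to `output_dir`. Output tables are
#' deterministic functions of the inputs and parameters.
#'
#' @param input_dir cohort directory (see [write_cohort()]).
#' @param output_dir output directory (created if needed).
#' @param params a [pipeline_params()].
#' @param config a [cohort_config()] supplying recording metadata for
#'   [read_cohort()].
#' @return The [score_cohort()] result, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         params = pipeline_params(),
                         config = cohort_config()) {
  cohort <- tryCatch(read_cohort(input_dir, config),
                     error = function(e) {
                       stop("pipeline aborted while loading inputs: ",
                            conditionMessage(e), call. = FALSE)
                     })
  res <- score_cohort(cohort, params)
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", output_dir, call. = FALSE)
  }
  readr::write_tsv(res$summary, file.path(output_dir, "summary.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(res$correlations, file.path(output_dir, "correlations.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(res$ttests, file.path(output_dir, "ttests.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(res$classification,
                   file.path(output_dir, "classification.tsv"),
                   na = "", progress = FALSE)
  prov <- list(
    package = "gazeval",
    version = as.character(packageVersion("gazeval")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input_dir = input_dir,
    params = .serialize_params(params),
    cohort_seed = config$seed
  )
  jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

.serialize_params <- function(params) {
  p <- unclass(params)
  p$filter <- unclass(p$filter)
  p$geometry <- unclass(p$geometry)
  p$bowl_aoi <- unclass(p$bowl_aoi)
  p$mouth_aoi <- unclass(p$mouth_aoi)
  p
}
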