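test_that("latent traits reproduce the configured correlation structure", {
  # independent traits: sample correlations near zero
  R0 <- diag(3)
  cfg <- cohort_config(n_participants = 10000, seed = 8,
                       trait_correlations = R0)
  th <- sample_traits(cfg)
  expect_lt(abs(cor(th$theta_pred_ms, th$theta_eval_mm)), 0.03)
  expect_lt(abs(cor(th$theta_pred_ms, th$theta_motor_ms)), 0.03)

  # configured oriented correlation 0.34: recovered on the oriented scale
  cfg <- cohort_config(n_participants = 10000, seed = 9)
  th <- sample_traits(cfg)
  expect_lt(abs(cor(-th$theta_pred_ms, th$theta_eval_mm) - 0.34), 0.03)
  expect_lt(abs(cor(-th$theta_pred_ms, -th$theta_motor_ms) - 0.33), 0.03)
  expect_lt(abs(mean(th$theta_pred_ms) - (-40)), 15)
  expect_lt(abs(sd(th$theta_eval_mm) - 0.14), 0.01)

  # determinism
  expect_identical(sample_traits(cfg), sample_traits(cfg))

  # a non-PSD matrix is rejected at configuration time
  Rbad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_config(trait_correlations = Rbad), "semidefinite")
})

test_that("noiseless prediction trials recover the embedded latency end-to-end", {
  cfg <- noiseless_config()
  for (L in c(-500, -100, 0, 200)) {
    set.seed(1)
    tr <- simulate_prediction_trial(L, cfg)
    fix <- detect_fixations(tr$samples, filter_params())
    s <- score_prediction_trial(fix, tr$annotation, default_aois()$bowl,
                                default_aois()$mouth, cfg$geometry)
    expect_identical(s$status, "scored")
    expect_lte(abs(s$latency_ms - L), 1000 / 60)
  }
})

test_that("jitter below the velocity threshold yields exactly two AOI fixations", {
  cfg <- noiseless_config(gaze_jitter_px = 2)
  set.seed(4)
  tr <- simulate_prediction_trial(-200, cfg)
  fix <- detect_fixations(tr$samples, filter_params())
  expect_identical(nrow(fix), 2L)
  bowl <- aoi_to_pixels(default_aois()$bowl, cfg$geometry)
  mouth <- aoi_to_pixels(default_aois()$mouth, cfg$geometry)
  expect_true(fix$centroid_x[1] >= bowl[["x0"]] && fix$centroid_x[1] < bowl[["x1"]])
  expect_true(fix$centroid_y[1] >= bowl[["y0"]] && fix$centroid_y[1] < bowl[["y1"]])
  expect_true(fix$centroid_y[2] >= mouth[["y0"]] && fix$centroid_y[2] < mouth[["y1"]])
})

test_that("full trial dropout makes participants unscorable", {
  cfg <- noiseless_config(dropout_prediction = 1)
  set.seed(2)
  scores <- lapply(1:6, function(k) {
    tr <- simulate_prediction_trial(-200, cfg)
    fix <- detect_fixations(tr$samples, filter_params())
    score_prediction_trial(fix, tr$annotation, default_aois()$bowl,
                           default_aois()$mouth, cfg$geometry)
  })
  agg <- aggregate_prediction(scores)
  expect_identical(agg$classification, "excluded")

  cfg <- noiseless_config(dropout_reach = 1)
  set.seed(2)
  rt <- simulate_reach_table(-380, cfg)
  expect_identical(aggregate_reach(rt)$classification, "excluded")
})

test_that("reach tables recover the latent motor latency exactly without noise", {
  cfg <- noiseless_config()
  set.seed(3)
  rt <- simulate_reach_table(-380, cfg)
  agg <- aggregate_reach(rt)
  expect_equal(agg$mean_latency_s, -0.38, tolerance = 1e-12)
  expect_identical(agg$n_valid_trials, 3L)
})

test_that("trait-to-score identifiability holds in the noiseless regime", {
  cfg <- noiseless_config(n_participants = 4, seed = 31)
  co <- simulate_cohort(cfg)
  res <- score_cohort(co)
  s <- res$summary[match(co$truth$participant_id, res$summary$participant_id), ]
  # prediction: within one sample period of the latent latency
  expect_true(all(abs(s$prediction_latency_ms - co$truth$theta_pred_ms)
                  <= 1000 / 60 + 1e-9))
  # reach: exact
  expect_equal(s$reach_latency_s, co$truth$theta_motor_ms / 1000,
               tolerance = 1e-12)
  # evaluation, scored on the raw trace: matches the latent amplitude times
  # the kernel's discrete window mean to numerical precision
  for (i in seq_len(4)) {
    rec <- co$recordings[[co$truth$participant_id[i]]]
    tri <- co$trials[co$trials$participant_id == co$truth$participant_id[i] &
                     co$trials$task == "evaluation", ]
    p <- combine_eyes(rec)
    ch <- vapply(seq_len(nrow(tri)), function(j) {
      score_dilation_trial(p, rec$samples$t, tri$grasp_t[j])$change
    }, 1)
    k_mean <- mean(pupil_response_kernel(
      (0:179) / 60, cfg$pupil_peak_s, cfg$pupil_shape))
    inapp <- tri$condition == "inappropriate"
    expect_equal(mean(ch[inapp]) - mean(ch[!inapp]),
                 co$truth$theta_eval_mm[i] * k_mean, tolerance = 1e-9)
  }
  # evaluation through the full cleaning chain: smoothing perturbs the
  # window means only marginally
  expect_equal(s$dilation_difference_mm, co$truth$theta_eval_mm,
               tolerance = 0.005)
})

test_that("cohorts regenerate identically from the same seed, including files", {
  cfg <- cohort_config(n_participants = 2, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(c1$recordings[["p001"]]$samples, c2$recordings[["p001"]]$samples)
  expect_equal(c1$trials, c2$trials)
  expect_equal(c1$reaches, c2$reaches)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(nrow(readr::read_tsv(file.path(d1, "truth.tsv"),
                                        show_col_types = FALSE)), 2L)

  # written cohorts read back equal to the in-memory original
  back <- read_cohort(d1, cfg)
  expect_equal(back$recordings[["p002"]]$samples,
               c1$recordings[["p002"]]$samples)
  expect_equal(as.data.frame(back$reaches), as.data.frame(c1$reaches))
})
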