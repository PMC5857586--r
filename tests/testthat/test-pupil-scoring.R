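test_that("eye combination averages valid eyes and propagates missingness", {
  s <- data.frame(t = 0:2 / 60, gaze_x = 1, gaze_y = 1,
                  pupil_left = c(3.0, NA, 3.4),
                  pupil_right = c(3.2, 4.0, 3.6),
                  valid_left = c(TRUE, FALSE, TRUE),
                  valid_right = c(TRUE, TRUE, FALSE))
  expect_equal(combine_eyes(s), c(3.1, 4.0, 3.4))
  s$valid_right[3] <- FALSE
  s$valid_left[3] <- FALSE
  expect_equal(combine_eyes(s)[3], NA_real_)
})

test_that("range clamp and step rejection honour their exact boundaries", {
  # 2.5 and 5.5 mm are inside the range; just outside is removed
  x <- c(2.5, 5.5, 2.4999, 5.5001)
  y <- clean_pupil(x, max_step_mm = 100, ma_window = 1, max_gap_samples = 1)
  expect_equal(y[1:2], c(2.5, 5.5))
  expect_true(all(is.na(y[3:4])))

  # a step of exactly 1 mm is retained; more than 1 mm is rejected
  y <- clean_pupil(c(3.0, 4.0, 3.0), ma_window = 1, max_gap_samples = 1)
  expect_equal(y, c(3.0, 4.0, 3.0))
  y <- clean_pupil(c(3.0, 4.2, 3.1), ma_window = 1, max_gap_samples = 1)
  expect_equal(y, c(3.0, NA, 3.1))

  # the reference is the previous retained value: a removed spike does not
  # cascade, and the sample after it is compared against the pre-spike value
  y <- clean_pupil(c(3.0, 6.0, 3.1), ma_window = 1)
  expect_equal(y, c(3.0, 3.05, 3.1))
})

test_that("only interior gaps shorter than 10 samples are interpolated", {
  gap_trace <- function(len) c(3.0, rep(NA, len), 4.0)
  y9 <- clean_pupil(gap_trace(9), ma_window = 1)
  expect_equal(y9, 3.0 + (0:10) / 10)
  y10 <- clean_pupil(gap_trace(10), ma_window = 1)
  expect_true(all(is.na(y10[2:11])))
  # edge gaps stay missing regardless of length
  y <- clean_pupil(c(NA, NA, 3.0, 3.1, NA), ma_window = 1)
  expect_true(all(is.na(y[c(1, 2, 5)])))
})

test_that("a constant trace is invariant under all four steps", {
  x <- rep(3.5, 50)
  expect_equal(clean_pupil(x), x)
  expect_equal(clean_pupil(rep(NA_real_, 20)), rep(NA_real_, 20))
})

test_that("the cleaning chain matches a hand-computed reference sequence", {
  x <- c(3.0, 3.2, 6.0, 3.4, 3.3, NA, NA, 3.1, 4.5, 3.2, 3.0, 3.1)
  # step 1 removes the 6.0; step 2 removes the 4.5 (|4.5 - 3.1| > 1);
  # step 3 fills the 1-sample and 2-sample gaps
  after_steps_1_to_3 <- c(3.0, 3.2, 3.3, 3.4, 3.3, 3.3 + (3.1 - 3.3) / 3,
                          3.3 + 2 * (3.1 - 3.3) / 3, 3.1, 3.15, 3.2, 3.0, 3.1)
  expect_equal(clean_pupil(x, ma_window = 1), after_steps_1_to_3)
  # step 4 is a truncated moving average (5 back, 4 forward) of that sequence
  cs <- cumsum(after_steps_1_to_3)
  want <- vapply(1:12, function(i) {
    a <- max(1, i - 5); b <- min(12, i + 4)
    (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1)
  }, 1)
  expect_equal(clean_pupil(x), want)
})

test_that("the step order is honoured: smoothing before interpolation differs", {
  x <- c(3.0, 3.2, 6.0, 3.4, 3.3, NA, NA, 3.1, 4.5, 3.2, 3.0, 3.1)
  # swapped order: steps 1, 2, 4, 3
  y <- x
  y[!is.na(y) & (y < 2.5 | y > 5.5)] <- NA
  y[!gazeval:::step_reject_cpp(y, 1.0)] <- NA
  swapped <- gazeval:::interpolate_gaps_cpp(
    gazeval:::moving_average_cpp(y, 5L, 4L), 10L)
  expect_false(isTRUE(all.equal(swapped, clean_pupil(x))))
})

test_that("cleaning stays within the range of the retained values", {
  set.seed(5)
  for (rep in 1:10) {
    x <- 3.5 + cumsum(rnorm(80, 0, 0.05))
    x[sample(80, 8)] <- NA
    x[sample(80, 2)] <- 7          # out-of-range spikes
    y <- clean_pupil(x)
    retained <- x[!is.na(x) & x >= 2.5 & x <= 5.5]
    expect_gte(min(y, na.rm = TRUE), min(retained) - 1e-12)
    expect_lte(max(y, na.rm = TRUE), max(retained) + 1e-12)
  }
})

test_that("dilation scoring windows and validity rules are exact", {
  sr <- 60
  t <- (0:299) / sr
  # flat trace: zero change
  s <- score_dilation_trial(rep(3.5, 300), t, grasp_t = 1.5)
  expect_true(s$valid)
  expect_equal(s$change, 0)

  # baseline 3.5, analysis 3.6: +0.1 mm
  x <- c(rep(3.5, 90), rep(3.6, 210))
  s <- score_dilation_trial(x, t, grasp_t = 1.5)
  expect_equal(s$baseline_mean, 3.5)
  expect_equal(s$analysis_mean, 3.6)
  expect_equal(s$change, 0.1)

  # a grasp too early for the baseline is invalid with a reason
  s <- score_dilation_trial(x, t, grasp_t = 0.5)
  expect_false(s$valid)
  expect_identical(s$reason, "window_outside_trace")

  # windows must each retain at least half their samples
  x2 <- rep(3.5, 300)
  x2[91:240] <- NA  # analysis window: 30/180 retained
  s <- score_dilation_trial(x2, t, grasp_t = 1.5)
  expect_false(s$valid)
  expect_identical(s$reason, "insufficient_valid_samples")
  x3 <- rep(3.5, 300)
  x3[91:170] <- NA  # analysis window: 100/180 retained
  expect_true(score_dilation_trial(x3, t, grasp_t = 1.5)$valid)
})

test_that("a noiseless generated trial equals the kernel's discrete window mean", {
  cfg <- noiseless_config()
  set.seed(7)
  tr <- simulate_evaluation_trial(0.1, "inappropriate", cfg)
  p <- combine_eyes(tr$samples)
  s <- score_dilation_trial(p, tr$samples$t, tr$annotation$grasp_t)
  k <- pupil_response_kernel(tr$samples$t - tr$annotation$grasp_t,
                             cfg$pupil_peak_s, cfg$pupil_shape)
  in_analysis <- tr$samples$t >= tr$annotation$grasp_t &
    tr$samples$t < tr$annotation$grasp_t + 3
  expect_equal(s$change, 0.1 * mean(k[in_analysis]), tolerance = 1e-6)
  # and the discrete mean agrees with the continuous unit normalization
  expect_equal(mean(k[in_analysis]), 1, tolerance = 0.01)
  # an appropriate trial under zero amplitude scores ~0
  tr0 <- simulate_evaluation_trial(0.1, "appropriate", cfg)
  s0 <- score_dilation_trial(combine_eyes(tr0$samples), tr0$samples$t,
                             tr0$annotation$grasp_t)
  expect_equal(s0$change, 0, tolerance = 1e-12)
})

test_that("participant aggregation needs three valid trials per condition", {
  trial <- function(cond, change, valid = TRUE) {
    list(trial_id = "x", condition = cond, change = change, valid = valid)
  }
  trials <- list(trial("appropriate", 0.00), trial("appropriate", 0.01),
                 trial("appropriate", -0.01), trial("inappropriate", 0.06),
                 trial("inappropriate", 0.07), trial("inappropriate", 0.05))
  agg <- aggregate_dilation(trials)
  expect_true(agg$included)
  expect_equal(agg$difference, 0.06)

  agg <- aggregate_dilation(trials[-4])   # only 2 valid inappropriate
  expect_false(agg$included)
  expect_true(is.na(agg$difference))

  agg <- aggregate_dilation(c(trials[1:3], list(
    trial("inappropriate", 0.00), trial("inappropriate", 0.01),
    trial("inappropriate", -0.01))))
  expect_equal(agg$difference, 0)
})
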