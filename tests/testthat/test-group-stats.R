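test_that("orientation flips latencies, keeps dilation, and is an involution", {
  tab <- tibble::tibble(prediction_latency_ms = c(-379, 100),
                        dilation_difference_mm = c(0.063, -0.02),
                        reach_latency_s = c(-0.38, 0.2),
                        vineland_motor = c(NA, 1))
  o <- orient_variables(tab)
  expect_equal(o$prediction_latency_ms, c(379, -100))
  expect_equal(o$dilation_difference_mm, c(0.063, -0.02))
  expect_equal(o$reach_latency_s, c(0.38, -0.2))
  oo <- orient_variables(o)
  expect_equal(as.data.frame(oo), as.data.frame(tab),
               ignore_attr = "orientation")
  expect_named(attr(o, "orientation"),
               c("prediction_latency_ms", "dilation_difference_mm",
                 "reach_latency_s", "vineland_motor"))
})

test_that("t statistics match closed-form hand computations", {
  # one-sample: {1, 2, 3} vs 0 -> t = 2 / (1 / sqrt(3)) = 2 sqrt(3), df 2
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-9)
  expect_equal(r$mean, 2)
  expect_equal(r$se, 1 / sqrt(3), tolerance = 1e-9)

  # symmetric about mu: t = 0, p = 1
  r <- one_sample_t(c(-1, 1, -2, 2), mu = 0)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # paired: differences {1, 1, 1, 3} -> mean 1.5, sd 1, t = 3, df 3
  r <- paired_t(c(2, 3, 4, 8), c(1, 2, 3, 5))
  expect_equal(r$t, 3, tolerance = 1e-9)
  expect_equal(r$df, 3)
  expect_equal(r$p, 2 * pt(-3, 3), tolerance = 1e-9)

  # pairwise deletion before the paired test
  r <- paired_t(c(2, 3, NA, 4, 8), c(1, 2, 5, NA, 5))
  expect_equal(r$n, 3)

  # pooled two-sample: {1,2,3} vs {2,3,4} -> t = -sqrt(3/2), df 4
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(1.5), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-sqrt(1.5), 4), tolerance = 1e-9)
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)

  # degenerate inputs error instead of returning infinities
  expect_error(one_sample_t(c(2, 2, 2)), "zero variance")
  expect_error(one_sample_t(c(1)), "at least 2")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero variance")
  expect_error(paired_t(c(1, NA), c(1, 2)), "complete pairs")
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("one-sample t rejects at its nominal rate under the null", {
  set.seed(99)
  rejections <- 0L
  for (i in 1:1000) {
    r <- one_sample_t(rnorm(80))
    if (abs(r$t) > qt(0.975, 79)) rejections <- rejections + 1L
  }
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})

test_that("pairwise-complete correlations match a naive per-pair recomputation", {
  set.seed(42)
  n <- 60
  tab <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$b <- tab$b + 0.5 * tab$a
  for (v in names(tab)) tab[[v]][sample(n, 12)] <- NA
  cm <- correlation_matrix(tab, c("a", "b", "c"))
  for (i in seq_len(nrow(cm))) {
    v1 <- cm$var1[i]; v2 <- cm$var2[i]
    ok <- !is.na(tab[[v1]]) & !is.na(tab[[v2]])
    expect_identical(cm$n[i], sum(ok))
    if (v1 == v2) {
      expect_equal(cm$r[i], 1)
    } else {
      x <- tab[[v1]][ok]; y <- tab[[v2]][ok]
      r_naive <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(cm$r[i], r_naive, tolerance = 1e-9)
      t_naive <- r_naive * sqrt((sum(ok) - 2) / (1 - r_naive^2))
      expect_equal(cm$p[i], 2 * pt(-abs(t_naive), sum(ok) - 2),
                   tolerance = 1e-9)
    }
  }
})

test_that("correlation extremes and degenerate cells behave", {
  tab <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3), z = c(3, 2, 1))
  cm <- correlation_matrix(tab, c("x", "y", "z"))
  get <- function(a, b) cm[cm$var1 == a & cm$var2 == b, ]
  expect_equal(get("x", "y")$r, 1)
  expect_equal(get("x", "z")$r, -1)
  expect_equal(get("x", "x")$r, 1)

  tab$w <- c(1, NA, NA)
  cm <- correlation_matrix(tab, c("x", "w"))
  expect_false(cm$computable[cm$var1 == "x" & cm$var2 == "w"])
})

test_that("negating one variable negates its correlations, |r| unchanged", {
  set.seed(17)
  tab <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  tab$b <- tab$b + tab$a
  c1 <- correlation_matrix(tab, c("a", "b"))
  tab$a <- -tab$a
  c2 <- correlation_matrix(tab, c("a", "b"))
  off1 <- c1[c1$var1 != c1$var2, ]
  off2 <- c2[c2$var1 != c2$var2, ]
  expect_equal(off2$r, -off1$r)
  expect_equal(abs(off2$r), abs(off1$r))
})

test_that("classification counts partition the cohort with both percentage bases", {
  cls <- classify_cohort(c("predictive", "predictive", "predictive",
                           "reactive", "excluded"))
  expect_equal(cls$n, c(3L, 1L, 1L))
  expect_equal(cls$pct_total, c(60, 20, 20))
  expect_equal(cls$pct_included[1], 75)
  expect_equal(cls$pct_included[2], 25)
  expect_true(is.na(cls$pct_included[3]))

  all_ex <- classify_cohort(rep("excluded", 4))
  expect_true(all(is.na(all_ex$pct_included[1:2])))
  expect_equal(sum(all_ex$n), 4L)
})

test_that("adjusted skewness matches its closed form and antisymmetry", {
  x <- c(1, 2, 10)
  n <- 3
  m <- mean(x)
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
  want <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(skewness(x), want, tolerance = 1e-9)
  expect_gt(skewness(x), 0)
  expect_equal(skewness(-x), -skewness(x), tolerance = 1e-12)
  expect_equal(skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_error(skewness(c(1, 2)), "at least 3")
  expect_error(skewness(c(2, 2, 2)), "zero variance")
})
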