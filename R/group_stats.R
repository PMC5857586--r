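#' Orient measures so that high performance is positive
#'
#' For the correlation analysis all variables are transformed so that better
#' performance is marked by positive values: prediction and reach latencies
#' are negated (more predictive, i.e. more negative latency, becomes more
#' positive), while the pupil dilation difference already points the right
#' way (larger surprise positive) and is left unchanged, as is the optional
#' external motor covariate. The orientation map is attached as the
#' `"orientation"` attribute.
#'
#' @param summaries participant summary table (see [score_cohort()]).
#' @return The oriented table, with an `"orientation"` attribute giving the
#'   sign applied per measure.
#' @export
orient_variables <- function(summaries) {
  orientation <- c(prediction_latency_ms = -1, dilation_difference_mm = 1,
                   reach_latency_s = -1, vineland_motor = 1)
  out <- summaries
  for (v in names(orientation)) {
    if (v %in% names(out)) out[[v]] <- orientation[[v]] * out[[v]]
  }
  attr(out, "orientation") <- orientation[names(orientation) %in% names(out)]
  out
}

.as_ttest <- function(kind, ht, mean, se, n) {
  tibble::tibble(kind = kind, t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 mean = mean, se = se, n = n)
}

#' One-sample t-test
#'
#' Tests the mean of `values` against `mu`; `t = (mean - mu) / (sd / sqrt(n))`
#' with `n - 1` degrees of freedom, two-sided p.
#'
#' @param values numeric vector (`NA` dropped).
#' @param mu null-hypothesis mean.
#' @return One-row tibble `kind, t, df, p, mean, se, n`.
#' @export
one_sample_t <- function(values, mu = 0) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("one_sample_t needs at least 2 observations", call. = FALSE)
  if (sd(x) == 0) stop("one_sample_t: zero variance", call. = FALSE)
  ht <- t.test(x, mu = mu)
  .as_ttest("one_sample", ht, mean(x), sd(x) / sqrt(length(x)), length(x))
}

#' Paired (dependent) t-test
#'
#' Drops pairs with either side missing, then runs a one-sample t-test on the
#' within-pair differences `x - y`. Exactly equal vectors have zero-variance
#' differences and raise an error rather than returning t = 0.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return One-row tibble `kind, t, df, p, mean, se, n` (`mean` is the mean
#'   difference, `n` the number of complete pairs).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2) stop("paired_t needs at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) stop("paired_t: zero variance of differences", call. = FALSE)
  ht <- t.test(d, mu = 0)
  out <- .as_ttest("paired", ht, mean(d), sd(d) / sqrt(length(d)), length(d))
  out
}

#' Two-sample t-test
#'
#' Pooled-variance Student t by default (df = n_a + n_b - 2, matching the
#' integer degrees of freedom convention of the reporting style this package
#' reproduces); Welch's unequal-variance test is available via
#' `var_equal = FALSE`.
#'
#' @param a,b numeric vectors (`NA` dropped).
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return One-row tibble `kind, t, df, p, mean, se, n` (`mean` is the mean
#'   difference `a - b`).
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("two_sample_t needs at least 2 observations per group", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    stop("two_sample_t: both groups have zero variance", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = var_equal)
  se <- unname((mean(a) - mean(b)) / ht$statistic)
  if (!is.finite(se)) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  .as_ttest("two_sample", ht, mean(a) - mean(b), se, length(a) + length(b))
}

#' Pairwise-complete Pearson correlation matrix
#'
#' For every pair of variables, Pearson's r over the rows where both are
#' present (pairwise deletion, so n varies cell to cell), with the two-sided
#' p from `t = r * sqrt((n - 2) / (1 - r^2))`. Cells with fewer than 3
#' complete pairs (or a constant variable) are marked not computable.
#'
#' @param data data frame containing `variables`.
#' @param variables character vector of column names to correlate.
#' @return A tibble with one row per unordered pair (including the diagonal):
#'   `var1, var2, r, n, p, computable`.
#' @export
correlation_matrix <- function(data, variables) {
  stopifnot(all(variables %in% names(data)))
  pairs <- list()
  for (i in seq_along(variables)) {
    for (j in i:length(variables)) {
      v1 <- variables[i]; v2 <- variables[j]
      x <- data[[v1]]; y <- data[[v2]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (i == j) {
        row <- tibble::tibble(var1 = v1, var2 = v2, r = 1, n = n,
                              p = NA_real_, computable = n >= 3)
      } else if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        row <- tibble::tibble(var1 = v1, var2 = v2, r = NA_real_, n = n,
                              p = NA_real_, computable = FALSE)
      } else {
        ht <- cor.test(x[ok], y[ok], method = "pearson")
        row <- tibble::tibble(var1 = v1, var2 = v2,
                              r = unname(ht$estimate), n = n,
                              p = ht$p.value, computable = TRUE)
      }
      pairs[[length(pairs) + 1L]] <- row
    }
  }
  dplyr::bind_rows(pairs)
}

#' Cohort classification counts
#'
#' Counts and percentages of predictive, reactive, and excluded participants:
#' percentages both of the full cohort and (for predictive/reactive) of the
#' included participants. With an all-excluded cohort the included-base
#' percentages are undefined and reported as `NA`.
#'
#' @param classifications character vector of per-participant classifications
#'   (`"predictive"`, `"reactive"`, `"excluded"`).
#' @return A tibble `classification, n, pct_total, pct_included`.
#' @export
classify_cohort <- function(classifications) {
  lev <- c("predictive", "reactive", "excluded")
  stopifnot(all(classifications %in% lev))
  n_total <- length(classifications)
  counts <- vapply(lev, function(l) sum(classifications == l), 1L)
  n_included <- counts[["predictive"]] + counts[["reactive"]]
  tibble::tibble(
    classification = lev,
    n = unname(counts),
    pct_total = if (n_total > 0) unname(100 * counts / n_total) else rep(0, 3),
    pct_included = c(
      if (n_included > 0) 100 * counts[["predictive"]] / n_included else NA_real_,
      if (n_included > 0) 100 * counts[["reactive"]] / n_included else NA_real_,
      NA_real_
    )
  )
}

#' Adjusted Fisher-Pearson skewness
#'
#' The sample-size-adjusted standardized third moment
#' `g1 * sqrt(n (n - 1)) / (n - 2)` (the coefficient most statistics software
#' reports when screening distributional assumptions).
#'
#' @param values numeric vector (`NA` dropped), length at least 3.
#' @return Skewness coefficient.
#' @export
skewness <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) stop("skewness needs at least 3 observations", call. = FALSE)
  if (sd(x) == 0) stop("skewness: zero variance", call. = FALSE)
  e1071::skewness(x, type = 2)
}
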