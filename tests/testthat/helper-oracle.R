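# Independent brute-force implementations used as oracles. These follow the
# same documented contract as the package but are written as naive
# per-sample/per-run loops with no shared code.

oracle_gaze_ok <- function(df) {
  (df$valid_left | df$valid_right) & is.finite(df$gaze_x) & is.finite(df$gaze_y)
}

oracle_velocities <- function(df, window) {
  n <- nrow(df)
  ok <- oracle_gaze_ok(df)
  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    before <- (i - window):(i - 1)
    after <- i:(i + window - 1)
    if (min(before) < 1 || max(after) > n) next
    if (any(!ok[c(before, after)])) next
    bx <- mean(df$gaze_x[before]); by <- mean(df$gaze_y[before])
    ax <- mean(df$gaze_x[after]); ay <- mean(df$gaze_y[after])
    v[i] <- sqrt((ax - bx)^2 + (ay - by)^2)
  }
  v
}

oracle_fixations <- function(df, params) {
  n <- nrow(df)
  ok <- oracle_gaze_ok(df)
  gx <- df$gaze_x
  gy <- df$gaze_y
  v <- oracle_velocities(df, params$window)
  core <- !is.na(v) & v < params$velocity_threshold
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      n_samples = integer(0))
  if (!any(core)) return(empty)

  # core runs by explicit scanning
  run_s <- integer(0); run_e <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!core[i]) { i <- i + 1L; next }
    s <- i
    while (i <= n && core[i]) i <- i + 1L
    run_s <- c(run_s, s); run_e <- c(run_e, i - 1L)
  }
  k <- length(run_s)

  # boundary assignment: step outward while within the distance threshold of
  # the core run's centroid; backward first, never crossing the previous
  # run's extended samples; forward never crossing the next run's core start
  ext_s <- integer(k); ext_e <- integer(k)
  for (j in seq_len(k)) {
    cx <- mean(gx[run_s[j]:run_e[j]])
    cy <- mean(gy[run_s[j]:run_e[j]])
    lower <- if (j > 1L) ext_e[j - 1L] + 1L else 1L
    p <- run_s[j] - 1L
    while (p >= lower && ok[p] &&
           sqrt((gx[p] - cx)^2 + (gy[p] - cy)^2) < params$distance_threshold) {
      p <- p - 1L
    }
    ext_s[j] <- p + 1L
    upper <- if (j < k) run_s[j + 1L] - 1L else n
    p <- run_e[j] + 1L
    while (p <= upper && ok[p] &&
           sqrt((gx[p] - cx)^2 + (gy[p] - cy)^2) < params$distance_threshold) {
      p <- p + 1L
    }
    ext_e[j] <- p - 1L
  }

  # merge: centroid distance below threshold and fewer than `window`
  # invalid-gaze samples in between
  groups <- list()
  cur <- ext_s[1L]:ext_e[1L]
  if (k > 1L) {
    for (j in 2L:k) {
      nxt <- ext_s[j]:ext_e[j]
      gap <- setdiff((max(cur) + 1L):(min(nxt) - 1L), integer(0))
      if (min(nxt) - max(cur) <= 1L) gap <- integer(0)
      d <- sqrt((mean(gx[cur]) - mean(gx[nxt]))^2 +
                (mean(gy[cur]) - mean(gy[nxt]))^2)
      if (d < params$distance_threshold && sum(!ok[gap]) < params$window) {
        cur <- c(cur, nxt)
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- nxt
      }
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups <- groups[vapply(groups, length, 1L) >= params$min_duration]
  if (length(groups) == 0) return(empty)
  data.frame(
    onset_t = vapply(groups, function(m) df$t[min(m)], 1),
    offset_t = vapply(groups, function(m) df$t[max(m)], 1),
    centroid_x = vapply(groups, function(m) mean(gx[m]), 1),
    centroid_y = vapply(groups, function(m) mean(gy[m]), 1),
    n_samples = vapply(groups, length, 1L)
  )
}
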