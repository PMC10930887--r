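# Independent brute-force oracles, deliberately naive (explicit loops,
# direct summation) and kept free of any package internals.

# centered moving average with truncated edges and NA exclusion
oracle_moving_average <- function(d, window) {
  n <- length(d)
  left <- window %/% 2
  right <- window - left - 1
  out <- numeric(n)
  for (x in seq_len(n)) {
    vals <- c()
    for (j in max(1, x - left):min(n, x + right))
      if (!is.na(d[j])) vals <- c(vals, d[j])
    out[x] <- if (length(vals)) sum(vals) / length(vals) else NA_real_
  }
  out
}

# exhaustive per-position evaluation of the side-window peak rule,
# including run collapse to the smoothed argmax (leftmost tie)
oracle_detect_peaks <- function(s, ref, side) {
  n <- length(s)
  cand <- logical(n)
  for (x in seq_len(n)) {
    if (is.na(s[x])) next
    lv <- c(); rv <- c()
    for (j in seq(x - side, x - 1))
      if (j >= 1 && !is.na(ref[j])) lv <- c(lv, ref[j])
    for (j in seq(x + 1, x + side))
      if (j <= n && !is.na(ref[j])) rv <- c(rv, ref[j])
    cand[x] <- length(lv) >= side / 2 && length(rv) >= side / 2 &&
      s[x] > mean(lv) && s[x] > mean(rv)
  }
  peaks <- integer(0)
  x <- 1
  while (x <= n) {
    if (cand[x]) {
      x2 <- x
      while (x2 < n && cand[x2 + 1]) x2 <- x2 + 1
      run <- x:x2
      best <- run[1]
      for (j in run) if (s[j] > s[best]) best <- j
      peaks <- c(peaks, best)
      x <- x2 + 1
    } else x <- x + 1
  }
  peaks
}

# random front-like profiles: baseline + bumps + noise, occasional NAs
random_profile <- function(n) {
  d <- rep(stats::runif(1, 0, 50), n)
  for (k in seq_len(stats::rpois(1, 3))) {
    x0 <- stats::runif(1, 1, n)
    amp <- stats::runif(1, 5, 60)
    sig <- stats::runif(1, 3, 30)
    d <- d + amp * exp(-(seq_len(n) - x0)^2 / (2 * sig^2))
  }
  d <- d + stats::rnorm(n, 0, stats::runif(1, 0, 3))
  if (stats::runif(1) < 0.3)
    d[sample.int(n, size = ceiling(n * 0.02))] <- NA
  d
}

# rectangular band mask: epithelium rows 1..(interface + depth per column)
band_mask <- function(height, width, interface_row, depth) {
  depth <- rep_len(depth, width)
  outer(seq_len(height), interface_row + depth, "<=")
}
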