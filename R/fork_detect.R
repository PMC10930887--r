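#' Detect invasive-fork peaks on a smoothed front profile
#'
#' A position `x` is a peak candidate when the smoothed profile value at
#' `x` strictly exceeds BOTH flanking side averages of width
#' `side_window`: the mean of the comparison profile over the
#' `side_window` positions immediately left of `x` and, separately, the
#' `side_window` positions immediately right of `x` (the position itself
#' is excluded). By default the side averages are taken on the RAW
#' (unsmoothed) profile, the literal reading of comparing flanking signal
#' to the smoothed value; `compare = "smoothed"` flips both to the
#' smoothed profile. Side windows truncate at the profile edges but must
#' retain at least `side_window / 2` valid positions, otherwise the
#' position cannot qualify. Contiguous runs of qualifying positions are
#' collapsed to a single peak at the run's argmax of the smoothed profile
#' (leftmost on ties).
#'
#' @param smoothed smoothed [front_profile] (see [smooth_profile()]).
#' @param raw raw [front_profile] of the same length.
#' @param side_window flank width in pixels (default 40).
#' @param compare `"raw"` (default) or `"smoothed"`: which profile the
#'   side averages are computed on.
#' @return Integer vector of peak positions (1-based profile indices),
#'   possibly empty.
#' @export
detect_peaks <- function(smoothed, raw, side_window = 40L,
                         compare = c("raw", "smoothed")) {
  compare <- match.arg(compare)
  stopifnot(inherits(smoothed, "front_profile"), inherits(raw, "front_profile"))
  n <- length(smoothed$depth)
  if (length(raw$depth) != n)
    stop("smoothed and raw profiles differ in length")
  side_window <- as.integer(side_window)
  if (side_window < 1L) stop("side_window must be >= 1")
  if (n < side_window)
    stop("profile (", n, ") shorter than side_window (", side_window, ")")
  s <- smoothed$depth
  ref <- if (compare == "raw") raw$depth else s
  v <- !is.na(ref)
  r0 <- ifelse(v, ref, 0)
  cs <- c(0, cumsum(r0))
  cv <- c(0, cumsum(as.numeric(v)))
  x <- seq_len(n)
  # left flank (x - side_window) .. (x - 1), truncated at 1
  llo <- pmax(x - side_window, 1L); lhi <- x - 1L
  lsum <- ifelse(lhi >= llo, cs[lhi + 1L] - cs[llo], 0)
  lcnt <- ifelse(lhi >= llo, cv[lhi + 1L] - cv[llo], 0)
  # right flank (x + 1) .. (x + side_window), truncated at n
  rlo <- x + 1L; rhi <- pmin(x + side_window, n)
  rsum <- ifelse(rhi >= rlo, cs[rhi + 1L] - cs[rlo], 0)
  rcnt <- ifelse(rhi >= rlo, cv[rhi + 1L] - cv[rlo], 0)
  min_valid <- side_window / 2
  cand <- !is.na(s) &
    lcnt >= min_valid & rcnt >= min_valid &
    s > lsum / pmax(lcnt, 1) & s > rsum / pmax(rcnt, 1)
  collapse_runs(cand, s)
}

# collapse contiguous TRUE runs to the run argmax of `score` (leftmost tie)
collapse_runs <- function(cand, score) {
  if (!any(cand)) return(integer(0))
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    peaks <- c(peaks, idx[which.max(score[idx])])
  }
  peaks
}

#' Assign half-open intervals to detected peaks
#'
#' Boundaries between consecutive peaks are the floor midpoints of the
#' peak positions; the first interval starts at position 1 and the last
#' ends past the profile end, so the intervals partition the profile.
#' (Peaks emitted by [detect_peaks()] are never adjacent integers, since
#' contiguous qualifying runs are collapsed first.)
#'
#' @param peaks sorted integer vector of 1-based peak positions.
#' @param profile_length profile length in pixels.
#' @return `data.frame` with columns `peak_x`, `start`, `end`; each
#'   interval is `[start, end)` in 1-based coordinates (`end` exclusive).
#'   Empty input gives an empty data.frame.
#' @export
assign_intervals <- function(peaks, profile_length) {
  peaks <- as.integer(peaks)
  if (!length(peaks))
    return(data.frame(peak_x = integer(0), start = integer(0),
                      end = integer(0)))
  if (is.unsorted(peaks, strictly = TRUE)) stop("peaks must be sorted ascending")
  if (any(peaks < 1L | peaks > profile_length))
    stop("peak positions outside profile")
  k <- length(peaks)
  bounds <- if (k > 1L) (peaks[-k] + peaks[-1L]) %/% 2L else integer(0)
  data.frame(peak_x = peaks,
             start = c(1L, bounds),
             end = c(bounds, profile_length + 1L))
}

#' Depth of one invasive fork
#'
#' With the default `reference = "initial_interface"` the fork depth is
#' the maximum raw depth over the fork's interval — depths are already
#' measured from the fixed frame-0 interface line. With
#' `reference = "local_baseline"` the smaller of the two
#' interval-boundary depths is subtracted, measuring the fork's
#' prominence above the local front.
#'
#' @param interval one row of the [assign_intervals()] output (list or
#'   single-row data.frame with `start`, `end`).
#' @param raw raw [front_profile].
#' @param reference `"initial_interface"` (default) or `"local_baseline"`.
#' @return Depth in pixels.
#' @export
fork_depth <- function(interval, raw,
                       reference = c("initial_interface", "local_baseline")) {
  reference <- match.arg(reference)
  start <- interval$start; end <- interval$end
  if (start < 1L || end > length(raw$depth) + 1L || start >= end)
    stop("interval outside profile")
  d <- raw$depth[start:(end - 1L)]
  if (all(is.na(d))) stop("all-invalid interval: no depth defined")
  peak <- max(d, na.rm = TRUE)
  if (reference == "initial_interface") return(peak)
  b1 <- raw$depth[start]; b2 <- raw$depth[end - 1L]
  base <- suppressWarnings(min(c(b1, b2), na.rm = TRUE))
  if (!is.finite(base)) base <- min(d, na.rm = TRUE)
  peak - base
}

#' Call invasive forks on one frame's profile
#'
#' Convenience wrapper: smooths the raw profile, detects peaks, assigns
#' intervals, and measures the depth of each fork.
#'
#' @param raw raw [front_profile].
#' @param window moving-average smoothing width (default 20).
#' @param side_window peak-rule flank width (default 40).
#' @param reference depth reference, see [fork_depth()].
#' @param compare side-average profile, see [detect_peaks()].
#' @return `data.frame` with columns `frame`, `peak_x`, `start_x`,
#'   `end_x`, `depth_px` (zero rows when no peaks qualify).
#' @export
call_forks <- function(raw, window = 20L, side_window = 40L,
                       reference = c("initial_interface", "local_baseline"),
                       compare = c("raw", "smoothed")) {
  reference <- match.arg(reference)
  compare <- match.arg(compare)
  sm <- smooth_profile(raw, window = window)
  peaks <- detect_peaks(sm, raw, side_window = side_window, compare = compare)
  iv <- assign_intervals(peaks, length(raw$depth))
  depth <- vapply(seq_len(nrow(iv)), function(i)
    fork_depth(iv[i, ], raw, reference = reference), numeric(1))
  data.frame(frame = rep(raw$frame_index, nrow(iv)),
             peak_x = iv$peak_x, start_x = iv$start, end_x = iv$end,
             depth_px = if (nrow(iv)) depth else numeric(0))
}

#' Compare two fork-depth distributions
#'
#' Welch two-sample t-test as the primary statistic, with a Mann-Whitney
#' (Wilcoxon rank-sum) test reported alongside and descriptive quantiles
#' for both samples. With fewer than 2 observations in either sample only
#' the descriptive output is returned (test statistics `NA`).
#'
#' @param depths_a,depths_b numeric vectors of fork depths (pixels).
#' @return List with `t_p_value`, `t_statistic`, `wilcox_p_value`,
#'   `stars`, and a `quantiles` matrix (rows = samples).
#' @export
compare_depth_distributions <- function(depths_a, depths_b) {
  if (!length(depths_a) || !length(depths_b))
    stop("both samples must be non-empty")
  qs <- rbind(a = stats::quantile(depths_a, c(0, .25, .5, .75, 1)),
              b = stats::quantile(depths_b, c(0, .25, .5, .75, 1)))
  if (length(depths_a) < 2L || length(depths_b) < 2L)
    return(list(t_p_value = NA_real_, t_statistic = NA_real_,
                wilcox_p_value = NA_real_, stars = NA_character_,
                n = c(a = length(depths_a), b = length(depths_b)),
                quantiles = qs))
  tt <- stats::t.test(depths_a, depths_b)
  wt <- suppressWarnings(stats::wilcox.test(depths_a, depths_b))
  list(t_p_value = tt$p.value, t_statistic = unname(tt$statistic),
       wilcox_p_value = wt$p.value, stars = p_stars(tt$p.value),
       n = c(a = length(depths_a), b = length(depths_b)),
       quantiles = qs)
}
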