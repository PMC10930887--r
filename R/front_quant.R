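#' Invasion-front profile
#'
#' Quasi-1D representation of the invasion front at one time point: for
#' each position `x` along the initial interface, the depth `d(x)` (in
#' pixels) of the furthest epithelium-labeled pixel beyond the fixed
#' frame-0 interface line. Positions where the epithelium does not reach
#' the interface are invalid and stored as `NA` (never coerced to zero).
#'
#' @param depth numeric vector of depths; `NA` marks invalid positions.
#' @param frame_index integer frame index (0-based to match file order
#'   conventions).
#' @param interface_length number of interface positions spanned by the
#'   epithelial monolayer at frame 0 (L0, pixels).
#' @return Object of class `front_profile`.
#' @export
front_profile <- function(depth, frame_index = 0L, interface_length = length(depth)) {
  if (!length(depth)) stop("empty profile")
  if (interface_length <= 0) stop("interface_length must be > 0")
  structure(list(depth = as.numeric(depth),
                 frame_index = as.integer(frame_index),
                 interface_length = interface_length),
            class = "front_profile")
}

#' @export
length.front_profile <- function(x) length(x$depth)

#' @export
print.front_profile <- function(x, ...) {
  ok <- !is.na(x$depth)
  cat(sprintf("front_profile: frame %d, %d positions (%d valid), depth range [%s, %s] px\n",
              x$frame_index, length(x$depth), sum(ok),
              if (any(ok)) format(min(x$depth[ok])) else "NA",
              if (any(ok)) format(max(x$depth[ok])) else "NA"))
  invisible(x)
}

#' Segment the labeled epithelium in every frame of a stack
#'
#' Produces one binary mask per frame (epithelium = `TRUE`) by global
#' thresholding followed by morphological cleanup: holes in the epithelium
#' are filled and connected foreground objects smaller than
#' `min_object_px` are removed.
#'
#' @param stack an [image_stack].
#' @param threshold_method `"otsu"` (default, Otsu's method per frame) or
#'   `"fixed"` (use `threshold`).
#' @param threshold fixed intensity cutoff in \[0, 1\], for
#'   `threshold_method = "fixed"`.
#' @param min_object_px connected components smaller than this are removed
#'   (default 64 px, i.e. debris well below one cell footprint at 10x).
#' @param fill_holes fill enclosed background holes inside the epithelium.
#' @return List of logical matrices, one per frame.
#' @export
mask_from_stack <- function(stack, threshold_method = c("otsu", "fixed"),
                            threshold = NULL, min_object_px = 64,
                            fill_holes = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_method <- match.arg(threshold_method)
  lapply(seq_along(stack$frames), function(i) {
    f <- stack$frames[[i]]
    if (diff(range(f)) == 0)
      stop("degenerate segmentation: frame ", i, " is uniform")
    th <- if (threshold_method == "otsu") {
      g <- (f - min(f)) / diff(range(f))
      min(f) + EBImage::otsu(g) * diff(range(f))
    } else {
      if (is.null(threshold)) stop("fixed thresholding needs `threshold`")
      threshold
    }
    m <- f > th
    if (all(m) || !any(m))
      stop("degenerate segmentation: frame ", i,
           " thresholds to all-", if (all(m)) "foreground" else "background")
    if (fill_holes) m <- EBImage::fillHull(m) > 0
    if (min_object_px > 0) {
      lab <- EBImage::bwlabel(m)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_object_px)
      m <- matrix(lab %in% keep, nrow(m), ncol(m))
    }
    if (!any(m)) stop("degenerate segmentation: frame ", i,
                      " empty after cleanup")
    m
  })
}

#' Extract a 1D front profile from a binary epithelium mask
#'
#' For each interface column `x`, the depth is the furthest epithelium
#' pixel beyond the fixed interface row, minus the interface row. Columns
#' whose epithelium does not reach the interface row are invalid (`NA`).
#' Detached objects lying ahead of the front (cells that have separated
#' from the monolayer) are excluded from the depth profile by default so
#' that `d(x)` stays single-valued per column; they still count toward
#' area-based statistics (see [normalized_extent()]).
#'
#' @param mask logical matrix, rows in the invasion direction.
#' @param interface_row row index (1-based) of the initial
#'   epithelium-stroma interface: the last epithelial row at frame 0.
#' @param frame_index integer frame index stored on the profile.
#' @param detached `"exclude"` (default: keep only connected components
#'   that touch the interface row or lie behind it) or `"include"`.
#' @return A [front_profile]; `interface_length` is the number of columns
#'   containing any epithelium.
#' @export
extract_front <- function(mask, interface_row, frame_index = 0L,
                          detached = c("exclude", "include")) {
  detached <- match.arg(detached)
  if (!any(mask)) stop("empty mask")
  if (interface_row < 1 || interface_row > nrow(mask))
    stop("interface_row outside image (1..", nrow(mask), ")")
  m <- mask
  if (detached == "exclude") {
    lab <- EBImage::bwlabel(mask)
    attached <- unique(as.vector(lab[seq_len(interface_row), ]))
    attached <- attached[attached > 0]
    m <- matrix(lab %in% attached, nrow(mask), ncol(mask))
  }
  depth <- apply(m, 2, function(col) {
    idx <- which(col)
    if (!length(idx) || max(idx) < interface_row) NA_real_
    else max(idx) - interface_row
  })
  if (all(is.na(depth)))
    warning("front does not reach the interface anywhere: all-invalid profile")
  L0 <- sum(colSums(mask) > 0)
  front_profile(depth, frame_index = frame_index, interface_length = L0)
}

#' Smooth a front profile with a centered moving average
#'
#' Centered moving average of width `window`; at the profile edges the
#' window truncates (shrinks) rather than padding, so no phantom mass is
#' introduced. Invalid (`NA`) positions are excluded from each average; a
#' position whose whole window is invalid remains invalid. For even
#' `window` the span covers `window/2` pixels left and `window/2 - 1`
#' pixels right of the center, i.e. `window` pixels in the interior.
#'
#' @param profile a [front_profile].
#' @param window moving-average width in pixels (default 20).
#' @return A smoothed [front_profile] with the same length and metadata.
#' @export
smooth_profile <- function(profile, window = 20L) {
  stopifnot(inherits(profile, "front_profile"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  n <- length(profile$depth)
  if (window > n) stop("window (", window, ") larger than profile (", n, ")")
  d <- profile$depth
  v <- !is.na(d)
  d0 <- ifelse(v, d, 0)
  left <- window %/% 2L
  right <- window - left - 1L
  cs <- c(0, cumsum(d0))
  cv <- c(0, cumsum(as.numeric(v)))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cv[hi + 1L] - cv[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  front_profile(out, frame_index = profile$frame_index,
                interface_length = profile$interface_length)
}

#' Normalized extent of invasion
#'
#' The invaded area at each frame is divided by the initial interface
#' length L0: `E(t) = (A(t) - A(t0)) / L0`, with A measured as the count
#' of epithelium pixels strictly beyond the fixed frame-0 interface row
#' (or, for traced ROI polygons, the shoelace area). `E(t0) = 0` by
#' construction and E carries length units (pixels, or microns when
#' `pixel_size` is set).
#'
#' @param masks list of logical masks (one per frame), or a list of
#'   `roi_polygon`s tracing the invaded region per frame.
#' @param interface_row initial interface row (1-based), required for mask
#'   input.
#' @param L0 initial interface length in pixels; by default taken from the
#'   epithelial span of the first mask, must be supplied for ROI input.
#' @param frame_interval minutes between frames (for the time column).
#' @param pixel_size microns per pixel, or `NULL` to stay in pixels.
#' @return A `data.frame` of class `invasion_summary` with columns
#'   `frame`, `time_min`, `area`, `extent`; attribute `units` records the
#'   length unit.
#' @export
normalized_extent <- function(masks, interface_row = NULL, L0 = NULL,
                              frame_interval = 60, pixel_size = NULL) {
  if (!length(masks)) stop("frames missing: no masks/ROIs supplied")
  if (inherits(masks[[1]], "roi_polygon")) {
    if (is.null(L0)) stop("L0 must be supplied for ROI-polygon input")
    area <- vapply(masks, function(p) polygon_area(p$vertices), numeric(1))
  } else {
    if (is.null(interface_row)) stop("interface_row required for mask input")
    area <- vapply(masks, function(m) {
      if (interface_row >= nrow(m)) 0
      else sum(m[(interface_row + 1L):nrow(m), , drop = FALSE])
    }, numeric(1))
    if (is.null(L0)) L0 <- sum(colSums(masks[[1]]) > 0)
  }
  if (is.null(L0) || L0 <= 0) stop("L0 = 0: no interface to normalize by")
  scale <- if (is.null(pixel_size)) 1 else pixel_size
  out <- data.frame(frame = seq_along(area) - 1L,
                    time_min = (seq_along(area) - 1L) * frame_interval,
                    area = area,
                    extent = (area - area[1]) / L0 * scale)
  attr(out, "units") <- if (is.null(pixel_size)) "px" else "um"
  attr(out, "L0") <- L0
  class(out) <- c("invasion_summary", "data.frame")
  out
}

#' Normalized extent computed from a depth profile
#'
#' For a single-valued front the invaded area equals the sum of the
#' per-column depths, so `E = sum(d) / L0` relative to frame 0. Used as a
#' cross-check against the area-count estimator.
#'
#' @param profile a [front_profile] (depths relative to the frame-0
#'   interface).
#' @return Extent in pixels.
#' @export
extent_from_profile <- function(profile) {
  d <- profile$depth
  sum(pmax(d[!is.na(d)], 0)) / profile$interface_length
}

#' Fold change of invasion extent between two conditions
#'
#' Ratio of mean final-frame normalized extents (test over control)
#' across independent replicate assay locations, with a Welch two-sample
#' t-test on the replicate values and significance stars at the
#' conventional thresholds (* p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001).
#'
#' @param extent_test numeric vector of replicate final-frame extents for
#'   the test condition.
#' @param extent_control same for the control condition.
#' @return List with `fold_change`, `p_value`, `stars`, per-condition
#'   `mean` and `sem`, and `n` per arm.
#' @export
fold_change <- function(extent_test, extent_control) {
  if (length(extent_test) < 2L || length(extent_control) < 2L)
    stop("need >= 2 replicate locations per condition")
  mc <- mean(extent_control)
  if (mc <= 0) stop("control mean extent <= 0: fold change undefined")
  # degenerate replicates (zero variance in both arms) have no defined
  # t-statistic; the ratio is still reported
  p <- tryCatch(stats::t.test(extent_test, extent_control)$p.value,
                error = function(e) NA_real_)
  list(fold_change = mean(extent_test) / mc,
       p_value = p,
       stars = p_stars(p),
       mean = c(test = mean(extent_test), control = mc),
       sem = c(test = stats::sd(extent_test) / sqrt(length(extent_test)),
               control = stats::sd(extent_control) / sqrt(length(extent_control))),
       n = c(test = length(extent_test), control = length(extent_control)))
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}
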