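#' Simulate a time-lapse invasion-front image stack with planted forks
#'
#' Generates a fluorescent epithelial band advancing into a dark stromal
#' band. The true front height field evolves as
#' `h(x, t) = v * t + sum of fork bumps`: the whole front advances at
#' `advance_rate` pixels per frame, and invasive forks nucleate as a
#' Poisson process (`fork_rate` expected new forks per frame per 1000
#' interface pixels) at uniform positions. Each fork is a Gaussian bump
#' in `x` (s.d. `fork_width_sigma`) whose amplitude ramps linearly over
#' `ramp_frames` frames to its planted depth, drawn from
#' `Normal(fork_depth_mean, fork_depth_sd)` truncated at 0. Frames render
#' epithelium rows (`row <= interface_row + h(x, t)`) at intensity `fg`,
#' stroma at `bg`, plus i.i.d. Gaussian intensity noise of s.d.
#' `noise_sigma`, clamped to \[0, 1\].
#'
#' Default geometry (512 x 512 px, interface at row 256, 25 hourly
#' frames) mirrors one assay field of view observed for 24 h.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames (>= 2).
#' @param interface_row initial interface row (1-based; epithelium
#'   occupies rows 1..interface_row at frame 0).
#' @param advance_rate front advance v, px/frame.
#' @param fork_rate expected fork nucleations per frame per 1000 px.
#' @param fork_depth_mean,fork_depth_sd planted fork depth distribution, px.
#' @param fork_width_sigma Gaussian fork width, px.
#' @param ramp_frames frames for a fork to reach full depth.
#' @param noise_sigma intensity noise s.d.
#' @param fg,bg epithelium / stroma mean intensities.
#' @param frame_interval minutes per frame (default 60).
#' @param seed RNG seed; the output is bit-identical for equal seeds.
#' @return List with `stack` (an [image_stack]) and `truth`: `h` (width x
#'   n_frames matrix of true front heights), `forks` (data.frame
#'   `birth_frame`, `x`, `depth`, `sigma`), plus the generating
#'   parameters.
#' @export
simulate_front_stack <- function(width = 512L, height = 512L, n_frames = 25L,
                                 interface_row = 256L, advance_rate = 2,
                                 fork_rate = 0.2, fork_depth_mean = 40,
                                 fork_depth_sd = 5, fork_width_sigma = 10,
                                 ramp_frames = 3L, noise_sigma = 0.05,
                                 fg = 0.8, bg = 0.2, frame_interval = 60,
                                 seed = NULL) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (interface_row <= 0L || interface_row >= height)
    stop("interface_row must lie strictly inside (0, height)")
  if (advance_rate < 0 || fork_rate < 0 || noise_sigma < 0)
    stop("rates and noise must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  xs <- seq_len(width)
  forks <- data.frame(birth_frame = integer(0), x = numeric(0),
                      depth = numeric(0), sigma = numeric(0))
  h <- matrix(0, nrow = width, ncol = n_frames)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {         # t = 0 .. n_frames - 1
    if (t > 0L && fork_rate > 0) {
      k <- stats::rpois(1, fork_rate * width / 1000)
      if (k > 0) {
        depth <- pmax(stats::rnorm(k, fork_depth_mean, fork_depth_sd), 0)
        forks <- rbind(forks, data.frame(
          birth_frame = t, x = stats::runif(k, 1, width),
          depth = depth, sigma = fork_width_sigma))
      }
    }
    ht <- rep(advance_rate * t, width)
    if (nrow(forks)) {
      age <- t - forks$birth_frame + 1L
      amp <- forks$depth * pmin(1, age / ramp_frames)
      for (j in seq_len(nrow(forks)))
        ht <- ht + amp[j] * exp(-(xs - forks$x[j])^2 / (2 * forks$sigma[j]^2))
    }
    h[, t + 1L] <- ht
    front_row <- pmin(interface_row + ht, height)
    mask <- outer(seq_len(height), front_row, "<=")
    img <- ifelse(mask, fg, bg)
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                          height, width)
    frames[[t + 1L]] <- pmin(pmax(img, 0), 1)
  }
  list(stack = image_stack(frames, frame_interval = frame_interval),
       truth = list(h = h, forks = forks, interface_row = interface_row,
                    advance_rate = advance_rate, fork_rate = fork_rate,
                    ramp_frames = ramp_frames, width = width,
                    height = height, n_frames = n_frames))
}

#' Ground-truth epithelium mask for one simulated frame
#'
#' @param truth the `truth` element returned by [simulate_front_stack()].
#' @param frame 0-based frame index.
#' @return Logical matrix (height x width), epithelium = `TRUE`.
#' @export
true_front_mask <- function(truth, frame) {
  front_row <- pmin(truth$interface_row + truth$h[, frame + 1L], truth$height)
  outer(seq_len(truth$height), front_row, "<=")
}

#' Score detected fork peaks against the generator registry
#'
#' Coverage matching: a planted fork is recovered when any detected peak
#' lies within `tol` pixels of its center; a detection is a false
#' positive when no planted fork (of any age) lies within `tol` of it.
#' Matching is many-to-many because overlapping planted bumps merge into
#' a single physical protrusion with one peak.
#'
#' Recall is reported against *scorable* forks: those that have completed
#' their depth ramp by the scored frame (mature) AND whose center lies at
#' least `edge_margin` pixels inside the profile — the side-window peak
#' rule cannot qualify positions whose flank retains fewer than half the
#' side window, so forks centered closer to the edge than that are
#' outside the rule's evaluable domain. Immature and edge forks still
#' absorb detections (they are not false positives).
#'
#' @param peaks integer vector of detected peak positions at `frame`.
#' @param truth generator `truth` list.
#' @param frame 0-based frame index that was scored.
#' @param tol match tolerance in pixels (default `2 * fork_width_sigma`
#'   of the first fork, falling back to 20).
#' @param edge_margin exclude forks centered within this many pixels of
#'   either profile edge from the recall denominator (default 20, half
#'   the standard 40-px side window).
#' @return List with `n_true_scorable`, `n_matched_scorable`, `recall`,
#'   `n_false_positive`.
#' @export
score_fork_detection <- function(peaks, truth, frame, tol = NULL,
                                 edge_margin = 20) {
  fk <- truth$forks
  alive <- fk[fk$birth_frame <= frame, , drop = FALSE]
  mature <- alive$birth_frame <= frame - truth$ramp_frames + 1L
  interior <- alive$x > edge_margin & alive$x <= truth$width - edge_margin
  scorable <- mature & interior
  if (is.null(tol))
    tol <- if (nrow(alive)) 2 * alive$sigma[1] else 20
  covered <- if (length(peaks) && nrow(alive))
    vapply(alive$x, function(x0) any(abs(peaks - x0) <= tol), logical(1))
  else rep(FALSE, nrow(alive))
  fp <- if (length(peaks) && nrow(alive))
    sum(vapply(peaks, function(p) all(abs(alive$x - p) > tol), logical(1)))
  else length(peaks)
  list(n_true_scorable = sum(scorable),
       n_matched_scorable = sum(covered & scorable),
       recall = if (sum(scorable)) sum(covered & scorable) / sum(scorable)
                else NA_real_,
       n_false_positive = fp)
}
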