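#' Simulate correlated-random-walk cell trajectories
#'
#' Each track is a persistent biased random walk: the heading angle
#' starts along +x and evolves by von Mises increments with concentration
#' `persistence_kappa` (kappa = 0 gives uniform turning, i.e. no
#' persistence; large kappa gives nearly straight motion). Per step the
#' cell moves `drift_speed * dt` along its current heading, plus
#' isotropic Gaussian positional noise of s.d. `step_noise` per
#' coordinate. With `drift_speed = 0` the walk is unbiased pure noise and
#' per-track displacement after n steps follows a Rayleigh law with mean
#' `step_noise * sqrt(n) * sqrt(pi / 2)`.
#'
#' Defaults mirror a 12 h migration movie at 10 min intervals (72 steps).
#'
#' @param n_tracks number of cells.
#' @param n_steps steps per track (>= 2 positions are guaranteed).
#' @param dt minutes per step (default 10).
#' @param drift_speed persistent speed along the heading, px/min.
#' @param persistence_kappa von Mises concentration of turning angles
#'   (>= 0; `Inf` freezes the heading).
#' @param step_noise positional noise s.d. per coordinate per step, px.
#' @param seed RNG seed; output is bit-identical for equal seeds.
#' @return List with `tracks` (a `trajectory_table`) and `truth` (the
#'   generating parameters).
#' @export
simulate_tracks <- function(n_tracks = 100L, n_steps = 72L, dt = 10,
                            drift_speed = 0.5, persistence_kappa = 2,
                            step_noise = 1, seed = NULL) {
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (step_noise < 0 || drift_speed < 0 || persistence_kappa < 0)
    stop("drift_speed, persistence_kappa and step_noise must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    theta <- cumsum(c(0, rvonmises(n_steps - 1L, persistence_kappa)))
    dx <- drift_speed * dt * cos(theta) +
      stats::rnorm(n_steps, 0, step_noise)
    dy <- drift_speed * dt * sin(theta) +
      stats::rnorm(n_steps, 0, step_noise)
    rows[[i]] <- data.frame(track_id = i,
                            frame = 0:n_steps,
                            x = cumsum(c(0, dx)),
                            y = cumsum(c(0, dy)))
  }
  df <- do.call(rbind, rows)
  df$time_min <- df$frame * dt
  list(tracks = trajectory_table(df, frame_interval = dt),
       truth = list(n_tracks = n_tracks, n_steps = n_steps, dt = dt,
                    drift_speed = drift_speed,
                    persistence_kappa = persistence_kappa,
                    step_noise = step_noise))
}

#' Sample von Mises turning angles (Best-Fisher rejection sampler)
#'
#' Mean direction 0, concentration `kappa`. `kappa = 0` reduces to the
#' uniform distribution on (-pi, pi]; `kappa = Inf` returns zeros.
#'
#' @param n number of draws.
#' @param kappa concentration parameter (>= 0).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (is.infinite(kappa)) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Expected step speed of the trajectory generator
#'
#' Monte Carlo estimate of `E(|step|) / dt` for one generator step
#' (drift of length `drift_speed * dt` plus isotropic Gaussian noise),
#' the quantity recovered by the mean of per-track velocities.
#'
#' @param drift_speed,dt,step_noise generator parameters.
#' @param n_sim Monte Carlo sample size.
#' @return Expected speed in px/min.
#' @export
expected_step_speed <- function(drift_speed, dt, step_noise, n_sim = 2e5) {
  mu <- drift_speed * dt
  sx <- mu + stats::rnorm(n_sim, 0, step_noise)
  sy <- stats::rnorm(n_sim, 0, step_noise)
  mean(sqrt(sx^2 + sy^2)) / dt
}
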