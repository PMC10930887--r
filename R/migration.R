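#' Per-track motility metrics
#'
#' For every track with at least two points: straight-line displacement
#' (start to end), total path length (sum of step lengths), velocity
#' (path length over elapsed time, length/min), and directionality.
#' Directionality defaults to the confinement ratio
#' `displacement / path_length` (dimensionless, in \[0, 1\]); the mean
#' cosine of successive turning angles is available as an alternative.
#' Missing frames use the actual time gaps — no interpolation is
#' performed. Tracks flagged as short (< 2 points) get `NA` metrics.
#'
#' @param traj a `trajectory_table` (see [trajectory_table()]).
#' @param directionality `"confinement"` (default) or `"mean_cos"`.
#' @return `data.frame` with one row per track: `track_id`,
#'   `displacement`, `path_length`, `velocity`, `directionality`,
#'   `n_steps`.
#' @export
track_metrics <- function(traj, directionality = c("confinement", "mean_cos")) {
  directionality <- match.arg(directionality)
  stopifnot(inherits(traj, "trajectory_table"))
  ids <- unique(traj$track_id)
  rows <- lapply(ids, function(id) {
    t <- traj[traj$track_id == id, , drop = FALSE]
    if (nrow(t) < 2L)
      return(data.frame(track_id = id, displacement = NA_real_,
                        path_length = NA_real_, velocity = NA_real_,
                        directionality = NA_real_, n_steps = 0L))
    dx <- diff(t$x); dy <- diff(t$y)
    steps <- sqrt(dx^2 + dy^2)
    path <- sum(steps)
    disp <- sqrt((t$x[nrow(t)] - t$x[1])^2 + (t$y[nrow(t)] - t$y[1])^2)
    elapsed <- t$time_min[nrow(t)] - t$time_min[1]
    if (elapsed <= 0) stop("zero elapsed time in track ", id)
    dir <- switch(directionality,
      confinement = if (path > 0) disp / path else NA_real_,
      mean_cos = {
        keep <- steps > 0
        if (sum(keep) < 2L) NA_real_ else {
          ux <- dx[keep] / steps[keep]; uy <- dy[keep] / steps[keep]
          k <- length(ux)
          mean(ux[-k] * ux[-1] + uy[-k] * uy[-1])
        }
      })
    data.frame(track_id = id, displacement = disp, path_length = path,
               velocity = path / elapsed, directionality = dir,
               n_steps = nrow(t) - 1L)
  })
  do.call(rbind, rows)
}

#' Compare a motility metric across two conditions
#'
#' Welch two-sample t-test per metric, with per-condition mean and
#' s.e.m. and significance stars at the conventional thresholds.
#'
#' @param metrics_by_condition named list of [track_metrics()] outputs,
#'   one element per condition (exactly two conditions).
#' @param metric column name to compare: `"displacement"`, `"velocity"`,
#'   or `"directionality"` (any metric column works).
#' @return List with `metric`, `p_value`, `stars`, and a `summary`
#'   data.frame (condition, n, mean, sem).
#' @export
compare_conditions <- function(metrics_by_condition, metric = "velocity") {
  if (length(metrics_by_condition) != 2L)
    stop("exactly two conditions are required")
  vals <- lapply(metrics_by_condition, function(m) {
    v <- m[[metric]]
    v[!is.na(v)]
  })
  ns <- lengths(vals)
  if (any(ns < 2L))
    stop("condition `", names(vals)[which(ns < 2L)[1]],
         "` has < 2 tracks with metric `", metric, "`")
  tt <- stats::t.test(vals[[1]], vals[[2]])
  list(metric = metric,
       p_value = tt$p.value,
       stars = p_stars(tt$p.value),
       summary = data.frame(
         condition = names(vals),
         n = as.integer(ns),
         mean = vapply(vals, mean, numeric(1)),
         sem = vapply(vals, function(v) stats::sd(v) / sqrt(length(v)),
                      numeric(1)),
         row.names = NULL))
}
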