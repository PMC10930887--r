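#' Read traced invasion-boundary ROI polygons from CSV
#'
#' Expects columns `frame`, `vertex_index`, `x`, `y` (extra columns are
#' ignored). `x` runs along the initial interface, `y` into the stroma,
#' both 0-based pixel coordinates. One polygon is returned per frame,
#' vertices ordered by `vertex_index`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @return A list of `roi_polygon` objects, each a list with `vertices`
#'   (two-column matrix, columns `x`, `y`), `frame_index`, `closed`.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "vertex_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI CSV missing column(s): ", paste(miss, collapse = ", "))
  for (cc in need)
    if (!is.numeric(df[[cc]]))
      stop("ROI CSV column `", cc, "` is not numeric")
  frames <- sort(unique(df$frame))
  lapply(frames, function(fr) {
    sub <- df[df$frame == fr, , drop = FALSE]
    sub <- sub[order(sub$vertex_index), , drop = FALSE]
    structure(
      list(vertices = cbind(x = sub$x, y = sub$y),
           frame_index = fr, closed = TRUE),
      class = "roi_polygon")
  })
}

#' Polygon area by the shoelace formula
#'
#' @param vertices two-column matrix of (x, y) vertex coordinates of a
#'   simple closed polygon.
#' @return Area in squared coordinate units (always non-negative).
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  if (n < 3L) stop("a closed polygon needs at least 3 vertices")
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Read a cell-trajectory table from CSV
#'
#' Accepts a minimal tracking export with one row per (track, frame) spot.
#' The default column mapping follows a TrackMate-style spots export
#' (`TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`) and falls back to
#' lower-case `track_id`, `frame`, `x`, `y`. Time is taken from a
#' `time_min` column when present, otherwise derived as
#' `frame * frame_interval`.
#'
#' Rows are returned sorted by (track_id, frame); input order is not
#' preserved. Tracks with fewer than 2 points are retained but flagged in
#' the logical `short_track` column (no metrics can be computed for them).
#'
#' @param path CSV file path.
#' @param frame_interval minutes between frames, used when no time column
#'   is present. Defaults to 10 (typical migration imaging cadence).
#' @param column_map named character vector mapping canonical names
#'   (`track_id`, `frame`, `x`, `y`, optionally `time_min`) to the file's
#'   column names; `NULL` tries the built-in dialects.
#' @return A `data.frame` of class `trajectory_table` with columns
#'   `track_id`, `frame`, `x`, `y`, `time_min`, `short_track`.
#' @export
read_trajectories <- function(path, frame_interval = 10, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dialects <- list(
    c(track_id = "track_id", frame = "frame", x = "x", y = "y"),
    c(track_id = "TRACK_ID", frame = "FRAME",
      x = "POSITION_X", y = "POSITION_Y"))
  if (!is.null(column_map)) dialects <- list(column_map)
  map <- NULL
  for (d in dialects)
    if (all(d %in% names(df))) { map <- d; break }
  if (is.null(map))
    stop("trajectory CSV: no known column dialect matched; columns found: ",
         paste(names(df), collapse = ", "))
  out <- data.frame(track_id = df[[map["track_id"]]],
                    frame = df[[map["frame"]]],
                    x = df[[map["x"]]], y = df[[map["y"]]])
  if (anyNA(out$x) || anyNA(out$y))
    stop("trajectory CSV: missing coordinates")
  tm_col <- if (!is.null(column_map) && "time_min" %in% names(column_map))
    column_map[["time_min"]] else "time_min"
  out$time_min <- if (tm_col %in% names(df)) df[[tm_col]]
    else out$frame * frame_interval
  trajectory_table(out)
}

#' Construct a trajectory table
#'
#' @param df data.frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `time_min`.
#' @param frame_interval minutes per frame used to fill `time_min` when
#'   absent.
#' @return A sorted, validated `trajectory_table` data.frame.
#' @export
trajectory_table <- function(df, frame_interval = 10) {
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$time_min)) df$time_min <- df$frame * frame_interval
  dup <- duplicated(df[c("track_id", "frame")])
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop(sprintf("duplicate (track_id, frame) pair: (%s, %s)",
                 first$track_id, first$frame))
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  n_per <- table(df$track_id)
  df$short_track <- as.vector(n_per[as.character(df$track_id)] < 2L)
  class(df) <- c("trajectory_table", "data.frame")
  df
}

#' Write a trajectory table to CSV
#'
#' @param traj a `trajectory_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(
    traj[c("track_id", "frame", "x", "y", "time_min")], path,
    row.names = FALSE)
  invisible(path)
}
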