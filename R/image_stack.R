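#' Image stack container
#'
#' A time-ordered sequence of single-channel intensity frames from a
#' live-microscopy invasion assay. Orientation convention: matrix rows
#' (axis 0) run in the invasion direction, with increasing row index going
#' INTO the stromal compartment; matrix columns (axis 1) run along the
#' initial epithelium-stroma interface.
#'
#' @param frames list of numeric matrices of identical dimensions.
#' @param pixel_size physical length per pixel in microns, or `NULL` if
#'   unknown (outputs then stay in pixel units).
#' @param frame_interval time between consecutive frames in minutes.
#'   Defaults to 60 (hourly invasion imaging).
#'
#' @return An object of class `image_stack`: a list with elements `frames`,
#'   `pixel_size`, `frame_interval`.
#' @export
image_stack <- function(frames, pixel_size = NULL, frame_interval = 60) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a numeric matrix")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stop("frames of unequal shape: all frames must share identical dimensions")
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0))
    stop("`pixel_size` must be a positive number or NULL")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0 minutes")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px, interval %g min%s\n",
              length(x$frames), d[1], d[2], x$frame_interval,
              if (is.null(x$pixel_size)) "" else
                sprintf(", %g um/px", x$pixel_size)))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages are kept in file order, one frame per page.
#'
#' @param path path to a multi-page grayscale TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack].
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = 60) {
  if (!file.exists(path)) stop("unreadable stack: file not found: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop("unreadable stack: ", path, " (", conditionMessage(e), ")",
                            call. = FALSE))
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) {
      if (dim(f)[3] == 1L) f <- f[, , 1L]
      else stop("expected grayscale TIFF, got ", dim(f)[3], " channels")
    }
    f
  })
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write an image stack to a multi-page 32-bit float TIFF
#'
#' Intensities must lie in \[0, 1\]. 32-bit float pages round-trip real
#' values within single precision (< 1e-9 relative for unit-scale data).
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  rng <- range(unlist(lapply(stack$frames, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("frame intensities must lie in [0, 1] for TIFF output")
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32L)
  invisible(path)
}
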