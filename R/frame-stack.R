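#' Frame stack: an ordered grayscale image sequence
#'
#' The raw observable of high-speed videoendoscopy: `n_frames` grayscale
#' images of the glottis sampled at `frame_rate` frames per second.
#' Intensities are stored in `[0, 1]`, frame-major, as a `T x H x W` array
#' (time, image row, image column; origin top-left).
#'
#' @param frames numeric array `T x H x W` with values in `[0, 1]`.
#' @param frame_rate sampling rate in frames per second.
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `frame_rate`, `n_frames`, `height`, `width` and `duration` (seconds).
#' @export
frame_stack <- function(frames, frame_rate) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort("`frames` must be a 3-d array (time x rows x cols).")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    abort("`frame_rate` must be a positive scalar (frames/s).")
  d <- dim(frames)
  structure(
    list(
      frames = frames,
      frame_rate = as.numeric(frame_rate),
      n_frames = d[[1L]],
      height = d[[2L]],
      width = d[[3L]],
      duration = d[[1L]] / frame_rate
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf(
    "<frame_stack> %d frames, %d x %d px, %.0f fps (%.1f ms)\n",
    x$n_frames, x$height, x$width, x$frame_rate, 1000 * x$duration
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# brightness time-series matrix (T x n_pixels) for pixels where roi is TRUE;
# pixel order follows column-major order of the H x W plane
stack_pixel_matrix <- function(stack, roi = NULL) {
  tt <- stack$n_frames
  m <- matrix(stack$frames, nrow = tt)
  if (is.null(roi)) return(m)
  stopifnot(is.logical(roi), all(dim(roi) == c(stack$height, stack$width)))
  m[, as.vector(roi), drop = FALSE]
}
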