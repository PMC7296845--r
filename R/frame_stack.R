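#' Ordered fluorescence frames from one imaging position
#'
#' Container for a time-lapse acquisition: an ordered list of equally sized
#' 2-D intensity matrices (a.u.) captured at a fixed interval from one
#' position in a well.
#'
#' @param frames List of numeric matrices, all with identical dimensions,
#'   finite and non-negative.
#' @param frame_interval Minutes between consecutive frames.
#' @param position_id Identifier of the imaging position.
#' @return A `FrameStack` object.
#' @export
frame_stack <- function(frames, frame_interval = 15, position_id = "pos1") {
  if (!is.list(frames) || length(frames) < 1L) {
    mq_stop("`frames` must be a non-empty list of matrices", "mq_validation_error",
            field = "frames")
  }
  frames <- lapply(frames, as_frame_matrix)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    mq_stop("all frames must share dimensions", "mq_validation_error",
            field = "frames")
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    mq_stop("frame intensities must be >= 0", "mq_validation_error",
            field = "frames")
  }
  stopifnot_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  structure(
    list(frames = frames, frame_interval = as.numeric(frame_interval),
         position_id = as.character(position_id)),
    class = "FrameStack"
  )
}

# Accept a FrameStack or a bare list of matrices.
stack_frames <- function(stack) {
  if (inherits(stack, "FrameStack")) return(stack$frames)
  if (is.list(stack)) return(lapply(stack, as_frame_matrix))
  mq_stop("`stack` must be a FrameStack or list of matrices", "mq_validation_error")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<FrameStack> %s: %d frame(s) of %d x %d px, interval %g min\n",
              x$position_id, length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}
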