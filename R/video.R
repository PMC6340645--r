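#' Construct a video sequence
#'
#' The pipeline's input container: an ordered stack of equal-shape 2-D
#' grayscale frames with a known frame rate.  Frames are stored as a 3-D
#' array indexed `[row, col, frame]` and converted to double precision.
#'
#' @param frames A 3-D numeric array `[rows, cols, n]`, or a list of
#'   equal-shape numeric matrices.
#' @param fps Frame rate in frames per second (> 0).
#' @return An object of class `echo_video` with elements `frames`
#'   (3-D array), `fps`, `n_frames`, and `shape` (rows, cols).
#' @export
video_sequence <- function(frames, fps) {
  if (is.list(frames)) {
    shapes <- vapply(frames, function(f) paste(dim(as.matrix(f)), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1L)
      stop_echogate("all frames must share one shape; saw shapes {%s}",
                    paste(unique(shapes), collapse = ", "))
    frames <- array(unlist(lapply(frames, as.matrix)),
                    dim = c(dim(as.matrix(frames[[1]])), length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_echogate("frames must be a [rows, cols, n] array or a list of matrices")
  if (dim(frames)[3] < 2L)
    stop_echogate("a video needs at least 2 frames, got %d", dim(frames)[3])
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop_echogate("fps must be a single positive number")
  storage.mode(frames) <- "double"
  structure(
    list(frames = frames, fps = as.numeric(fps),
         n_frames = dim(frames)[3], shape = dim(frames)[1:2]),
    class = "echo_video")
}

#' @export
print.echo_video <- function(x, ...) {
  cat(sprintf("<echo_video> %d frames of %dx%d px at %.6g fps (%.3f s)\n",
              x$n_frames, x$shape[1], x$shape[2], x$fps, x$n_frames / x$fps))
  invisible(x)
}

#' Flatten a video into a frames-by-pixels matrix
#'
#' @param video An `echo_video`.
#' @return An `n_frames` x `m` matrix; pixels are flattened in column-major
#'   order (a fixed convention — all that matters is that it is consistent).
#' @export
frame_matrix <- function(video) {
  stopifnot(inherits(video, "echo_video"))
  m <- prod(video$shape)
  t(matrix(video$frames, nrow = m, ncol = video$n_frames))
}

#' Extract one frame as a matrix
#' @param video An `echo_video`.
#' @param i Frame index (1-based).
#' @return A rows-by-cols numeric matrix.
#' @export
get_frame <- function(video, i) {
  stopifnot(inherits(video, "echo_video"), i >= 1, i <= video$n_frames)
  video$frames[, , i]
}

#' Subset a video by frame indices
#' @param video An `echo_video`.
#' @param idx Frame indices to keep, in order.
#' @param fps Optional new frame rate (used when decimating).
#' @return An `echo_video`.
#' @export
subset_video <- function(video, idx, fps = video$fps) {
  stopifnot(inherits(video, "echo_video"), all(idx >= 1), all(idx <= video$n_frames))
  video_sequence(video$frames[, , idx, drop = FALSE], fps)
}
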