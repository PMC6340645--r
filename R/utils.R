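#' Circular distance between phases on the unit circle
#'
#' Phases live in `[0, 1)`; the distance is the shorter arc, so it is
#' bounded by 0.5.
#'
#' @param a,b Numeric vectors of phases (recycled to a common length).
#' @return Numeric vector of distances in `[0, 0.5]`.
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Wrap values onto the unit interval
#' @param x Numeric vector.
#' @return `x` modulo 1, in `[0, 1)`.
#' @keywords internal
wrap_phase <- function(x) x %% 1

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Frame interval of an acquisition
#'
#' @param fps Frame rate in frames per second.
#' @return Interval between consecutive frames in milliseconds.
#' @examples
#' frame_interval_ms(233)  # ~4.29 ms
#' @export
frame_interval_ms <- function(fps) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  1000 / fps
}

stop_echogate <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
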