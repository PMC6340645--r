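#' Instantaneous phase via the analytic signal
#'
#' The Hilbert transform `H(x)` extends a real narrow-band series to its
#' analytic signal `x + i*H(x)`; the quadrant-aware angle of that complex
#' series is the instantaneous phase.  The angle in `[-pi, pi)` is mapped
#' affinely to `[0, 1)` by `(phi + pi) / (2*pi)`, which places the local
#' minima of a near-sinusoid at phase 0 — the convention the respiratory
#' cutoff gate relies on (heaviest motion at respiration-signal minima,
#' phase 0).  The mean is removed internally: a DC offset corrupts the
#' analytic-signal angle.
#'
#' @param x Finite numeric series, length >= 8, not constant.
#' @return Phase series in `[0, 1)`.
#' @export
hilbert_phase <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop_echogate("hilbert_phase needs length >= 8, got %d", n)
  if (any(!is.finite(x))) stop_echogate("hilbert_phase input contains non-finite values")
  x <- x - mean(x)
  if (all(x == 0)) stop_echogate("constant series: instantaneous phase undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  phi <- atan2(Im(a), Re(a))
  ((phi + pi) / (2 * pi)) %% 1
}

#' Unwrap a phase series in cycle units
#'
#' Cumulative phase assuming each step moves less than half a cycle.
#'
#' @param phase Wrapped phases in `[0, 1)`.
#' @return Non-modular cumulative phase (same first value).
#' @export
unwrap_phase <- function(phase) {
  d <- diff(phase)
  d <- d - round(d)
  c(phase[1], phase[1] + cumsum(d))
}

#' Estimate cardiac and respiratory phases from a decomposition
#'
#' Cardiac phase is the Hilbert phase of the band-limited heart-beat
#' residual; respiratory phase is the Hilbert phase of the respiration
#' trend.
#'
#' The phase-0 convention (signal minima) is only physiologically
#' meaningful if the selected row's similarity signal *dips* during
#' systole and heavy respiration — true when the reference frame is a
#' quiescent diastolic one, but inverted when the entropy criterion
#' lands on a transient frame (the signal then peaks where that frame's
#' state recurs).  With `orient = TRUE` (default) each component's sign
#' is anchored against the corresponding component of the column-mean
#' similarity signal, which dips at globally transient frames no matter
#' which row was selected; a negative correlation flips the component's
#' phase by half a cycle.
#'
#' @param decomp An `echo_decomp`, normally after [bandlimit()].
#' @param fps Frame rate (kept for interface symmetry; the transform
#'   itself is rate-free).
#' @param orient Anchor the phase-0 convention against the column-mean
#'   similarity signal?
#' @return An object of class `echo_phases`: `cardiac_phase`,
#'   `resp_phase` (both in `[0, 1)`), `unwrapped_cardiac`, `fps`.
#' @export
estimate_phases <- function(decomp, fps = decomp$fps, orient = TRUE) {
  stopifnot(inherits(decomp, "echo_decomp"))
  cardiac <- tryCatch(hilbert_phase(decomp$r_heart), error = function(e)
    stop_echogate("heart-beat signal: %s", conditionMessage(e)))
  resp <- tryCatch(hilbert_phase(decomp$tau_resp), error = function(e)
    stop_echogate("respiration signal: %s", conditionMessage(e)))
  if (orient && !is.null(decomp$anchor_resid)) {
    if (stats::cor(decomp$r_heart, decomp$anchor_resid) < 0)
      cardiac <- (cardiac + 0.5) %% 1
    if (stats::cor(decomp$tau_resp, decomp$anchor_trend) < 0)
      resp <- (resp + 0.5) %% 1
  }
  structure(list(cardiac_phase = cardiac, resp_phase = resp,
                 unwrapped_cardiac = unwrap_phase(cardiac), fps = fps),
            class = "echo_phases")
}

#' @export
print.echo_phases <- function(x, ...) {
  cycles <- diff(range(x$unwrapped_cardiac))
  cat(sprintf("<echo_phases> %d frames, ~%.1f cardiac cycles\n",
              length(x$cardiac_phase), cycles))
  invisible(x)
}
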