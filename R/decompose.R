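#' Frequency bands for cleaning the decomposed signals
#'
#' Defaults are typical mouse physiology: respiration below 230 BPM,
#' heart beat within 310-840 BPM.
#'
#' @param resp_lowpass_bpm Low-pass cutoff for the respiration trend.
#' @param heart_band_bpm Length-2 vector `(low, high)` band for the
#'   heart-beat residual.
#' @return A `band_spec` list.
#' @export
band_spec <- function(resp_lowpass_bpm = 230, heart_band_bpm = c(310, 840)) {
  if (resp_lowpass_bpm <= 0 || heart_band_bpm[1] <= 0)
    stop_echogate("band edges must be positive")
  if (!(resp_lowpass_bpm < heart_band_bpm[1] &&
        heart_band_bpm[1] < heart_band_bpm[2]))
    stop_echogate("require resp_lowpass < heart low < heart high (got %g, %g, %g)",
                  resp_lowpass_bpm, heart_band_bpm[1], heart_band_bpm[2])
  structure(list(resp_lowpass_bpm = resp_lowpass_bpm,
                 heart_band_bpm = heart_band_bpm),
            class = "band_spec")
}

# Order-n Butterworth amplitude responses.
butter_lp_amp <- function(f, fc, order = 4) 1 / sqrt(1 + (f / fc)^(2 * order))
butter_hp_amp <- function(f, fc, order = 4) {
  out <- numeric(length(f))
  nz <- f > 0
  out[nz] <- 1 / sqrt(1 + (fc / f[nz])^(2 * order))
  out
}

# Zero-phase filtering: multiply the two-sided FFT by a real, symmetric
# amplitude response.  `response` is a function of nonnegative frequency
# in Hz.  A real even response introduces no phase shift or group delay,
# which the downstream Hilbert phase requires.
apply_zero_phase <- function(x, fps, response) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fps / n
  H <- response(f)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

zero_phase_lowpass <- function(x, fps, cutoff_hz, order = 4) {
  check_nyquist(cutoff_hz, fps, "low-pass cutoff")
  apply_zero_phase(x, fps, function(f) butter_lp_amp(f, cutoff_hz, order))
}

# Band-pass as cascaded high/low-pass amplitudes, renormalized to unity
# peak gain over the realized frequency grid so an in-band sinusoid
# passes essentially unchanged.
zero_phase_bandpass <- function(x, fps, low_hz, high_hz, order = 4) {
  check_nyquist(low_hz, fps, "band-pass low edge")
  check_nyquist(high_hz, fps, "band-pass high edge")
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fps / n
  H <- butter_hp_amp(f, low_hz, order) * butter_lp_amp(f, high_hz, order)
  mx <- max(H)
  if (mx > 0) H <- H / mx
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

check_nyquist <- function(edge_hz, fps, what) {
  if (edge_hz >= fps / 2)
    stop_echogate("%s (%.3g Hz = %.0f BPM) is at or above Nyquist (%.3g Hz)",
                  what, edge_hz, edge_hz * 60, fps / 2)
  invisible(TRUE)
}

#' Select the best similarity-matrix row and decompose it
#'
#' Every row of `S` is decomposed by the Hodrick-Prescott filter into a
#' respiratory trend and a cardiac residual; the row whose residual has
#' the smallest periodogram entropy (i.e. is most narrow-band) is
#' selected.  Ties break to the lowest row index.
#'
#' @param S An `echo_similarity` (or a plain symmetric matrix).
#' @param lambda HP smoothness penalty (default 6400).
#' @param fps Frame rate; defaults to the one stored in `S`.
#' @return An object of class `echo_decomp`: `row_index`, `u_hat`,
#'   `tau_resp`, `r_heart`, `lambda`, `entropy_per_row`, `fps`,
#'   `bandlimited` (FALSE), plus optional stacked `trend_matrix` /
#'   `residual_matrix`.
#' @param keep_matrices Keep the stacked per-row trend/residual matrices?
#' @export
select_row <- function(S, lambda = 6400, fps = NULL, keep_matrices = FALSE) {
  if (inherits(S, "echo_similarity")) {
    fps <- fps %||% S$fps
    S <- S$values
  }
  if (is.null(fps)) stop_echogate("fps is required")
  S <- as.matrix(S)
  hp <- hp_filter_rows(S, lambda)
  # Polarity anchor: the column-mean similarity signal dips whenever a
  # frame is globally transient (systole, heavy respiratory motion),
  # regardless of which row is selected.  Its HP components fix the sign
  # convention of the selected row's components downstream.
  anchor <- hp_filter(colMeans(S), lambda)
  entropies <- vapply(seq_len(nrow(S)), function(i) {
    tryCatch(periodogram_entropy(hp$residual[i, ], fps)$entropy,
             error = function(e) stop_echogate(
               "row %d: %s", i, conditionMessage(e)))
  }, numeric(1))
  i_star <- which.min(entropies)          # which.min takes the first minimum
  structure(list(
    row_index = i_star,
    u_hat = S[i_star, ],
    tau_resp = hp$trend[i_star, ],
    r_heart = hp$residual[i_star, ],
    lambda = lambda,
    entropy_per_row = entropies,
    fps = fps,
    bandlimited = FALSE,
    anchor_trend = anchor$trend,
    anchor_resid = anchor$residual,
    trend_matrix = if (keep_matrices) hp$trend else NULL,
    residual_matrix = if (keep_matrices) hp$residual else NULL),
    class = "echo_decomp")
}

#' Frequency-clean a signal decomposition
#'
#' Low-pass filters the respiratory trend at the respiration cutoff and
#' band-pass filters the cardiac residual to the heart band, both with
#' zero-phase (no group delay) filters so instantaneous phase estimates
#' are not shifted in time.
#'
#' @param decomp An `echo_decomp`.
#' @param bands A [band_spec()].
#' @param fps Frame rate; defaults to the decomposition's.
#' @return The decomposition with filtered `tau_resp` / `r_heart` and
#'   `bandlimited = TRUE`.  `u_hat` is untouched.
#' @export
bandlimit <- function(decomp, bands = band_spec(), fps = decomp$fps) {
  stopifnot(inherits(decomp, "echo_decomp"))
  lp_hz <- bands$resp_lowpass_bpm / 60
  band_hz <- bands$heart_band_bpm / 60
  decomp$tau_resp <- zero_phase_lowpass(decomp$tau_resp, fps, lp_hz)
  decomp$r_heart <- zero_phase_bandpass(decomp$r_heart, fps, band_hz[1], band_hz[2])
  if (!is.null(decomp$anchor_trend)) {
    decomp$anchor_trend <- zero_phase_lowpass(decomp$anchor_trend, fps, lp_hz)
    decomp$anchor_resid <- zero_phase_bandpass(decomp$anchor_resid, fps,
                                               band_hz[1], band_hz[2])
  }
  decomp$bandlimited <- TRUE
  decomp$bands <- bands
  decomp
}

#' @export
print.echo_decomp <- function(x, ...) {
  cat(sprintf("<echo_decomp> row %d of %d (entropy %.3f, lambda %g%s)\n",
              x$row_index, length(x$entropy_per_row),
              x$entropy_per_row[x$row_index], x$lambda,
              if (isTRUE(x$bandlimited)) ", band-limited" else ""))
  invisible(x)
}
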