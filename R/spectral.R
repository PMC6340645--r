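#' FFT periodogram of a univariate series
#'
#' Mean-removed periodogram on a one-sided frequency grid, zero-padded to
#' the next power of two at least `4 * length(x)` so that entropy
#' comparisons across signals of equal length share a stable, fine grid.
#'
#' @param x Finite numeric series, length >= 4.
#' @param fps Sampling rate in frames/second.
#' @return A list of class `echo_periodogram`: `freq` (Hz), `bpm`,
#'   `power` (nonnegative), `normalized_power` (sums to 1).
#' @export
periodogram <- function(x, fps) {
  x <- as.numeric(x)
  if (length(x) < 4) stop_echogate("periodogram needs length >= 4")
  if (any(!is.finite(x))) stop_echogate("periodogram input contains non-finite values")
  x <- x - mean(x)
  if (all(x == 0))
    stop_echogate("all-zero (constant) series: periodogram normalization undefined")
  n <- length(x)
  nfft <- 2^ceiling(log2(max(4 * n, 8)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- nfft / 2
  power <- Mod(X[1:(half + 1)])^2
  freq <- (0:half) * fps / nfft
  structure(list(freq = freq, bpm = freq * 60, power = power,
                 normalized_power = power / sum(power)),
            class = "echo_periodogram")
}

#' Spectral entropy of a series
#'
#' Shannon entropy (natural log) of the normalized periodogram treated as
#' a probability distribution, with `0 * log(0) := 0`.  Near-sinusoidal
#' (narrow-band) signals have low entropy; broadband noise has high
#' entropy.  Used to pick the similarity-matrix row whose cardiac
#' residual is most sinusoidal.
#'
#' @inheritParams periodogram
#' @return List with `periodogram` and scalar `entropy` (>= 0).
#' @export
periodogram_entropy <- function(x, fps) {
  p <- periodogram(x, fps)
  list(periodogram = p, entropy = entropy_of(p$normalized_power))
}

# Shannon entropy (nats) of a normalized spectrum, 0*log(0) := 0.
entropy_of <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Dominant frequency of a series
#' @inheritParams periodogram
#' @return Frequency (Hz) of the periodogram's largest power.
#' @export
dominant_frequency <- function(x, fps) {
  p <- periodogram(x, fps)
  p$freq[which.max(p$power)]
}
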