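#' Configuration for the synthetic ultrasound simulator
#'
#' Defaults mirror a typical preclinical mouse acquisition: ~300 frames at
#' 233 FPS covering ~11 cardiac cycles (512 BPM) and exactly 2 respiratory
#' cycles (93.2 BPM).  The heart is rendered as a bright pulsating ring;
#' respiration as a slow global vertical translation concentrated in a
#' short interval of each respiratory cycle; ultrasound speckle as
#' multiplicative unit-mean noise.
#'
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate, frames/second.
#' @param heart_rate Cardiac rate in beats/minute (must exceed `resp_rate`).
#' @param resp_rate Respiratory rate in breaths/minute.
#' @param image_shape Integer vector `(rows, cols)` in pixels.
#' @param speckle_level Dimensionless multiplicative noise scale; 0 disables
#'   speckle.
#' @param resp_amplitude Peak respiratory displacement in pixels.
#' @param resp_width Width (in respiratory-phase units) of the Gaussian
#'   displacement bump around respiratory phase 0.
#' @param resp_radius_coupling Apparent ring-radius change per pixel of
#'   respiratory displacement (an out-of-plane slice-shift effect: the
#'   imaging plane cuts the chamber off-center while the chest moves).
#' @param cardiac_asymmetry Shape parameter in `[0, 1)`; 0 gives a symmetric
#'   contraction/relaxation, larger values make contraction faster than
#'   relaxation.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_frames = 300L, fps = 233, heart_rate = 512,
                       resp_rate = 93.2, image_shape = c(64L, 64L),
                       speckle_level = 0.2, resp_amplitude = 3,
                       resp_width = 0.15, resp_radius_coupling = 0.15,
                       cardiac_asymmetry = 0.2, seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), fps = fps,
              heart_rate = heart_rate, resp_rate = resp_rate,
              image_shape = as.integer(image_shape),
              speckle_level = speckle_level,
              resp_amplitude = resp_amplitude, resp_width = resp_width,
              resp_radius_coupling = resp_radius_coupling,
              cardiac_asymmetry = cardiac_asymmetry, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_frames < 2L) stop_echogate("n_frames must be >= 2")
  if (cfg$fps <= 0) stop_echogate("fps must be positive")
  if (cfg$heart_rate <= 0 || cfg$resp_rate <= 0)
    stop_echogate("heart_rate and resp_rate must be strictly positive")
  if (cfg$heart_rate <= cfg$resp_rate)
    stop_echogate("heart_rate (%g) must exceed resp_rate (%g)",
                  cfg$heart_rate, cfg$resp_rate)
  if (cfg$cardiac_asymmetry < 0 || cfg$cardiac_asymmetry >= 1)
    stop_echogate("cardiac_asymmetry must lie in [0, 1)")
  if (cfg$speckle_level < 0) stop_echogate("speckle_level must be >= 0")
  if (cfg$resp_width <= 0) stop_echogate("resp_width must be positive")
  geo <- ring_geometry(cfg)
  need <- 2 * (geo$r0 + 3 * geo$sigma_r + abs(cfg$resp_amplitude))
  if (min(cfg$image_shape) < need)
    stop_echogate("image too small to contain the ring: need >= %.0f px, got %d",
                  need, min(cfg$image_shape))
  invisible(cfg)
}

# Fixed ring geometry derived from the image size: baseline radius,
# contraction amplitude (radius shrinks 25% at peak systole), wall width.
ring_geometry <- function(cfg) {
  r0 <- 0.30 * min(cfg$image_shape)
  list(r0 = r0, amp = 0.25 * r0, sigma_r = 2.5)
}

#' Cardiac radius waveform
#'
#' Smooth asymmetric bump: the ring contracts to its minimum radius at
#' cardiac phase 0 (the R-peak analog) with a fast fall (duration
#' `0.25 * (1 - asymmetry)` cycles before phase 0) and a slower
#' half-cosine recovery (`0.25 * (1 + asymmetry)` after), then rests at
#' its diastolic baseline for the remaining half cycle — the short-lived
#' systolic event within each cycle that makes systolic frames globally
#' transient, anchoring the similarity-signal minima at the R-peak
#' analog.
#'
#' @param phase Cardiac phases in `[0, 1)` (any real values are wrapped).
#' @param asymmetry Shape parameter in `[0, 1)`; 0 gives a symmetric bump.
#' @return Values in `[-1, 0]`: 0 at baseline, -1 at peak contraction.
#' @export
cardiac_waveform <- function(phase, asymmetry = 0.2) {
  s <- phase %% 1
  dur <- 0.5
  dc <- dur / 2 * (1 - asymmetry)   # contraction (fall), before phase 0
  dr <- dur / 2 * (1 + asymmetry)   # relaxation (rise), after phase 0
  w <- numeric(length(s))
  rise <- s < dr
  w[rise] <- -(1 + cos(pi * s[rise] / dr)) / 2
  fall <- s > (1 - dc)
  w[fall] <- -(1 - cos(pi * (s[fall] - (1 - dc)) / dc)) / 2
  w
}

#' Respiratory displacement profile
#'
#' Global vertical displacement concentrated near respiratory phase 0,
#' where the heaviest breathing motion occurs.
#'
#' @param phase Respiratory phases.
#' @param amplitude Peak displacement in pixels.
#' @param width Gaussian width in phase units.
#' @return Displacements in pixels.
#' @export
resp_displacement <- function(phase, amplitude = 3, width = 0.15) {
  amplitude * exp(-(circ_dist(phase, 0) / width)^2)
}

# Render one noise-free frame: bright Gaussian annulus on a dim background,
# optionally translated vertically by the respiratory displacement.
render_frame <- function(cfg, cardiac_phase, resp_disp = 0) {
  geo <- ring_geometry(cfg)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  cy <- (nr + 1) / 2 + resp_disp
  cx <- (nc + 1) / 2
  rc <- geo$r0 + geo$amp * cardiac_waveform(cardiac_phase, cfg$cardiac_asymmetry) +
    (cfg$resp_radius_coupling %||% 0) * resp_disp
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  rho <- sqrt(x^2 + y^2)
  0.15 + 0.75 * exp(-(rho - rc)^2 / (2 * geo$sigma_r^2))
}

#' Simulate a synthetic cardiac ultrasound video with ground truth
#'
#' Generates a quasi-periodic grayscale video together with the exact
#' per-frame cardiac and respiratory phases and the R-peak frame indices
#' (frames where the cardiac phase wraps through 0, i.e. peak
#' contraction).  Cardiac phase advances by `heart_rate / (60 * fps)` per
#' frame, exactly; respiration starts at phase 0.5 so heavy motion does
#' not sit on the video edges.  Speckle is multiplicative with unit mean
#' (half the sum of two squared standard normals, an Exp(1) variate),
#' applied last; intensities are clipped to `[0, 1]`.
#'
#' @param config A [sim_config()].
#' @return A list of class `echo_sim` with `video` (an `echo_video`) and
#'   `truth` (list: `cardiac_phase`, `resp_phase`, `r_peak_frames`
#'   (1-based), `resp_disp` in pixels, `config`).
#' @export
simulate_video <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_frames
  step_h <- config$heart_rate / (60 * config$fps)
  step_r <- config$resp_rate / (60 * config$fps)
  unwrapped <- (seq_len(n) - 1) * step_h
  cardiac <- unwrapped %% 1
  resp <- (0.5 + (seq_len(n) - 1) * step_r) %% 1
  disp <- resp_displacement(resp, config$resp_amplitude, config$resp_width)

  frames <- array(0, dim = c(config$image_shape, n))
  npix <- prod(config$image_shape)
  for (t in seq_len(n)) {
    img <- render_frame(config, cardiac[t], disp[t])
    if (config$speckle_level > 0) {
      g1 <- rnorm(npix); g2 <- rnorm(npix)
      noise <- (g1^2 + g2^2) / 2          # Exp(1), unit mean
      img <- img * (1 + config$speckle_level * (noise - 1))
    }
    frames[, , t] <- pmin(pmax(img, 0), 1)
  }

  r_peaks <- c(1L, 1L + which(floor(unwrapped[-1] + 1e-12) >
                                floor(unwrapped[-n] + 1e-12)))
  structure(
    list(video = video_sequence(frames, config$fps),
         truth = list(cardiac_phase = cardiac, resp_phase = resp,
                      r_peak_frames = r_peaks, resp_disp = disp,
                      config = config)),
    class = "echo_sim")
}

#' Render the noise-free ground-truth cardiac cycle
#'
#' Frames of one cardiac cycle at the requested phases, with no speckle
#' and no respiratory displacement — the reference against which
#' reconstructed single-cycle videos are scored.
#'
#' @param config A [sim_config()].
#' @param phases Cardiac phases in `[0, 1)`.
#' @return An `echo_video` whose frame `i` is the clean image at
#'   `phases[i]`.
#' @export
render_cycle <- function(config, phases) {
  stopifnot(length(phases) >= 2, all(phases >= 0), all(phases < 1))
  frames <- array(0, dim = c(config$image_shape, length(phases)))
  for (i in seq_along(phases))
    frames[, , i] <- render_frame(config, phases[i], 0)
  video_sequence(frames, config$fps)
}
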