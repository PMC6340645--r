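#' Fit the Nadaraya-Watson phase-reconstruction model
#'
#' The model reconstructs the image at any cardiac phase as a
#' kernel-weighted average of all frames, with a bivariate kernel: an RBF
#' in circular cardiac-phase distance (bandwidth
#' `sigma_phi = k_phi * median consecutive phase step`) times an RBF in
#' similarity-signal distance from the LOWESS prediction (bandwidth
#' `sigma_L = k_L * robust sigma of the non-respiratory frames`).  The
#' second factor is what suppresses frames with heavy respiratory motion
#' even when their cardiac phase matches the target.
#'
#' @param video The `echo_video` the phases were estimated from.
#' @param decomp The `echo_decomp` (provides the similarity signal and the
#'   heart-beat residual used to measure the native cycle length).
#' @param phases An `echo_phases`.
#' @param gating An `echo_gating`.
#' @param k_phi Phase-bandwidth constant (default 0.4).
#' @param k_L Similarity-bandwidth constant (default 2.0).
#' @return An object of class `echo_recon_model`.
#' @export
fit_reconstruction <- function(video, decomp, phases, gating,
                               k_phi = 0.4, k_L = 2.0) {
  stopifnot(inherits(video, "echo_video"), inherits(decomp, "echo_decomp"),
            inherits(phases, "echo_phases"), inherits(gating, "echo_gating"))
  n <- video$n_frames
  ph <- phases$cardiac_phase
  step <- stats::median(circ_dist(ph[-1], ph[-n]))
  if (step == 0) stop_echogate("zero median phase step: the video appears frozen")
  sigma_phi <- k_phi * step

  nonresp <- setdiff(seq_len(n), gating$respiratory)
  if (length(nonresp) < 3)
    stop_echogate("fewer than 3 non-respiratory frames; cannot set sigma_L")
  sigma_L <- k_L * robust_sigma(gating$residuals[nonresp])
  # Degeneracy guard: a noiseless video has (near-)zero residual scale.
  floor_L <- 1e-6 * max(diff(range(decomp$u_hat)), .Machine$double.eps)
  sigma_L <- max(sigma_L, floor_L)

  heart_hz <- dominant_frequency(decomp$r_heart, video$fps)
  if (heart_hz <= 0) stop_echogate("no dominant cardiac frequency found")
  structure(list(
    frames = frame_matrix(video), shape = video$shape, fps = video$fps,
    cardiac_phase = ph, u_hat = decomp$u_hat,
    lowess_model = gating$lowess_model,
    sigma_phi = sigma_phi, sigma_L = sigma_L, k_phi = k_phi, k_L = k_L,
    frames_per_cycle = video$fps / heart_hz),
    class = "echo_recon_model")
}

#' Reconstruct the image at a cardiac phase
#'
#' Direct evaluation of the kernel-regression estimate: every pixel of
#' the output is a convex combination of the input frames' pixels, with
#' weights `exp(-d_phi^2 / (2 sigma_phi^2)) * exp(-(L(phi) - u_hat)^2 /
#' (2 sigma_L^2))` where `d_phi` is the circular phase distance.  The sum
#' runs over all frames (optionally a subset); the similarity kernel is
#' what de-weights respiratory frames.
#'
#' @param model An `echo_recon_model`.
#' @param phi Target cardiac phase in `[0, 1)`.
#' @param kernel `"bivariate"` (default) or `"phase_only"` (drops the
#'   similarity factor — the univariate baseline).
#' @param include Optional frame indices to restrict the sum to.
#' @return A rows-by-cols image matrix.
#' @export
reconstruct_phase <- function(model, phi, kernel = c("bivariate", "phase_only"),
                              include = NULL) {
  stopifnot(inherits(model, "echo_recon_model"))
  if (phi < 0 || phi >= 1) stop_echogate("target phase must lie in [0, 1)")
  kernel <- match.arg(kernel)
  w <- reconstruction_weights(model, phi, kernel)
  if (!is.null(include)) {
    mask <- logical(length(w)); mask[include] <- TRUE
    w[!mask] <- 0
  }
  total <- sum(w)
  if (total < 1e-12)
    stop_echogate(paste0(
      "total kernel weight %.3g < 1e-12 at phase %.4f; ",
      "increase the bandwidths (k_phi, k_L)"), total, phi)
  w <- w / total
  img <- as.numeric(w %*% model$frames)
  matrix(img, model$shape[1], model$shape[2])
}

reconstruction_weights <- function(model, phi, kernel = "bivariate") {
  dphi <- circ_dist(phi, model$cardiac_phase)
  w <- exp(-dphi^2 / (2 * model$sigma_phi^2))
  if (kernel == "bivariate") {
    Lphi <- predict(model$lowess_model, phi)
    w <- w * exp(-(Lphi - model$u_hat)^2 / (2 * model$sigma_L^2))
  }
  w
}

#' Reconstruct a single-cycle video at a temporal magnification
#'
#' Evenly spaced phases starting at 0; the frame count is
#' `round(magnification * native frames-per-cycle)`, the native cycle
#' length being the frame rate over the dominant cardiac frequency of the
#' heart-beat residual.
#'
#' @param model An `echo_recon_model`.
#' @param magnification Positive temporal magnification factor.
#' @param kernel Passed to [reconstruct_phase()].
#' @return An object of class `echo_cycle`: `video` (an `echo_video` at
#'   `magnification * fps`), `phase_grid`, `magnification`.
#' @export
single_cycle <- function(model, magnification = 1,
                         kernel = c("bivariate", "phase_only")) {
  stopifnot(inherits(model, "echo_recon_model"))
  if (magnification <= 0) stop_echogate("magnification must be positive")
  kernel <- match.arg(kernel)
  n <- max(2L, as.integer(round(magnification * model$frames_per_cycle)))
  grid <- (seq_len(n) - 1) / n
  frames <- array(0, dim = c(model$shape, n))
  for (i in seq_len(n))
    frames[, , i] <- reconstruct_phase(model, grid[i], kernel)
  structure(list(video = video_sequence(frames, model$fps * magnification),
                 phase_grid = grid, magnification = magnification,
                 kernel = kernel),
            class = "echo_cycle")
}

#' @export
print.echo_recon_model <- function(x, ...) {
  cat(sprintf(
    "<echo_recon_model> %d frames, sigma_phi = %.4g, sigma_L = %.4g, %.2f frames/cycle\n",
    nrow(x$frames), x$sigma_phi, x$sigma_L, x$frames_per_cycle))
  invisible(x)
}
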