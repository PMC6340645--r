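#' Reference cardiac phase from R-peak annotations
#'
#' Piecewise-linear phase ramp: 0 at each R-peak frame, rising linearly
#' to 1 at the next peak.  Frames before the first or after the last peak
#' are flagged out-of-support.
#'
#' @param r_peak_frames Strictly increasing frame indices (1-based), >= 2.
#' @param n_frames Total number of frames.
#' @return An object of class `echo_refphase`: `phase` (length
#'   `n_frames`, NA out of support), `in_support` (logical),
#'   `r_peak_frames`.
#' @export
ecg_reference_phase <- function(r_peak_frames, n_frames) {
  r <- as.numeric(r_peak_frames)
  if (length(r) < 2) stop_echogate("need >= 2 R-peaks, got %d", length(r))
  if (any(diff(r) <= 0)) stop_echogate("R-peak frames must be strictly increasing")
  t <- seq_len(n_frames)
  phase <- rep(NA_real_, n_frames)
  for (i in seq_len(length(r) - 1)) {
    lo <- r[i]; hi <- r[i + 1]
    sel <- t >= lo & t < hi
    phase[sel] <- (t[sel] - lo) / (hi - lo)
  }
  phase[t == r[length(r)]] <- 0
  in_support <- !is.na(phase)
  structure(list(phase = phase, in_support = in_support,
                 r_peak_frames = r_peak_frames),
            class = "echo_refphase")
}

#' Circular phase-error statistics
#'
#' Per-frame error is the circular distance `min(|a - b|, 1 - |a - b|)`
#' (maximum 0.5).  With `allow_offset` (default), a single constant
#' circular offset minimizing the mean error is removed first — the
#' image-based estimator carries no absolute phase anchor, so only the
#' relative phase trajectory is meaningful.
#'
#' @param estimated Per-frame estimated phases in `[0, 1)`.
#' @param reference An `echo_refphase` or a numeric phase vector of the
#'   same length.
#' @param allow_offset Remove the best constant circular offset first?
#' @return An object of class `echo_phase_error`: `mean`, `stddev`,
#'   `median`, `iqr`, `range`, `offset`, `errors` (per in-support frame).
#' @export
phase_error <- function(estimated, reference, allow_offset = TRUE) {
  if (inherits(reference, "echo_refphase")) {
    mask <- reference$in_support
    ref <- reference$phase[mask]
    est <- estimated[mask]
  } else {
    ref <- as.numeric(reference)
    est <- estimated
  }
  if (length(est) != length(ref))
    stop_echogate("estimated and reference lengths differ (%d vs %d)",
                  length(est), length(ref))
  if (length(est) == 0) stop_echogate("all frames are out of support")
  offset <- 0
  if (allow_offset) offset <- best_circular_offset(est, ref)
  errors <- circ_dist(est, (ref + offset) %% 1)
  structure(list(mean = mean(errors), stddev = stats::sd(errors),
                 median = stats::median(errors), iqr = stats::IQR(errors),
                 range = range(errors), offset = offset, errors = errors),
            class = "echo_phase_error")
}

# Constant delta minimizing mean circular distance between est and
# ref + delta: coarse grid search then local refinement.
best_circular_offset <- function(est, ref) {
  obj <- function(d) mean(circ_dist(est, (ref + d) %% 1))
  grid <- seq(0, 1, length.out = 1001)[-1001]
  vals <- vapply(grid, obj, numeric(1))
  d0 <- grid[which.min(vals)]
  opt <- stats::optimize(obj, interval = c(d0 - 0.002, d0 + 0.002))
  if (opt$objective < min(vals)) opt$minimum %% 1 else d0
}

#' @export
print.echo_phase_error <- function(x, ...) {
  cat(sprintf(
    "<echo_phase_error> mean %.4f +/- %.4f, median %.4f, IQR %.4f, range [%.4f, %.4f]\n",
    x$mean, x$stddev, x$median, x$iqr, x$range[1], x$range[2]))
  invisible(x)
}

#' Detect estimated cardiac events (phase wrap minima)
#'
#' Frames where the estimated cardiac phase wraps through 0 — the minima
#' of the sawtooth phase signal, the image-based analog of R-peaks.
#'
#' @param estimated_phase Per-frame phases in `[0, 1)`.
#' @return Integer frame indices (1-based).
#' @export
phase_wrap_events <- function(estimated_phase) {
  d <- diff(estimated_phase)
  which(d < -0.5) + 1L
}

#' R-peak frame-localization error
#'
#' Matches each reference R-peak to an estimated phase-wrap event
#' (greedy nearest-neighbor, each event used at most once; reference
#' peaks left unmatched at the sequence edges are dropped) and reports
#' the mean and standard deviation of the absolute frame differences.
#' No sub-frame interpolation: errors are in whole frames.
#'
#' @param estimated_cardiac_phase Per-frame estimated phases.
#' @param r_peak_frames Reference R-peak frame indices (>= 2).
#' @return List: `mean`, `stddev`, `errors`, `events`, `matches`
#'   (data.frame of matched reference/event pairs).
#' @export
r_peak_frame_error <- function(estimated_cardiac_phase, r_peak_frames) {
  if (length(r_peak_frames) < 2) stop_echogate("need >= 2 reference peaks")
  events <- phase_wrap_events(estimated_cardiac_phase)
  if (length(events) == 0) stop_echogate("no estimated phase-wrap events found")
  refs <- as.numeric(r_peak_frames)
  dmat <- abs(outer(refs, as.numeric(events), "-"))
  matches <- data.frame(reference = numeric(0), event = numeric(0),
                        error = numeric(0))
  while (nrow(dmat) > 0 && ncol(dmat) > 0 && is.finite(min(dmat))) {
    idx <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    matches <- rbind(matches, data.frame(
      reference = refs[idx[1]], event = events[idx[2]], error = min(dmat)))
    dmat[idx[1], ] <- Inf
    dmat[, idx[2]] <- Inf
  }
  errors <- matches$error
  list(mean = mean(errors), stddev = stats::sd(errors), errors = errors,
       events = events, matches = matches[order(matches$reference), ])
}

#' Leave-one-out cross-validation of the reconstruction model
#'
#' Per round: pick a random non-respiratory frame, hold it out together
#' with the frame closest to its cardiac phase in every other cycle
#' (cycles delimited by the unwrapped estimated phase), reconstruct at
#' the held-out frame's phase from the remaining frames, and score the
#' normalized correlation against the held-out frame.  Optionally also
#' reports the baseline mean pairwise normalized correlation among the
#' frames at the reference R-peaks.
#'
#' @param video An `echo_video`.
#' @param config A [pipeline_config()].
#' @param n_rounds Number of LOOCV rounds (>= 1).
#' @param seed Integer seed (round-by-round results are reproducible).
#' @param r_peak_frames Optional reference R-peak frames for the baseline.
#' @param pipeline Optional precomputed [run_pipeline()] result (to avoid
#'   refitting when evaluating repeatedly).
#' @return List: `mean`, `stddev`, `ncorr` (per round), `held_out`
#'   (frame per round), `baseline_mean`, `baseline_sd` (NA without
#'   peaks).
#' @export
loocv_reconstruction <- function(video, config = pipeline_config(fps = video$fps),
                                 n_rounds = 10, seed = 1,
                                 r_peak_frames = NULL, pipeline = NULL) {
  stopifnot(n_rounds >= 1)
  pp <- pipeline %||% run_pipeline(video, config)
  n <- video$n_frames
  nonresp <- setdiff(seq_len(n), pp$gating$respiratory)
  unwr <- pp$phases$unwrapped_cardiac
  cyc <- floor(unwr - min(unwr))
  if (length(unique(cyc)) < 3)
    stop_echogate("fewer than 3 cardiac cycles; LOOCV needs >= 3")
  set.seed(seed)
  picks <- sample(nonresp, n_rounds, replace = n_rounds > length(nonresp))
  scores <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    t0 <- picks[r]
    target <- pp$phases$cardiac_phase[t0]
    held <- vapply(unique(cyc), function(cc) {
      cand <- which(cyc == cc)
      cand[which.min(circ_dist(pp$phases$cardiac_phase[cand], target))]
    }, integer(1))
    held <- union(held, t0)
    keep <- setdiff(seq_len(n), held)
    recon <- reconstruct_phase(pp$model, target, include = keep)
    scores[r] <- normalized_correlation(recon, get_frame(video, t0))
  }
  baseline_mean <- NA_real_; baseline_sd <- NA_real_
  if (!is.null(r_peak_frames) && length(r_peak_frames) >= 2) {
    pk <- r_peak_frames
    prs <- utils::combn(seq_along(pk), 2)
    ncs <- apply(prs, 2, function(ij)
      normalized_correlation(get_frame(video, pk[ij[1]]),
                             get_frame(video, pk[ij[2]])))
    baseline_mean <- mean(ncs); baseline_sd <- stats::sd(ncs)
  }
  list(mean = mean(scores), stddev = stats::sd(scores), ncorr = scores,
       held_out = picks, baseline_mean = baseline_mean,
       baseline_sd = baseline_sd)
}

#' Mean per-frame normalized correlation against a reference cycle
#'
#' Reconstructs the image at each reference phase (shifted by a constant
#' offset mapping ground-truth phase to the model's phase convention)
#' and averages the per-frame normalized correlations with the reference
#' frames.
#'
#' @param model An `echo_recon_model`.
#' @param ref_video An `echo_video` holding the reference cycle frames.
#' @param ref_phases Phases of the reference frames in `[0, 1)`.
#' @param offset Constant circular offset: the model is queried at
#'   `(ref_phases + offset) %% 1`.
#' @param kernel Passed to [reconstruct_phase()].
#' @return Scalar mean normalized correlation.
#' @export
cycle_ncorr <- function(model, ref_video, ref_phases, offset = 0,
                        kernel = "bivariate") {
  stopifnot(ref_video$n_frames == length(ref_phases))
  ncs <- vapply(seq_along(ref_phases), function(i) {
    recon <- reconstruct_phase(model, (ref_phases[i] + offset) %% 1,
                               kernel = kernel)
    normalized_correlation(recon, get_frame(ref_video, i))
  }, numeric(1))
  mean(ncs)
}

#' Temporal downsample-and-reconstruct experiment
#'
#' For each decimation factor and each start offset: keep every k-th
#' frame, run the full pipeline on the decimated video, and reconstruct
#' the single cardiac cycle back at the original resolution, scoring the
#' mean per-frame normalized correlation against the supplied
#' ground-truth cycle.  Decimated videos with fewer than 4 frames per
#' cardiac cycle are flagged (scored NA), where phase estimation is
#' expected to break down.
#'
#' @param video The full-rate `echo_video`.
#' @param truth Per-frame ground-truth list (as from [simulate_video()]):
#'   needs `cardiac_phase` and `config` (for the true heart rate).
#' @param gt_cycle An `echo_video` of the ground-truth single cycle.
#' @param gt_phases Phases of the ground-truth cycle frames.
#' @param factors Integer decimation factors (>= 1).
#' @param n_starts Number of random start offsets drawn from the first
#'   `2 * n_starts` frames (default 7 offsets from the first 14 frames,
#'   roughly half a cardiac cycle).
#' @param seed Integer seed for the start offsets.
#' @param config Pipeline configuration template (fps is overridden per
#'   factor).
#' @return List with `table` (data.frame: factor, fps, mean_ncorr,
#'   sd_ncorr, flagged) and `scores` (matrix factor x start).
#' @export
downsample_experiment <- function(video, truth, gt_cycle, gt_phases,
                                  factors = 1:5, n_starts = 7, seed = 1,
                                  config = pipeline_config(fps = video$fps)) {
  stopifnot(all(factors >= 1))
  set.seed(seed)
  window <- min(2L * n_starts, video$n_frames)
  starts <- sample(seq_len(window), n_starts)
  heart_hz <- truth$config$heart_rate / 60
  scores <- matrix(NA_real_, length(factors), n_starts,
                   dimnames = list(paste0("x", factors), NULL))
  flagged <- logical(length(factors))
  for (fi in seq_along(factors)) {
    k <- factors[fi]
    sub_fps <- video$fps / k
    if (sub_fps / heart_hz < 4) {
      flagged[fi] <- TRUE
      next
    }
    for (si in seq_along(starts)) {
      idx <- seq(starts[si], video$n_frames, by = k)
      sub <- subset_video(video, idx, fps = sub_fps)
      cfg <- config; cfg$fps <- sub_fps
      pp <- run_pipeline(sub, cfg)
      pe <- phase_error(pp$phases$cardiac_phase, truth$cardiac_phase[idx],
                        allow_offset = TRUE)
      scores[fi, si] <- cycle_ncorr(pp$model, gt_cycle, gt_phases,
                                    offset = pe$offset)
    }
  }
  tab <- data.frame(
    factor = factors, fps = video$fps / factors,
    mean_ncorr = rowMeans(scores), sd_ncorr = apply(scores, 1, stats::sd),
    flagged = flagged)
  list(table = tab, scores = scores, starts = starts)
}
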