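#' Pipeline configuration
#'
#' Every default matches the published operating point for mouse
#' echocardiography: HP penalty 6400, respiration low-pass 230 BPM,
#' heart band 310-840 BPM, cutoff c = 0.2, gate multiple k = 2.0, kernel
#' constants k_phi = 0.4 and k_L = 2.0.
#'
#' @param fps Frame rate in frames/second (required downstream).
#' @param lambda HP-filter penalty.
#' @param resp_lowpass_bpm Respiration low-pass cutoff.
#' @param heart_band_bpm Heart band `(low, high)` in BPM.
#' @param c Step-1 respiratory-phase cutoff.
#' @param k Step-2 gate multiple.
#' @param k_phi,k_L Kernel bandwidth constants.
#' @param one_sided One-sided step-2 gate?
#' @param lowess_span,lowess_iters LOWESS parameters.
#' @param seed Optional integer seed recorded in the config.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fps = 233, lambda = 6400, resp_lowpass_bpm = 230,
                            heart_band_bpm = c(310, 840), c = 0.2, k = 2.0,
                            k_phi = 0.4, k_L = 2.0, one_sided = TRUE,
                            lowess_span = 0.3, lowess_iters = 3, seed = NULL) {
  structure(list(fps = fps, lambda = lambda,
                 resp_lowpass_bpm = resp_lowpass_bpm,
                 heart_band_bpm = heart_band_bpm, c = c, k = k,
                 k_phi = k_phi, k_L = k_L, one_sided = one_sided,
                 lowess_span = lowess_span, lowess_iters = lowess_iters,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full phase-estimation / gating / reconstruction pipeline
#'
#' Stages in order: inter-frame similarity matrix; HP decomposition and
#' entropy-based row selection; zero-phase band cleanup; Hilbert phase
#' estimation; two-step respiratory gating; kernel-regression model fit.
#' The first failing stage aborts with its name and cause.
#'
#' @param video An `echo_video`.
#' @param config A [pipeline_config()]; `config$fps` defaults to the
#'   video's rate when NULL.
#' @param verbose Print per-stage timings?
#' @return List of class `echo_pipeline`: `similarity`, `decomp`,
#'   `phases`, `gating`, `model`, `config`, `log` (data.frame of stage
#'   timings).
#' @export
run_pipeline <- function(video, config = pipeline_config(fps = video$fps),
                         verbose = FALSE) {
  stopifnot(inherits(video, "echo_video"))
  config$fps <- config$fps %||% video$fps
  fps <- config$fps
  log <- data.frame(stage = character(0), seconds = numeric(0))
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_echogate("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    dt <- proc.time()[["elapsed"]] - t0
    log <<- rbind(log, data.frame(stage = stage, seconds = dt))
    if (verbose) message(sprintf("[%s] %.2fs", stage, dt))
    out
  }
  S <- tick("similarity", similarity_matrix(video))
  decomp <- tick("decomposition", select_row(S, lambda = config$lambda, fps = fps))
  decomp <- tick("bandlimit", bandlimit(
    decomp, band_spec(config$resp_lowpass_bpm, config$heart_band_bpm), fps))
  phases <- tick("phases", estimate_phases(decomp, fps))
  gating <- tick("gating", gate_video(
    decomp$u_hat, phases, c = config$c, k = config$k,
    one_sided = config$one_sided, span = config$lowess_span,
    iters = config$lowess_iters))
  model <- tick("model", fit_reconstruction(
    video, decomp, phases, gating, k_phi = config$k_phi, k_L = config$k_L))
  if (verbose)
    message(sprintf("selected row %d (entropy %.3f)", decomp$row_index,
                    decomp$entropy_per_row[decomp$row_index]))
  structure(list(similarity = S, decomp = decomp, phases = phases,
                 gating = gating, model = model, config = config, log = log),
            class = "echo_pipeline")
}

#' @export
print.echo_pipeline <- function(x, ...) {
  cat(sprintf("<echo_pipeline> row %d selected; %d/%d frames gated; %.2f frames/cycle\n",
              x$decomp$row_index, length(x$gating$respiratory),
              x$gating$n_frames, x$model$frames_per_cycle))
  invisible(x)
}
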