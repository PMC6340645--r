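#' Step 1: respiratory-phase cutoff gate
#'
#' Discards the frames whose respiratory phase lies within `c` of phase 0
#' (on either side of the wrap), where the heaviest respiratory motion
#' occurs: `{t : phi_resp(t) < c or phi_resp(t) > 1 - c}`.
#'
#' @param resp_phase Per-frame respiratory phases in `[0, 1)`.
#' @param c Cutoff in `[0, 0.5)`; 0.2 by default (chosen empirically for
#'   mouse data).
#' @return Integer vector of discarded frame indices (1-based).
#' @export
cutoff_gate <- function(resp_phase, c = 0.2) {
  if (any(resp_phase < 0 | resp_phase >= 1))
    stop_echogate("respiratory phases must lie in [0, 1)")
  if (c < 0 || c >= 0.5)
    stop_echogate("cutoff c must lie in [0, 0.5); c = %g would discard everything", c)
  which(resp_phase < c | resp_phase > (1 - c))
}

#' Periodic robust LOWESS fit of similarity versus cardiac phase
#'
#' Fits Cleveland's LOWESS (tricube-weighted local linear regression with
#' bisquare robustifying iterations) to `(phase, value)` pairs.  Cardiac
#' phase is circular, so the training pairs are replicated at `phase - 1`
#' and `phase + 1` before fitting and predictions are taken on `[0, 1)`;
#' the span is interpreted as a fraction of the original points (the
#' internal fraction on the tripled data is `span / 3`).
#'
#' @param phase Cardiac phases in `[0, 1)` of the training frames.
#' @param value Similarity-signal values, same length.
#' @param span Neighborhood fraction of the training points (default 0.3).
#' @param iters Robustifying iterations (default 3).
#' @return An object of class `echo_lowess`; use [predict.echo_lowess()]
#'   to evaluate `L(phi)` at any phase.
#' @export
lowess_fit <- function(phase, value, span = 0.3, iters = 3) {
  stopifnot(length(phase) == length(value))
  if (length(phase) < 10)
    stop_echogate("lowess_fit needs >= 10 points, got %d", length(phase))
  if (any(phase < 0 | phase >= 1)) stop_echogate("phases must lie in [0, 1)")
  sp <- sort(phase)
  gaps <- diff(c(sp, sp[1] + 1))         # circular gaps
  if (max(gaps) > 0.25)
    stop_echogate("cardiac-phase coverage has a gap of %.3f (> 0.25) after %.3f",
                  max(gaps), sp[which.max(gaps)])
  x <- c(phase - 1, phase, phase + 1)
  y <- rep(value, 3)
  fit <- stats::lowess(x, y, f = span / 3, iter = iters)
  fun <- stats::approxfun(fit$x, fit$y, rule = 2, ties = mean)
  structure(list(fun = fun, span = span, iters = iters,
                 phase = phase, value = value),
            class = "echo_lowess")
}

#' Predict from a periodic LOWESS model
#' @param object An `echo_lowess`.
#' @param phi Cardiac phases (wrapped onto `[0, 1)`).
#' @param ... Unused.
#' @return Predicted similarity values.
#' @export
predict.echo_lowess <- function(object, phi, ...) {
  object$fun(phi %% 1)
}

#' Robust standard-deviation estimate from residuals
#'
#' Scaled median absolute deviation, `1.4826 * median(|r - median(r)|)`,
#' consistent for the standard deviation under normality.
#'
#' @param residuals Numeric vector, length >= 3.
#' @return Nonnegative scalar `sigma_L`.
#' @export
robust_sigma <- function(residuals) {
  if (length(residuals) < 3)
    stop_echogate("robust_sigma needs >= 3 residuals, got %d", length(residuals))
  stats::mad(residuals)                  # constant = 1.4826, center = median
}

#' Step 2: LOWESS outlier gate
#'
#' Gates out frames whose similarity-signal value departs from the LOWESS
#' prediction at their cardiac phase by more than `k * sigma_L`.  The
#' default is one-sided (only frames *below* the fit, since respiratory
#' motion depresses similarity); `one_sided = FALSE` applies the
#' absolute-value rule.
#'
#' @param u_hat Similarity signal per frame.
#' @param cardiac_phase Cardiac phases per frame.
#' @param lowess_model An `echo_lowess`.
#' @param sigma_L Robust scale from [robust_sigma()].
#' @param k Gate multiple (> 0); 2.0 approximates a 95% band.
#' @param one_sided Gate only below the fit? (default TRUE)
#' @return Integer vector of gated frame indices (1-based).
#' @export
gate_respiratory <- function(u_hat, cardiac_phase, lowess_model, sigma_L,
                             k = 2, one_sided = TRUE) {
  if (k <= 0) stop_echogate("gate multiple k must be positive, got %g", k)
  dev <- predict(lowess_model, cardiac_phase) - u_hat
  if (one_sided) which(dev > k * sigma_L) else which(abs(dev) > k * sigma_L)
}

#' Two-step respiratory gating of a video
#'
#' Runs the respiratory-phase cutoff (step 1), fits the periodic LOWESS
#' model of similarity versus cardiac phase on the retained frames, and
#' applies the robust `k * sigma` outlier gate (step 2).  The robust
#' scale is computed from the residuals of *all* frames by default.
#'
#' @param u_hat Selected similarity signal per frame.
#' @param phases An `echo_phases`.
#' @param c Step-1 cutoff (default 0.2).
#' @param k Step-2 gate multiple (default 2.0).
#' @param one_sided One-sided step-2 gate? (default TRUE)
#' @param span,iters LOWESS parameters (see [lowess_fit()]).
#' @param sigma_all_frames Compute `sigma_L` from all frames (TRUE,
#'   default) or only frames surviving step 1?
#' @return An object of class `echo_gating`: `f_cutoff`, `f_resp`
#'   (1-based index vectors), `lowess_model`, `sigma_L`, `c`, `k`,
#'   `one_sided`, `residuals` (per frame, fit minus signal), and
#'   `respiratory` (union of the two sets).
#' @export
gate_video <- function(u_hat, phases, c = 0.2, k = 2, one_sided = TRUE,
                       span = 0.3, iters = 3, sigma_all_frames = TRUE) {
  stopifnot(inherits(phases, "echo_phases"))
  n <- length(u_hat)
  stopifnot(length(phases$cardiac_phase) == n)
  f_cutoff <- cutoff_gate(phases$resp_phase, c)
  keep <- setdiff(seq_len(n), f_cutoff)
  if (length(keep) < 10)
    stop_echogate("only %d frames survive the cutoff gate; need >= 10", length(keep))
  model <- lowess_fit(phases$cardiac_phase[keep], u_hat[keep],
                      span = span, iters = iters)
  resid <- predict(model, phases$cardiac_phase) - u_hat
  sigma_L <- robust_sigma(if (sigma_all_frames) resid else resid[keep])
  f_resp <- gate_respiratory(u_hat, phases$cardiac_phase, model, sigma_L,
                             k = k, one_sided = one_sided)
  structure(list(f_cutoff = f_cutoff, f_resp = f_resp,
                 lowess_model = model, sigma_L = sigma_L, c = c, k = k,
                 one_sided = one_sided, residuals = resid,
                 respiratory = sort(union(f_cutoff, f_resp)), n_frames = n),
            class = "echo_gating")
}

#' @export
print.echo_gating <- function(x, ...) {
  cat(sprintf(
    "<echo_gating> %d/%d frames gated (step1: %d, step2: %d), sigma_L = %.4g\n",
    length(x$respiratory), x$n_frames, length(x$f_cutoff), length(x$f_resp),
    x$sigma_L))
  invisible(x)
}
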