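---
title: "echogate: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{echogate: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Preclinical echocardiography of small animals records a two-dimensional
grayscale video of a beating heart at a few hundred frames per second.
Mice have heart rates of 310–840 BPM and respiratory rates of 80–230 BPM,
so a 233 FPS acquisition yields only ~27 frames per cardiac cycle, and every
frame sits at an unknown position within *two* interleaved physiological
cycles.  Hardware phase references (ECG electrodes, respiration pillows) are
cumbersome in small animals.  `echogate` estimates both phases
retrospectively, from the images alone, then uses them to (a) discard
frames corrupted by respiratory motion and (b) pool frames across many
heart beats into a single-cycle video at arbitrary temporal magnification.

## The pipeline

1. **Inter-frame similarity.** The video becomes an `N x N` matrix `S` of
   pairwise normalized correlations (Pearson correlation of flattened
   pixels).  Each row of `S` is a univariate time series that inherits the
   video's quasi-periodicity: a slow respiratory undulation superposed on a
   fast cardiac oscillation.  Normalized correlation is invariant to global
   affine intensity changes, so gain/brightness drift does not disturb it.

2. **Trend/residual decomposition.** Each row `u(t)` is split by the
   Hodrick–Prescott filter, `min_tau sum (u - tau)^2 + lambda sum (d2
   tau)^2`, into a smooth trend `tau_resp(t)` (respiration) and a residual
   `r_heart(t) = u - tau` (heart beat).  `lambda = 6400` is the default
   operating point at these frame rates; the trend transfer gain is ~0.98
   at 93 BPM and ~0.05 at 512 BPM, which is what makes the decoupling work.
   The solve is the sparse SPD system `(I + lambda D'D) tau = u` with
   natural boundaries; a dense direct solve serves as the test oracle.

3. **Row selection by spectral entropy.** For each row the periodogram of
   the cardiac residual is normalized to a probability distribution and its
   Shannon entropy computed (natural log; any base preserves the argmin).
   The row with the smallest entropy — the most narrow-band, sinusoid-like
   residual — is selected; ties break to the lowest index.  The
   periodogram is a mean-removed FFT periodogram zero-padded to the next
   power of two at least `4N`, so rows of equal length are compared on one
   stable grid.

4. **Band cleanup.** The trend is low-pass filtered at 230 BPM and the
   residual band-pass filtered to 310–840 BPM.  Because the instantaneous
   phase must not be delayed, filtering is *zero-phase*: the FFT is
   multiplied by an order-4 Butterworth amplitude response (a real, even
   function of frequency introduces no phase shift); the band-pass
   response is renormalized to unity peak gain so an in-band tone passes
   with <1% ripple, while a 512 BPM tone is attenuated >20 dB by the
   230 BPM low-pass.  No time-domain IIR filtering package is required and
   the result is deterministic to machine precision.

5. **Hilbert phase.** The angle of the analytic signal `x + iH(x)`
   (computed by the standard FFT method, quadrant-aware `atan2`) is mapped
   from `[-pi, pi)` to `[0, 1)` by `(phi + pi) / (2 pi)`, which places the
   local minima of a near-sinusoid at phase 0.  The mean is removed first:
   a DC offset corrupts the angle.  Cardiac phase comes from the residual,
   respiratory phase from the trend.

6. **Two-step respiratory gating.** Step 1 discards frames with
   respiratory phase within `c = 0.2` of the wrap (the heavy-motion
   interval around the respiration-signal minima).  Step 2 fits a robust
   periodic LOWESS of similarity versus cardiac phase on the retained
   frames and gates frames whose similarity falls below the fit by more
   than `k = 2` times a scaled-MAD robust sigma (`1.4826 * MAD`).  The
   gate is one-sided by default — respiratory motion *depresses*
   similarity — with a two-sided option.

7. **Kernel-regression reconstruction.** The image at any cardiac phase is
   the Nadaraya–Watson average of all frames under a product of two RBF
   kernels: circular phase distance (bandwidth `0.4 x` the median
   consecutive phase step) and similarity distance from the LOWESS
   prediction (bandwidth `2 x` the robust sigma of the non-respiratory
   frames).  The second factor is what starves respiratory frames of
   weight even at matching cardiac phase.  Single-cycle videos sample
   `round(magnification x frames-per-cycle)` evenly spaced phases, the
   native cycle length read off the residual's dominant frequency.

## Phase-polarity anchoring (a design choice beyond the published method)

The conventions "respiratory phase 0 = heaviest motion" and "cardiac phase
minima = R-peaks" implicitly assume that the *selected* similarity row dips
during transient frames.  That holds when the reference frame (the selected
row) is a quiescent diastolic one — but nothing in the entropy criterion
guarantees it.  If the winner happens to be a systolic or
respiratory-displaced frame, its similarity signal *peaks* where that
transient state recurs, and both phase conventions invert by half a cycle.

`estimate_phases(orient = TRUE)` resolves the sign without constants or
thresholds: the column-mean similarity signal dips at globally transient
frames no matter which row is selected, so each component of the selected
row is correlated against the corresponding Hodrick–Prescott component of
the column mean, and a negative correlation flips that component's phase by
0.5.  For a quiescent winner the flip is a no-op.  Disable with
`orient = FALSE` to reproduce the raw convention.

## The synthetic world

`simulate_video()` generates the stated world used by every end-to-end
test: 300 frames at 233 FPS (1.29 s), heart at 512 BPM (11.0 cycles,
27.3 frames/cycle), respiration at 93.2 BPM (exactly 2 cycles — 93.2 =
2 x 60 x 233 / 300), 64 x 64 pixels, seed 1.

* **Heart**: a bright Gaussian annulus (baseline radius 19.2 px, wall
  sigma 2.5 px) whose radius follows an asymmetric raised-cosine bump —
  contraction over 0.2 of the cycle before phase 0, relaxation over 0.3
  after, baseline for the remaining half cycle.  Peak contraction shrinks
  the radius 25%.  The short-lived systolic excursion is what anchors the
  similarity-signal minima at the R-peak analog, mirroring the behavior
  the method exhibits on real data; the asymmetry makes the direction of
  time observable.
* **Respiration**: a global vertical translation `3 * exp(-(d(phi,0)/0.15)^2)`
  pixels, concentrated near respiratory phase 0 (≈30% duty cycle).  A
  width of 0.15 keeps the heavy-motion interval inside the `c = 0.2`
  cutoff window while keeping the respiration trend near-sinusoidal
  enough for a stable Hilbert phase.  In addition, 0.15 px of apparent
  ring-radius change per pixel of displacement models the out-of-plane
  slice shift of a breathing chest.  Without this coupling a *pure* rigid
  translation has an unphysical side effect: the similarity rows of
  displaced frames become artificially smooth (translation acts as a
  radial blur on the ring correlation), and the entropy criterion then
  systematically selects displaced reference frames whose respiration
  signature is weak — a pathology of the toy geometry, not of the method.
* **Speckle**: multiplicative unit-mean noise, `I * (1 + s*(e - 1))` with
  `e ~ Exp(1)` built from squared standard-normal pairs and `s = 0.2`.
  This reproduces the heavy-tailed, intensity-proportional character of
  ultrasound speckle but not its spatial grain or temporal persistence.

Ground truth is exact by construction: cardiac phase advances
`heart_rate/(60 fps)` per frame, R-peak frames are the wraps through 0,
and the per-frame respiratory displacement is recorded.

**What a green test does and does not establish.**  The simulator shares
the paper-level *structure* of real data (two incommensurate
quasi-periodicities, localized respiratory corruption, multiplicative
noise) but none of its anatomical richness (no valves, papillary muscles,
out-of-plane cardiac motion, probe drift, arrhythmia).  Passing tests
demonstrate internal correctness and the qualitative orderings reported on
real data (LOOCV beats the R-peak-frame baseline; the bivariate kernel
beats the phase-only kernel; reconstruction quality degrades with temporal
downsampling).  They do not certify performance on animal data, and the
published real-data error magnitudes are used only as *scales* for the
synthetic thresholds.

## Numerical choices and degenerate inputs

* HP filter: `lambda = 0` returns the input exactly; linear series are
  reproduced for any `lambda`; the mean is always preserved (constants are
  in the null space of the penalty).
* Periodogram entropy uses `0 log 0 = 0`; all-zero series are an error,
  not silently zero.
* LOWESS periodicity: training pairs are replicated at `phi - 1` and
  `phi + 1`, the span (default 0.3, 3 robustness iterations) counted as a
  fraction of the *original* points; a circular phase gap > 0.25 is an
  error naming the gap.  The fit is `stats::lowess` — Cleveland's
  tricube/bisquare algorithm, exactly the method named.
* `sigma_L = 0` (noiseless data) is floored at `1e-6` of the similarity
  signal's range before reconstruction, so Eq.-style weights never divide
  by zero; a total kernel weight below `1e-12` raises an error advising a
  larger bandwidth rather than silently falling back.
* Reconstruction sums over *all* frames by default (the similarity kernel
  down-weights respiratory frames); LOOCV uses the `include` argument to
  restrict the sum.
* Rounding of single-cycle frame counts is `round(mag x frames/cycle)`;
  the published per-magnification counts are mutually inconsistent with
  any single rounding rule, so the rule, not the printed counts, is the
  contract.
* Frame indices are 1-based inside R (ecosystem convention) and 0-based in
  every CSV/JSON written to disk.
* Video I/O uses a directory of plain-text PGM (P2) frames plus a JSON
  sidecar for the frame rate — the only image format that needs no binary
  reader in the target environment.

## Known limitations

* Strong periodicity assumptions: arrhythmic subjects violate the
  narrow-band premise of the Hilbert phase.
* Whole-frame correlation assumes a large fraction of the image pulsates;
  a small heart in a large static field weakens the cardiac signature.
* The Hilbert phase is least reliable within roughly one period of the
  video edges; with only ~2 respiratory cycles per acquisition this
  affects the respiratory phase most (the spec-level phase-accuracy
  assertions therefore exclude edge windows).
* Kernel averaging blurs very fast structures at high magnification; no
  deblurring or registration-based averaging is attempted.
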