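# echogate

Image-only cardiorespiratory phase estimation, respiratory gating and
temporal super-resolution for cardiac ultrasound video.

## Why

In small-animal echocardiography (mouse hearts beat at 310–840 BPM,
respiration at 80–230 BPM) every video frame sits at an unknown position in
two interleaved physiological cycles, and attaching ECG/respiration
hardware is cumbersome. `echogate` recovers both phases retrospectively
from the pixels alone:

1. the video becomes an `N x N` inter-frame normalized-correlation matrix
   `S`, whose rows are univariate time series carrying both periodicities;
2. the Hodrick–Prescott filter (penalty `λ = 6400` on squared second
   differences) splits each row into a respiratory trend `τ̂_resp(t)` and a
   cardiac residual `r̂_heart(t)`; the row whose residual has the lowest
   periodogram entropy is selected;
3. after zero-phase band cleanup (low-pass 230 BPM; band-pass 310–840 BPM)
   the instantaneous phases `φ̂(t) ∈ [0, 1)` are the angles of the analytic
   (Hilbert) signals;
4. frames with heavy respiratory motion are gated in two steps — a
   respiratory-phase cutoff (`c = 0.2` around the respiration minima), then
   a robust periodic LOWESS fit of similarity vs cardiac phase with a
   `k = 2` scaled-MAD outlier gate;
5. the image at any cardiac phase is reconstructed by Nadaraya–Watson
   kernel regression,
   `M(φ) = Σ_t K(φ, φ̂(t)) I(t) / Σ_t K(φ, φ̂(t))`, with a bivariate RBF
   kernel in (circular phase distance) × (similarity distance from the
   LOWESS prediction), bandwidths `σ_φ = 0.4 ×` median phase step and
   `σ_L = 2 ×` robust σ of non-respiratory frames — yielding single-cycle
   videos at arbitrary temporal magnification.

A bundled simulator (`simulate_video()`) generates ultrasound-like videos
(pulsating speckled ring + localized respiratory displacement) with exact
ground-truth phases, so the whole pipeline is testable without animal data.

## Worked example

```r
library(echogate)

sim <- simulate_video(sim_config())   # 300 frames, 233 FPS, 512/93.2 BPM, seed 1
pp  <- run_pipeline(sim$video)
pp
#> <echo_pipeline> row 57 selected; 93/300 frames gated; 27.31 frames/cycle

phase_error(pp$phases$cardiac_phase, sim$truth$cardiac_phase)
#> <echo_phase_error> mean 0.0230 +/- 0.0124, median 0.0248, IQR 0.0193, range [0.0000, 0.0555]

r_peak_frame_error(pp$phases$cardiac_phase, sim$truth$r_peak_frames)$mean
#> [1] 1

cv <- loocv_reconstruction(sim$video, n_rounds = 10, seed = 1,
                           r_peak_frames = sim$truth$r_peak_frames, pipeline = pp)
c(loocv = cv$mean, baseline = cv$baseline_mean)
#>     loocv  baseline
#> 0.9538837 0.8842191

cycle <- single_cycle(pp$model, magnification = 4)
cycle$video
#> <echo_video> 109 frames of 64x64 px at 932 fps (0.117 s)
```

Reading: the estimated cardiac phase tracks the simulated truth to 0.023
cycles on average (the published real-data scale is 0.03–0.06); estimated
phase minima land within 1 frame of the true R-peak frames; leave-one-out
reconstruction correlates 0.95 with held-out frames, beating the 0.88
baseline correlation among R-peak frames (the published ordering is
0.83 vs 0.72); and a 4× single-cycle video re-samples the 27.3-frame cycle
at 109 frames.

## Command line

```sh
echogate simulate    --config cfg.json --out-video vid/ --out-truth truth.csv --out-rpeaks rp.csv
echogate phases      --video vid/ --out phases.csv
echogate gate        --video vid/ --c 0.2 --k 2.0 --out gating.csv
echogate reconstruct --video vid/ --magnification 4 --out cycle/
echogate evaluate    --video vid/ --truth truth.csv --rpeaks rp.csv --report report.json
```

Videos are directories of plain-text PGM frames with a `meta.json` frame-rate
sidecar; all CSV/JSON outputs use 0-based frame indices.

## Further reading

`vignettes/echogate-methods.Rmd` documents the model, the synthetic world
and every numerical design choice (zero-phase filtering, phase-polarity
anchoring, degenerate-input handling, known limitations).
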