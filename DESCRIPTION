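Package: echogate
Title: Retrospective Cardiorespiratory Phase Estimation, Gating and
    Temporal Super-Resolution for Cardiac Ultrasound Video
Version: 0.1.0
Authors@R: person("echogate", "developers", role = c("aut", "cre"),
    email = "echogate@example.org")
Description: Image-only estimation of the instantaneous cardiac and
    respiratory phase of every frame in a quasi-periodic grayscale
    ultrasound video.  The video is transformed into an inter-frame
    normalized-correlation similarity matrix, each row of which is a
    univariate time series carrying the cardiorespiratory periodicity.
    A Hodrick-Prescott trend filter decouples the slow respiratory trend
    from the fast cardiac residual, the best row is selected by
    periodogram entropy, and instantaneous phases are read off the angle
    of the analytic (Hilbert-transform) signal.  Frames with heavy
    respiratory motion are gated out by a respiratory-phase cutoff
    followed by a robust LOWESS outlier gate, and a Nadaraya-Watson
    kernel-regression model with a bivariate phase-by-similarity RBF
    kernel reconstructs the image at any cardiac phase, enabling
    single-cycle videos at arbitrary temporal magnification.  A bundled
    synthetic ultrasound simulator with ground-truth phases makes the
    whole pipeline testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
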