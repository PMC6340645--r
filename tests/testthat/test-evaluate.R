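test_that("ECG reference phase is a piecewise-linear ramp with support flags", {
  ref <- ecg_reference_phase(c(1, 11), 15)
  expect_equal(ref$phase[6], 0.5)
  expect_equal(ref$phase[1], 0)
  expect_false(any(ref$in_support[12:15]))
  ref2 <- ecg_reference_phase(c(1, 11, 21), 25)
  expect_equal(ref2$phase[11], 0)              # ramp restarts at each peak
  expect_error(ecg_reference_phase(5, 10), ">= 2")
  expect_error(ecg_reference_phase(c(5, 5), 10), "increasing")
})

test_that("reference phase from true peaks matches the simulator phase", {
  sim <- default_sim()
  ref <- ecg_reference_phase(sim$truth$r_peak_frames, 300)
  step <- sim$truth$config$heart_rate / (60 * 233)
  sel <- ref$in_support
  expect_true(all(circ_dist(ref$phase[sel], sim$truth$cardiac_phase[sel]) <=
                    step + 1e-9))
})

test_that("phase error statistics follow the circular-distance definition", {
  ph <- runif(50)
  pe <- phase_error(ph, ph, allow_offset = FALSE)
  expect_equal(pe$mean, 0)
  expect_equal(pe$range, c(0, 0))
  anti <- phase_error((ph + 0.5) %% 1, ph, allow_offset = FALSE)
  expect_equal(anti$mean, 0.5)
  expect_true(all(pe$errors >= 0 & pe$errors <= 0.5))
  # offset removal cannot hurt
  est <- (ph + 0.17) %% 1
  expect_lte(phase_error(est, ph, TRUE)$mean,
             phase_error(est, ph, FALSE)$mean)
  expect_lt(phase_error(est, ph, TRUE)$mean, 1e-3)
  expect_error(phase_error(ph, ph[1:10]), "lengths")
})

test_that("error metrics are invariant to time reversal with negated phases", {
  set.seed(9)
  est <- runif(80); ref <- runif(80)
  a <- phase_error(est, ref, allow_offset = FALSE)
  b <- phase_error(rev(1 - est) %% 1, rev(1 - ref) %% 1, allow_offset = FALSE)
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$stddev, b$stddev, tolerance = 1e-12)
})

test_that("r-peak localization matches events to references", {
  saw <- function(n, period, start = 0) ((seq_len(n) - 1 - start) / period) %% 1
  ph <- saw(100, 10)
  peaks <- seq(11, 91, by = 10)
  r <- r_peak_frame_error(ph, peaks)
  expect_equal(r$mean, 0)
  expect_equal(r$stddev, 0)
  r1 <- r_peak_frame_error(ph, peaks + 1)      # events uniformly 1 frame early
  expect_equal(r1$mean, 1)
  expect_equal(r1$stddev, 0)
  # invariance to a common frame-index shift (relabelled time axis)
  sub <- 15:100                                # drop a wrap-free prefix
  r2 <- r_peak_frame_error(ph[sub], peaks[peaks >= 21] - 14)
  expect_equal(sort(r2$errors), sort(r$errors[r$matches$reference >= 21]))
  expect_error(r_peak_frame_error(rep(0.4, 50) + (1:50) * 1e-4, c(10, 20)),
               "events")
})

test_that("r-peak localization on the simulated video is frame-accurate", {
  sim <- default_sim()
  pp <- default_pipeline()
  r <- r_peak_frame_error(pp$phases$cardiac_phase, sim$truth$r_peak_frames)
  expect_lte(r$mean, 1.5)
})

test_that("LOOCV reconstruction scores high and is seed-deterministic", {
  sim <- default_sim()
  pp <- default_pipeline()
  cv1 <- loocv_reconstruction(sim$video, n_rounds = 5, seed = 3, pipeline = pp,
                              r_peak_frames = sim$truth$r_peak_frames)
  cv2 <- loocv_reconstruction(sim$video, n_rounds = 5, seed = 3, pipeline = pp,
                              r_peak_frames = sim$truth$r_peak_frames)
  expect_identical(cv1$ncorr, cv2$ncorr)
  expect_gt(cv1$mean, cv1$baseline_mean)
  sim0 <- noiseless_sim()
  cv0 <- loocv_reconstruction(sim0$video, n_rounds = 5, seed = 1)
  expect_gte(cv0$mean, 0.99)
})

test_that("downsampling flags videos with < 4 frames per cardiac cycle", {
  sim <- default_sim()
  ds <- downsample_experiment(sim$video, sim$truth, gt_cycle(),
                              gt_cycle_phases(), factors = c(1, 7),
                              n_starts = 2, seed = 1)
  expect_false(ds$table$flagged[1])
  expect_true(ds$table$flagged[2])
  expect_true(is.na(ds$table$mean_ncorr[2]))
  expect_false(is.na(ds$table$mean_ncorr[1]))
})

test_that("the frame interval of a 233 FPS acquisition is ~4.29 ms", {
  expect_equal(frame_interval_ms(233), 1000 / 233, tolerance = 1e-12)
  expect_equal(round(frame_interval_ms(233), 2), 4.29)
})
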