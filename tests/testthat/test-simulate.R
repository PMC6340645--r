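test_that("simulation configuration is validated", {
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(fps = 0), "fps")
  expect_error(sim_config(heart_rate = -1), "positive")
  expect_error(sim_config(heart_rate = 80, resp_rate = 100), "exceed")
  expect_error(sim_config(image_shape = c(16L, 16L)), "too small")
  expect_error(sim_config(cardiac_asymmetry = 1), "asymmetry")
})

test_that("ground-truth phases advance exactly and peaks are consistent", {
  sim <- default_sim()
  cfg <- sim$truth$config
  step <- cfg$heart_rate / (60 * cfg$fps)
  d <- diff(sim$truth$cardiac_phase) %% 1
  expect_equal(d, rep(step %% 1, cfg$n_frames - 1), tolerance = 1e-12)
  expect_true(all(sim$truth$cardiac_phase >= 0 & sim$truth$cardiac_phase < 1))
  expect_true(all(sim$truth$resp_phase >= 0 & sim$truth$resp_phase < 1))
  # consecutive R-peaks one cycle apart (within a frame), count ~ n*rate/(60*fps)
  cycle_frames <- 60 * cfg$fps / cfg$heart_rate
  expect_true(all(abs(diff(sim$truth$r_peak_frames) - cycle_frames) <= 1))
  expect_equal(length(sim$truth$r_peak_frames),
               round(cfg$n_frames * step), tolerance = 1)
})

test_that("default world spans 2 respiratory and ~11 cardiac cycles", {
  cfg <- sim_config()
  duration <- cfg$n_frames / cfg$fps
  expect_equal(duration * cfg$resp_rate / 60, 2, tolerance = 1e-6)
  expect_equal(duration * cfg$heart_rate / 60, 11, tolerance = 0.05)
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_video(sim_config(n_frames = 40L))
  b <- simulate_video(sim_config(n_frames = 40L))
  c <- simulate_video(sim_config(n_frames = 40L, seed = 99L))
  expect_identical(a$video$frames, b$video$frames)
  expect_false(identical(a$video$frames, c$video$frames))
})

test_that("noiseless motion-free frames at equal cardiac phase are identical", {
  # 233/512-ish rates never revisit a phase exactly; force a rational ratio:
  # heart period exactly 20 frames.
  cfg <- sim_config(n_frames = 60L, fps = 200, heart_rate = 600,
                    speckle_level = 0, resp_amplitude = 0)
  sim <- simulate_video(cfg)
  expect_equal(sim$truth$cardiac_phase[1], sim$truth$cardiac_phase[21])
  expect_identical(get_frame(sim$video, 1), get_frame(sim$video, 21))
  expect_identical(get_frame(sim$video, 7), get_frame(sim$video, 27))
})

test_that("intensities are bounded and the phantom is bright", {
  sim <- default_sim()
  expect_true(all(sim$video$frames >= 0 & sim$video$frames <= 1))
  expect_gt(mean(sim$video$frames), 0)
})

test_that("cardiac waveform is an asymmetric bump anchored at phase 0", {
  ph <- seq(0, 1 - 1e-9, length.out = 2000)
  w <- cardiac_waveform(ph, asymmetry = 0.2)
  expect_equal(cardiac_waveform(0), -1)       # peak contraction
  expect_true(all(w <= 0 & w >= -1))
  expect_equal(w[ph > 0.35 & ph < 0.75], rep(0, sum(ph > 0.35 & ph < 0.75)))
  # asymmetry: slower relaxation than contraction
  expect_gt(sum(w[ph < 0.5] < -0.5), sum(w[ph >= 0.5] < -0.5))
  # continuity
  expect_lt(max(abs(diff(w))), 0.01)
})

test_that("respiratory displacement is concentrated near phase 0", {
  expect_equal(resp_displacement(0, 3, 0.15), 3)
  expect_lt(resp_displacement(0.5, 3, 0.15), 1e-4)
  expect_equal(resp_displacement(0.9, 3, 0.15), resp_displacement(0.1, 3, 0.15))
})
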