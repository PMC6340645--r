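test_that("kernel bandwidths follow their defining formulas", {
  pp <- default_pipeline()
  sim <- default_sim()
  cfg <- sim$truth$config
  # phases advancing exactly 1/27.27 per frame give sigma_phi = 0.4/27.27
  ph <- ((0:199) / 27.27) %% 1
  step <- median(circ_dist(ph[-1], ph[-200]))
  expect_equal(0.4 * step, 0.4 / 27.27, tolerance = 1e-9)
  # on the simulated video the fitted sigma_phi lands near the true step
  true_sp <- 0.4 * cfg$heart_rate / (60 * cfg$fps)
  expect_lt(abs(pp$model$sigma_phi - true_sp) / true_sp, 0.1)
  expect_gt(pp$model$sigma_L, 0)
})

test_that("zero residual scale triggers the degeneracy floor, frozen video errors", {
  pp <- default_pipeline()
  g <- pp$gating
  g$residuals <- rep(0, 300)
  m <- fit_reconstruction(default_sim()$video, pp$decomp, pp$phases, g)
  floor_L <- 1e-6 * diff(range(pp$decomp$u_hat))
  expect_equal(m$sigma_L, floor_L, tolerance = 1e-12)
  frozen <- pp$phases
  frozen$cardiac_phase <- rep(0.3, 300)
  expect_error(
    fit_reconstruction(default_sim()$video, pp$decomp, frozen, pp$gating),
    "frozen")
})

test_that("reconstruction equals the brute-force kernel-average definition", {
  sim <- default_sim()
  m <- default_pipeline()$model
  L <- m$lowess_model
  X <- frame_matrix(sim$video)
  for (phi in c(0.0, 0.23, 0.5, 0.87)) {
    dphi <- pmin(abs(phi - m$cardiac_phase) %% 1,
                 1 - abs(phi - m$cardiac_phase) %% 1)
    w <- exp(-dphi^2 / (2 * m$sigma_phi^2)) *
      exp(-(predict(L, phi) - m$u_hat)^2 / (2 * m$sigma_L^2))
    want <- matrix(as.numeric((w / sum(w)) %*% X), 64, 64)
    got <- reconstruct_phase(m, phi)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("reconstruction is a convex combination and continuous in phase", {
  sim <- default_sim()
  m <- default_pipeline()$model
  lo <- apply(sim$video$frames, c(1, 2), min)
  hi <- apply(sim$video$frames, c(1, 2), max)
  for (phi in c(0.1, 0.6)) {
    img <- reconstruct_phase(m, phi)
    expect_true(all(img >= lo - 1e-12 & img <= hi + 1e-12))
  }
  d1 <- max(abs(reconstruct_phase(m, 0.4) - reconstruct_phase(m, 0.41)))
  d2 <- max(abs(reconstruct_phase(m, 0.4) - reconstruct_phase(m, 0.401)))
  expect_lt(d2, d1)
  expect_lt(d2, 0.01)
})

test_that("identical frames reconstruct to themselves; tiny sigma picks a frame", {
  f <- toy_frames()$a / 10
  v <- video_sequence(list(f, f, f, f), fps = 10)
  S <- similarity_matrix(video_sequence(default_sim()$video$frames[, , 1:20], 233))
  # build a minimal model by hand around constant frames
  m <- default_pipeline()$model
  m_id <- m
  m_id$frames <- frame_matrix(v)
  m_id$shape <- c(3L, 3L)
  m_id$cardiac_phase <- c(0.1, 0.35, 0.6, 0.85)
  m_id$u_hat <- rep(0.9, 4)
  m_id$lowess_model <- lowess_fit(runif(50), rep(0.9, 50))
  for (phi in c(0, 0.42, 0.9))
    expect_equal(reconstruct_phase(m_id, phi), f, tolerance = 1e-12)
  # sigma_phi -> 0 limit converges to the phase-matching frame
  m2 <- m
  m2$sigma_phi <- 5e-6   # well below the closest phase collision (~7e-5)
  t0 <- 47
  got <- reconstruct_phase(m2, m$cardiac_phase[t0], kernel = "phase_only")
  expect_lt(max(abs(got - get_frame(default_sim()$video, t0))), 1e-6)
})

test_that("vanishing total weight raises the bandwidth error", {
  m <- default_pipeline()$model
  m$sigma_phi <- 1e-6
  m$sigma_L <- 1e-9
  # a phase maximally far from every sample phase has ~zero weight
  ph <- sort(m$cardiac_phase)
  gaps <- diff(c(ph, ph[1] + 1))
  target <- (ph[which.max(gaps)] + max(gaps) / 2) %% 1
  expect_error(reconstruct_phase(m, target), "bandwidth")
  expect_error(reconstruct_phase(m, 1.2), "\\[0, 1\\)")
})

test_that("single-cycle videos follow the frame-count rule", {
  m <- default_pipeline()$model
  expect_equal(m$frames_per_cycle, 27.27, tolerance = 0.3)
  for (mag in c(1, 2, 8)) {
    cyc <- single_cycle(m, mag)
    expect_equal(cyc$video$n_frames, round(mag * m$frames_per_cycle))
    expect_equal(cyc$phase_grid,
                 (seq_len(cyc$video$n_frames) - 1) / cyc$video$n_frames)
    if (mag == 1) break                     # keep runtime modest
  }
  expect_error(single_cycle(m, 0), "positive")
})

test_that("the bivariate kernel beats the phase-only kernel on noisy cycles", {
  sim <- default_sim()
  pp <- default_pipeline()
  pe <- phase_error(pp$phases$cardiac_phase, sim$truth$cardiac_phase)
  nb <- cycle_ncorr(pp$model, gt_cycle(), gt_cycle_phases(),
                    offset = pe$offset, kernel = "bivariate")
  nu <- cycle_ncorr(pp$model, gt_cycle(), gt_cycle_phases(),
                    offset = pe$offset, kernel = "phase_only")
  expect_gt(nb, nu)
})
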