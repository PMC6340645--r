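test_that("cutoff gate implements the set definition", {
  expect_equal(cutoff_gate(c(0.1, 0.5, 0.85, 0.3), c = 0.2), c(1L, 3L))
  expect_length(cutoff_gate(runif(50), c = 0), 0)
  expect_error(cutoff_gate(runif(5), c = 0.5), "0.5")
  expect_error(cutoff_gate(c(0.2, 1.0), c = 0.2), "\\[0, 1\\)")
})

test_that("cutoff gate discards ~2c of uniform phases", {
  set.seed(21)
  n <- 1e4
  frac <- length(cutoff_gate(runif(n), c = 0.2)) / n
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / n))
})

test_that("periodic LOWESS recovers a smooth periodic curve", {
  set.seed(2)
  ph <- runif(200)
  curve <- function(p) 0.9 + 0.05 * cos(2 * pi * p) + 0.02 * sin(4 * pi * p)
  fit <- lowess_fit(ph, curve(ph))
  grid <- seq(0, 0.999, by = 0.001)
  rmse <- sqrt(mean((predict(fit, grid) - curve(grid))^2))
  expect_lt(rmse / sqrt(mean(curve(grid)^2)), 0.01)
  # continuity across the wrap
  expect_lt(abs(predict(fit, 0.0005) - predict(fit, 0.9995)), 0.005)
})

test_that("LOWESS is robust to gross low outliers", {
  set.seed(4)
  ph <- runif(300)
  curve <- function(p) 0.9 + 0.05 * cos(2 * pi * p)
  y <- curve(ph)
  clean <- lowess_fit(ph, y)
  y_out <- y
  out <- sample(300, 15)                     # 5% gross outliers pulled far below
  y_out[out] <- y_out[out] - 0.5
  robust <- lowess_fit(ph, y_out)
  grid <- seq(0, 0.999, by = 0.005)
  rmse <- function(f) sqrt(mean((predict(f, grid) - curve(grid))^2))
  expect_lt(rmse(robust), 3 * max(rmse(clean), 1e-4))
})

test_that("degenerate and invalid LOWESS inputs behave per contract", {
  ph <- runif(50)
  fit <- lowess_fit(ph, rep(0.7, 50))
  expect_equal(predict(fit, c(0.1, 0.6, 0.95)), rep(0.7, 3), tolerance = 1e-9)
  expect_error(lowess_fit(ph[1:5], rep(1, 5) + rnorm(5)), ">= 10")
  expect_error(lowess_fit(runif(50) * 0.5, rnorm(50)), "gap")
})

test_that("robust sigma is the scaled MAD with its robustness properties", {
  expect_equal(robust_sigma(rep(0, 10)), 0)
  set.seed(6)
  expect_equal(robust_sigma(rnorm(1e5)), 1, tolerance = 0.02)
  r <- rnorm(100, sd = 0.1)
  s0 <- robust_sigma(r)
  r[7] <- 50
  expect_lt(abs(robust_sigma(r) - s0) / s0, 0.1)
  expect_error(robust_sigma(c(1, 2)), ">= 3")
})

test_that("the sigma gate catches exactly the depressed frames", {
  set.seed(8)
  ph <- runif(100)
  fit <- lowess_fit(ph, rep(0.9, 100))
  u <- rep(0.9, 100)
  expect_length(gate_respiratory(u, ph, fit, sigma_L = 0.01, k = 2), 0)
  u[42] <- 0.9 - 3 * 0.01
  expect_equal(gate_respiratory(u, ph, fit, sigma_L = 0.01, k = 2), 42L)
  # the depressed frame is invisible to a high-side-only deviation
  u2 <- rep(0.9, 100); u2[13] <- 0.9 + 3 * 0.01
  expect_length(gate_respiratory(u2, ph, fit, 0.01, k = 2, one_sided = TRUE), 0)
  expect_equal(gate_respiratory(u2, ph, fit, 0.01, k = 2, one_sided = FALSE), 13L)
  expect_error(gate_respiratory(u, ph, fit, 0.01, k = 0), "positive")
})

test_that("one-sided gate is a subset of the two-sided gate", {
  pp <- default_pipeline()
  g1 <- gate_video(pp$decomp$u_hat, pp$phases, one_sided = TRUE)
  g2 <- gate_video(pp$decomp$u_hat, pp$phases, one_sided = FALSE)
  expect_true(all(g1$f_resp %in% g2$f_resp))
})

test_that("gating the simulated video separates heavy from still frames", {
  sim <- default_sim()
  g <- default_pipeline()$gating
  disp <- sim$truth$resp_disp
  heavy <- which(disp > max(disp) / 2)
  still <- which(disp < 0.01 * max(disp))
  expect_gte(mean(heavy %in% g$respiratory), 0.8)
  expect_lte(mean(still %in% g$respiratory), 0.1)
})

test_that("re-gating the retained frames with the same model adds nothing", {
  pp <- default_pipeline()
  g <- pp$gating
  keep <- setdiff(seq_len(300), g$respiratory)
  again <- gate_respiratory(pp$decomp$u_hat[keep],
                            pp$phases$cardiac_phase[keep],
                            g$lowess_model, g$sigma_L, k = g$k)
  expect_lte(length(again), 0.02 * 300)
})

test_that("phase-ordered m-mode roughness drops after gating", {
  sim <- default_sim()
  pp <- default_pipeline()
  X <- frame_matrix(sim$video)
  roughness <- function(idx) {
    ord <- idx[order(pp$phases$cardiac_phase[idx])]
    mean(abs(X[ord[-1], ] - X[ord[-length(ord)], ]))
  }
  all_idx <- seq_len(300)
  kept <- setdiff(all_idx, pp$gating$respiratory)
  expect_lt(roughness(kept), roughness(all_idx))
})
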