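# Shared fixtures, built once per test run.  The default simulation is the
# stated world of the acceptance criteria (300 frames, 233 FPS, 512 BPM
# heart, 93.2 BPM respiration, default speckle, seed 1).

.fixtures <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_video(sim_config())
  .fixtures$sim
}

default_pipeline <- function() {
  if (is.null(.fixtures$pp))
    .fixtures$pp <- run_pipeline(default_sim()$video)
  .fixtures$pp
}

noiseless_sim <- function() {
  if (is.null(.fixtures$sim0))
    .fixtures$sim0 <- simulate_video(sim_config(speckle_level = 0))
  .fixtures$sim0
}

# Ground-truth single cycle at the native resolution (27 frames).
gt_cycle_phases <- function() (0:26) / 27

gt_cycle <- function() {
  if (is.null(.fixtures$gt))
    .fixtures$gt <- render_cycle(default_sim()$truth$config, gt_cycle_phases())
  .fixtures$gt
}

# Two tiny distinct non-constant frames.
toy_frames <- function() {
  list(a = matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3),
       b = matrix(c(2, 1, 4, 3, 7, 5, 8, 6, 9), 3, 3))
}
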