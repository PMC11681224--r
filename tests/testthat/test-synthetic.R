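test_that("a no-acceleration profile runs at constant speed with closed-form duration", {
  p <- sprint_profile(v_max = 5, accel_tau_s = 0, decel_onset_m = 100,
                      frame_rate_hz = 30)
  traj <- simulate_profile(p)
  expect_equal(unique(traj$speed_m_per_s), 5)
  expect_equal(traj$location_m[nrow(traj)] >= 100, TRUE)
  expect_equal(traj$time_s[nrow(traj)], 100 / 5, tolerance = 1 / 30)
  expect_equal(diff(traj$location_m), rep(5 / 30, nrow(traj) - 1),
               tolerance = 1e-12)
})

test_that("accelerating speeds match the analytic saturating exponential", {
  p <- sprint_profile(v_max = 7, accel_tau_s = 1.2, decel_onset_m = 100,
                      decel_rate = 0, frame_rate_hz = 30)
  traj <- simulate_profile(p)
  expect_equal(traj$speed_m_per_s,
               7 * (1 - exp(-traj$time_s / 1.2)), tolerance = 1e-9)
  # deceleration decays exponentially from the onset speed
  pd <- sprint_profile(v_max = 7, accel_tau_s = 0.3, decel_onset_m = 50,
                       decel_rate = 0.1, frame_rate_hz = 30)
  td <- simulate_profile(pd)
  after <- which(td$location_m >= 50)
  i0 <- after[1]
  expect_equal(td$speed_m_per_s[after],
               td$speed_m_per_s[i0] *
                 exp(-0.1 * (td$time_s[after] - td$time_s[i0])),
               tolerance = 1e-9)
})

test_that("non-finishing parameter sets raise an error instead of looping", {
  # decays so early and fast that total distance converges below 100 m
  p <- sprint_profile(v_max = 6, accel_tau_s = 0, decel_onset_m = 10,
                      decel_rate = 0.5)
  expect_error(simulate_profile(p), "does not reach")
  expect_error(sprint_profile(v_max = -1), "positive")
  expect_error(sprint_profile(decel_onset_m = 150), "decel_onset_m")
})

test_that("integrator ground truth matches closed forms for constant speed", {
  p <- sprint_profile(v_max = 6, accel_tau_s = 0, decel_onset_m = 100)
  gt <- ground_truth_subtasks(p)
  expect_equal(gt$mean_speed_m_per_s, rep(6, 10), tolerance = 1e-6)
  gtw <- ground_truth_subtasks(p, window_s = 4 / 30)
  expect_equal(gtw$mean_speed_m_per_s, rep(6, 10), tolerance = 1e-6)
  # independent check at a coarse bin width
  gt20 <- ground_truth_subtasks(p, subtask_length_m = 20)
  expect_equal(nrow(gt20), 5L)
})

test_that("windowed ground truth sits above instantaneous truth while accelerating", {
  p <- sprint_profile(v_max = 7, accel_tau_s = 1.2, decel_onset_m = 80,
                      decel_rate = 0.05)
  gi <- ground_truth_subtasks(p)
  gw <- ground_truth_subtasks(p, window_s = 4 / 30)
  expect_gt(gw$mean_speed_m_per_s[1], gi$mean_speed_m_per_s[1])
  # once speed is steady the two definitions agree closely
  expect_equal(gw$mean_speed_m_per_s[6], gi$mean_speed_m_per_s[6],
               tolerance = 1e-3)
})

test_that("rendering is deterministic in the seed and isolates noise from truth", {
  spec <- small_spec(noise_sd = 4)
  traj <- simulate_profile(small_profile())[1:25, ]
  r1 <- render_cameras(traj, spec)
  r2 <- render_cameras(traj, spec)
  expect_identical(r1$sequences$cam1$frames, r2$sequences$cam1$frames)
  spec2 <- small_spec(noise_sd = 4); spec2$seed <- 99L
  r3 <- render_cameras(traj, spec2)
  expect_false(identical(r1$sequences$cam1$frames, r3$sequences$cam1$frames))
  expect_equal(r1$truth, r3$truth)  # ground truth independent of noise seed
})

test_that("a noise-free render is detected at the true centroid to half a pixel", {
  spec <- small_spec()
  traj <- simulate_profile(small_profile())
  rc <- render_cameras(traj, spec)
  cfg <- small_config()
  for (id in c("cam1", "cam3")) {
    trk <- detect_track(rc$sequences[[id]], rc$backgrounds[[id]], cfg)
    truth <- rc$truth[rc$truth$camera_id == id, ]
    both <- !is.na(trk$x_px) & !is.na(truth$true_x_px)
    expect_gt(sum(both), 10)
    expect_lte(max(abs(trk$x_px[both] - truth$true_x_px[both])), 0.5)
  }
})

test_that("oversized silhouettes and bad intensities are rejected", {
  expect_error(render_spec(width_px = 64, height_px = 36, runner_w_px = 70),
               "exceeds the frame")
  expect_error(render_spec(runner_intensity = 300), "\\[0, 255\\]")
})

test_that("fixtures round-trip through disk and carry their ground truth", {
  dir <- file.path(withr::local_tempdir(), "fx")
  prof <- small_profile()
  spec <- small_spec(noise_sd = 2)
  make_fixture(prof, spec, dir)
  expect_true(all(dir.exists(file.path(dir, paste0("cam", 1:4)))))
  cfg <- load_run_config(file.path(dir, "config.json"))
  expect_length(cfg$cameras, 4L)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(names(gt), c("frame", "time_s", "location_m", "speed_m_per_s"))
  gts <- utils::read.csv(file.path(dir, "ground_truth_subtasks.csv"))
  expect_equal(nrow(gts), 10L)

  # written frames reload pixel-identically
  rc <- render_cameras(simulate_profile(prof), spec)
  back <- read_frame_sequence(file.path(dir, "cam2"), "cam2",
                              prof$frame_rate_hz)
  expect_equal(back$frames, rc$sequences$cam2$frames)

  # two fixtures with different seeds: different noise, same ground truth
  dir2 <- file.path(withr::local_tempdir(), "fx2")
  spec2 <- small_spec(noise_sd = 2); spec2$seed <- 77L
  make_fixture(prof, spec2, dir2)
  gt2 <- utils::read.csv(file.path(dir2, "ground_truth.csv"))
  expect_equal(gt2, gt)
  f1 <- png::readPNG(file.path(dir, "cam1", "frame_00005.png"))
  f2 <- png::readPNG(file.path(dir2, "cam1", "frame_00005.png"))
  expect_false(identical(f1, f2))
})

test_that("streaming simulate-and-track equals batch render-then-track", {
  prof <- small_profile()
  spec <- small_spec(noise_sd = 5)
  cfg <- small_config()
  stream <- run_synthetic_pipeline(prof, spec, cfg)
  rc <- render_cameras(simulate_profile(prof), spec)
  batch <- track_run(rc$sequences, rc$backgrounds, rc$calibrations, cfg)
  expect_equal(stream$world_track$location_m, batch$world_track$location_m)
  expect_equal(stream$subtasks$bins, batch$subtasks$bins)
})

test_that("a zero-contrast runner yields a clear all-missing diagnostic", {
  prof <- small_profile()
  spec <- small_spec(runner_intensity = 160, background_intensity = 160)
  expect_error(run_synthetic_pipeline(prof, spec, small_config()),
               "not detected.*contrast")
})

test_that("small-scale end-to-end recovery stays within 3% of windowed truth", {
  prof <- small_profile()
  cfg <- small_config()
  for (seed in c(5, 6)) {
    spec <- small_spec(noise_sd = 6); spec$seed <- seed
    res <- run_synthetic_pipeline(prof, spec, cfg)
    rel <- res$subtasks$bins$mean_speed_m_per_s /
      res$truth_subtasks_windowed$mean_speed_m_per_s - 1
    expect_lt(max(abs(rel)), 0.03)
  }
})
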