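# Small, fast synthetic configurations used across test files. The scaled
# geometry keeps the unit suite quick; full 640x360 @ 30 Hz conditions are
# exercised in the acceptance tests.

small_spec <- function(noise_sd = 0, seed = 11, ...) {
  render_spec(width_px = 200, height_px = 60, runner_w_px = 8,
              runner_h_px = 20, marker_start_px = 180, marker_end_px = 20,
              noise_sd = noise_sd, seed = seed, ...)
}

small_profile <- function(...) {
  sprint_profile(v_max = 8, accel_tau_s = 0.5, decel_onset_m = 85,
                 decel_rate = 0.05, frame_rate_hz = 10, ...)
}

small_config <- function(...) {
  run_config(frame_rate_hz = 10, ...)
}

# a bare WorldTrack from vectors, for kinematics/fusion tests
make_world_track <- function(location_m, frame_rate_hz = 30,
                             frame = seq_along(location_m) - 1) {
  structure(data.frame(frame = frame, time_s = frame / frame_rate_hz,
                       location_m = location_m,
                       source = "test"),
            frame_rate_hz = frame_rate_hz,
            class = c("WorldTrack", "data.frame"))
}

# a SegmentTrack with explicit range, for stitching tests
make_segment <- function(frame, location_m, offset, span = 25,
                         camera_id = "cam", frame_rate_hz = 30) {
  structure(data.frame(frame = frame, location_m = location_m),
            camera_id = camera_id, frame_rate_hz = frame_rate_hz,
            valid_range_m = c(offset, offset + span),
            class = c("SegmentTrack", "data.frame"))
}
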