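#' Run the full tracking pipeline on four camera sequences
#'
#' Detection (per camera) -> pixel-to-metre calibration -> fusion into one
#' 0-100 m track -> gap filling -> smoothing -> windowed instantaneous
#' velocity -> 10-m subtask means, with a run report of detection rates and
#' warnings.
#'
#' @param sequences List of `FrameSequence` objects (one per camera).
#' @param backgrounds Named list of background matrices keyed by camera id.
#' @param calibrations Named list of `CameraCalibration` objects keyed by
#'   camera id.
#' @param config A `RunConfig`.
#' @return List with `centroid_tracks`, `segment_tracks`, `world_track`
#'   (filled and smoothed), `velocity`, `subtasks`, and `report` (a
#'   `RunReport` list: per-camera detection rates, fused-track summary,
#'   warnings with frame ranges).
#' @export
track_run <- function(sequences, backgrounds, calibrations,
                      config = run_config()) {
  check_synchronized(sequences)
  ids <- vapply(sequences, function(s) s$camera_id, character(1))
  centroid_tracks <- list(); segment_tracks <- list()
  detection_rate <- numeric(length(ids)); names(detection_rate) <- ids
  for (id in ids) {
    bg <- backgrounds[[id]]
    if (is.null(bg)) sv_stop_io("missing background image for camera ", id)
    ct <- detect_track(sequences[[which(ids == id)]], bg, config)
    centroid_tracks[[id]] <- ct
    detection_rate[id] <- mean(!is.na(ct$x_px))
    segment_tracks[[id]] <- to_segment_track(ct, calibrations[[id]])
  }
  stitched <- stitch_tracks(segment_tracks, config)
  present <- !is.na(stitched$location_m)
  if (sum(present) < 2) {
    sv_stop_validation(
      "athlete not detected: only ", sum(present), " frame(s) carry a ",
      "location (per-camera detection rates: ",
      paste(sprintf("%s %.0f%%", ids, 100 * detection_rate),
            collapse = ", "),
      "); check contrast between athlete and background")
  }
  warnings <- character(0)
  gaps <- rle(!present)
  if (any(gaps$values & gaps$lengths > config$velocity_window_frames)) {
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1
    long <- which(gaps$values & gaps$lengths > config$velocity_window_frames)
    warnings <- c(warnings, sprintf(
      "long gap interpolated over frames %d-%d",
      stitched$frame[starts[long]], stitched$frame[ends[long]]))
  }
  if ((attr(stitched, "overlap_frames") %||% 0) > 0) {
    warnings <- c(warnings, sprintf(
      "%d frame(s) reported by two cameras; midpoint rule applied",
      attr(stitched, "overlap_frames")))
  }
  filled <- fill_missing(stitched)
  smoothed <- smooth_track(filled, config$smoothing_window_frames)
  vel <- instantaneous_velocity(smoothed, config$velocity_window_frames)
  subtasks <- segment_subtasks(vel, config, track = smoothed)
  report <- list(detection_rate = detection_rate,
                 n_frames = nrow(stitched),
                 frames_interpolated = sum(!present),
                 track_range_m = range(smoothed$location_m),
                 total_time_s = subtasks$total_time_s,
                 average_speed_m_per_s = subtasks$average_speed_m_per_s,
                 warnings = warnings)
  list(centroid_tracks = centroid_tracks, segment_tracks = segment_tracks,
       world_track = smoothed, velocity = vel, subtasks = subtasks,
       report = report)
}

#' Simulate, render and track a synthetic sprint in one pass
#'
#' Streams the renderer into the detector one frame at a time (cameras are
#' processed sequentially), so a full-resolution 100-m run never holds all
#' frames in memory. Numerically identical to rendering with
#' [render_cameras()] and tracking with [track_run()], since each camera
#' consumes the same per-camera RNG stream.
#'
#' @param profile A `SprintProfile`.
#' @param spec A `RenderSpec`.
#' @param config Optional `RunConfig` (defaults to the profile's frame
#'   rate).
#' @return As [track_run()], plus `trajectory` (the ground truth),
#'   `truth_subtasks` (fine-step integrator bin means of instantaneous
#'   speed) and `truth_subtasks_windowed` (bin means of the configured
#'   windowed estimand; see [ground_truth_subtasks()]).
#' @export
run_synthetic_pipeline <- function(profile, spec, config = NULL) {
  if (is.null(config)) {
    config <- run_config(frame_rate_hz = profile$frame_rate_hz)
  }
  traj <- simulate_profile(profile)
  calibrations <- default_calibrations(spec)
  segment_tracks <- list()
  detection_rate <- numeric(0)
  n <- nrow(traj)
  for (k in seq_along(calibrations)) {
    cal <- calibrations[[k]]
    bg <- camera_background(spec)
    set.seed(spec$seed + k)
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      r <- render_one_frame(bg, traj$location_m[i], cal, spec)
      cen <- detect_frame(r$frame, bg, config)
      xs[i] <- cen[["x"]]; ys[i] <- cen[["y"]]
    }
    ct <- centroid_track(cal$camera_id,
                         data.frame(frame = traj$frame, x_px = xs, y_px = ys),
                         profile$frame_rate_hz)
    detection_rate[cal$camera_id] <- mean(!is.na(xs))
    segment_tracks[[cal$camera_id]] <- to_segment_track(ct, cal)
  }
  stitched <- stitch_tracks(segment_tracks, config)
  if (sum(!is.na(stitched$location_m)) < 2) {
    sv_stop_validation(
      "athlete not detected in the synthetic run (detection rates: ",
      paste(sprintf("%s %.0f%%", names(detection_rate),
                    100 * detection_rate), collapse = ", "),
      "); check contrast between runner and background intensities")
  }
  smoothed <- smooth_track(fill_missing(stitched),
                           config$smoothing_window_frames)
  vel <- instantaneous_velocity(smoothed, config$velocity_window_frames)
  subtasks <- segment_subtasks(vel, config, track = smoothed)
  list(segment_tracks = segment_tracks, world_track = smoothed,
       velocity = vel, subtasks = subtasks,
       trajectory = traj,
       truth_subtasks = ground_truth_subtasks(profile,
                                              config$subtask_length_m),
       truth_subtasks_windowed = ground_truth_subtasks(
         profile, config$subtask_length_m,
         window_s = config$velocity_window_frames / profile$frame_rate_hz),
       report = list(detection_rate = detection_rate,
                     total_time_s = subtasks$total_time_s,
                     average_speed_m_per_s = subtasks$average_speed_m_per_s))
}
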