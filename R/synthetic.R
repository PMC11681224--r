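#' Three-phase sprint velocity profile
#'
#' Parametric ground-truth model of a 100-m sprint with the three classic
#' phases: acceleration (saturating exponential rise to `v_max` with time
#' constant `accel_tau_s`), maximum velocity, and deceleration (exponential
#' speed decay at fractional rate `decel_rate` once the athlete passes
#' `decel_onset_m`). Defaults emulate a collegiate sprinter peaking near
#' 7 m/s and fading over the final 20 m.
#'
#' @param v_max Peak speed, m/s.
#' @param accel_tau_s Acceleration time constant, s; 0 means an instant
#'   start at `v_max`.
#' @param decel_onset_m Location where deceleration begins, m.
#' @param decel_rate Fractional speed loss per second during deceleration.
#' @param frame_rate_hz Sampling rate of the generated trajectory, Hz.
#' @param track_length_m Total distance, m.
#' @return An object of class `SprintProfile`.
#' @export
sprint_profile <- function(v_max = 7, accel_tau_s = 1.2, decel_onset_m = 80,
                           decel_rate = 0.05, frame_rate_hz = 30,
                           track_length_m = 100) {
  if (!is.finite(v_max) || v_max <= 0) {
    sv_stop_validation("v_max must be positive, got ", v_max)
  }
  if (!is.finite(accel_tau_s) || accel_tau_s < 0) {
    sv_stop_validation("accel_tau_s must be >= 0, got ", accel_tau_s)
  }
  if (!is.finite(decel_onset_m) || decel_onset_m <= 0 ||
      decel_onset_m > track_length_m) {
    sv_stop_validation("decel_onset_m must lie in (0, track_length_m], got ",
                       decel_onset_m)
  }
  structure(list(v_max = v_max, accel_tau_s = accel_tau_s,
                 decel_onset_m = decel_onset_m, decel_rate = decel_rate,
                 frame_rate_hz = frame_rate_hz,
                 track_length_m = track_length_m),
            class = "SprintProfile")
}

# Shared integrator: speed sampled at step dt, location by trapezoidal
# integration, stopping at the first sample at or beyond the finish line.
simulate_steps <- function(profile, dt, cap_s = 60) {
  p <- profile
  n_cap <- ceiling(cap_s / dt) + 1
  time_s <- numeric(n_cap); loc <- numeric(n_cap); spd <- numeric(n_cap)
  v_of_accel <- function(t) {
    if (p$accel_tau_s == 0) p$v_max else p$v_max * (1 - exp(-t / p$accel_tau_s))
  }
  t_onset <- NA_real_; v_onset <- NA_real_
  spd[1] <- v_of_accel(0)
  k <- 1
  while (loc[k] < p$track_length_m) {
    if (k >= n_cap) {
      sv_stop_validation("profile does not reach ", p$track_length_m,
                         " m within ", cap_s, " s")
    }
    t_next <- k * dt
    if (is.na(t_onset) && loc[k] >= p$decel_onset_m) {
      t_onset <- time_s[k]; v_onset <- spd[k]
    }
    v_next <- if (is.na(t_onset)) v_of_accel(t_next) else
      v_onset * exp(-p$decel_rate * (t_next - t_onset))
    k <- k + 1
    time_s[k] <- t_next
    spd[k] <- v_next
    loc[k] <- loc[k - 1] + dt * (spd[k - 1] + v_next) / 2
  }
  data.frame(time_s = time_s[seq_len(k)], location_m = loc[seq_len(k)],
             speed_m_per_s = spd[seq_len(k)])
}

#' Simulate a ground-truth sprint trajectory at the camera frame rate
#'
#' @param profile A `SprintProfile`.
#' @param cap_s Abort if the finish line is not reached within this many
#'   seconds (guards against non-finishing parameter sets).
#' @return Data frame with one row per frame: `frame` (0-based), `time_s`,
#'   `location_m`, `speed_m_per_s`. The final row is the first frame at or
#'   beyond the finish line.
#' @export
simulate_profile <- function(profile, cap_s = 60) {
  stopifnot(inherits(profile, "SprintProfile"))
  out <- simulate_steps(profile, dt = 1 / profile$frame_rate_hz, cap_s)
  cbind(frame = seq_len(nrow(out)) - 1L, out)
}

#' Ground-truth subtask speeds by fine-step integration
#'
#' Integrates the profile at a fine time step (independent of the frame
#' rate and of the tracking pipeline). With `window_s = NULL` each bin's
#' mean speed is the true time-average of instantaneous speed in the bin —
#' bin width over the interpolated time between the bin-edge crossings.
#'
#' With a `window_s`, the oracle instead reports the ground truth of the
#' quantity the tracking system is defined to measure: forward-window
#' secant speeds `(x(t + window_s) - x(t)) / window_s` anchored at location
#' `x(t)` and averaged per bin over the fine grid. During acceleration the
#' windowed estimator reads systematically above the instantaneous speed
#' (the secant looks half a window into the future), so comparing the
#' pipeline against the window-matched truth isolates genuine measurement
#' error (detection, calibration, fusion) from the discretization bias
#' shared by any implementation of the same estimator.
#'
#' @param profile A `SprintProfile`.
#' @param subtask_length_m Bin width, m.
#' @param dt Integration step, s.
#' @param window_s Velocity window in seconds (e.g. `4/30` for the standard
#'   4-frame window at 30 Hz), or `NULL` for instantaneous truth.
#' @return Data frame `start_m`, `end_m`, `mean_speed_m_per_s`.
#' @export
ground_truth_subtasks <- function(profile, subtask_length_m = 10, dt = 1e-4,
                                  window_s = NULL) {
  traj <- simulate_steps(profile, dt = dt)
  edges <- seq(0, profile$track_length_m, by = subtask_length_m)
  if (is.null(window_s)) {
    tcross <- vapply(edges, function(e) {
      crossing_time(traj$time_s, traj$location_m, e)
    }, numeric(1))
    return(data.frame(start_m = edges[-length(edges)], end_m = edges[-1],
                      mean_speed_m_per_s = subtask_length_m / diff(tcross)))
  }
  w <- as.integer(round(window_s / dt))
  n <- nrow(traj)
  i <- seq_len(n - w)
  spd <- (traj$location_m[i + w] - traj$location_m[i]) /
    (traj$time_s[i + w] - traj$time_s[i])
  loc <- traj$location_m[i]
  nb <- length(edges) - 1
  k <- pmin(floor(loc / subtask_length_m) + 1, nb)
  mean_speed <- vapply(seq_len(nb), function(b) {
    sel <- k == b
    if (!any(sel)) NA_real_ else mean(spd[sel])
  }, numeric(1))
  data.frame(start_m = edges[-length(edges)], end_m = edges[-1],
             mean_speed_m_per_s = mean_speed)
}

#' Rendering specification for the synthetic four-camera setup
#'
#' Describes how the simulated athlete is drawn into camera frames: a dark
#' rectangular silhouette translating across a uniform bright background,
#' with additive clipped Gaussian pixel noise and optional small distractor
#' blobs. Defaults mirror a 640x360 px, 30 Hz webcam setup where the two
#' 25-m markers project to pixel columns 570 and 70 (0.05 m/px) and the
#' athlete wears dark clothing against a bright track.
#'
#' @param width_px,height_px Frame dimensions.
#' @param runner_w_px,runner_h_px Silhouette size in pixels.
#' @param runner_intensity,background_intensity Grayscale levels in
#'   `[0, 255]`; their difference must exceed the detection threshold for
#'   the athlete to be detectable.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise
#'   (clipped to `[0, 255]`).
#' @param distractor_count Number of small moving distractor blobs per
#'   camera; their default size stays below the minimum blob area so they
#'   are rejected by the area filter.
#' @param distractor_size_px Side of the square distractor blobs.
#' @param marker_start_px,marker_end_px Pixel columns where the segment's
#'   far and near markers project (shared by all four cameras in the default
#'   symmetric layout).
#' @param seed Integer RNG seed; each camera derives its own stream from it,
#'   so fixtures are byte-reproducible.
#' @return An object of class `RenderSpec`.
#' @export
render_spec <- function(width_px = 640, height_px = 360,
                        runner_w_px = 10, runner_h_px = 34,
                        runner_intensity = 30, background_intensity = 160,
                        noise_sd = 5, distractor_count = 0,
                        distractor_size_px = 3,
                        marker_start_px = 570, marker_end_px = 70,
                        seed = 1) {
  if (runner_intensity < 0 || runner_intensity > 255 ||
      background_intensity < 0 || background_intensity > 255) {
    sv_stop_validation("intensities must lie in [0, 255]")
  }
  if (runner_w_px > width_px || runner_h_px > height_px) {
    sv_stop_validation("runner silhouette (", runner_w_px, "x", runner_h_px,
                       ") exceeds the frame (", width_px, "x", height_px, ")")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 runner_w_px = as.integer(runner_w_px),
                 runner_h_px = as.integer(runner_h_px),
                 runner_intensity = runner_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 distractor_count = as.integer(distractor_count),
                 distractor_size_px = as.integer(distractor_size_px),
                 marker_start_px = marker_start_px,
                 marker_end_px = marker_end_px,
                 seed = as.integer(seed)),
            class = "RenderSpec")
}

#' Default four-camera calibration set for a render spec
#'
#' Cameras `cam1`..`cam4` cover 0-25, 25-50, 50-75 and 75-100 m with the
#' spec's shared marker pixel columns.
#'
#' @param spec A `RenderSpec`.
#' @return Named list of four `CameraCalibration` objects.
#' @export
default_calibrations <- function(spec) {
  cals <- lapply(1:4, function(k) {
    calibrate_camera(spec$marker_start_px, spec$marker_end_px,
                     segment_span_m = 25,
                     segment_offset_m = 25 * (k - 1),
                     camera_id = paste0("cam", k))
  })
  names(cals) <- paste0("cam", 1:4)
  cals
}

# Draw one frame for one camera: background + runner rectangle (if the
# athlete's location is within the segment +/- 1 m) + distractors + noise.
# Consumes RNG; callers own the seed. Returns list(frame, true_x_px).
render_one_frame <- function(background, location_m, cal, spec) {
  f <- background
  true_x <- NA_real_
  lo <- cal$segment_offset_m - 1
  hi <- cal$segment_offset_m + cal$segment_span_m + 1
  if (!is.na(location_m) && location_m >= lo && location_m <= hi) {
    centre <- world_to_pixel(location_m, cal)
    c0 <- round(centre - (spec$runner_w_px - 1) / 2)
    cols <- c0:(c0 + spec$runner_w_px - 1)
    cols <- cols[cols >= 1 & cols <= spec$width_px]
    if (length(cols) > 0) {
      r0 <- round(spec$height_px * 0.6 - (spec$runner_h_px - 1) / 2)
      rows <- r0:(r0 + spec$runner_h_px - 1)
      rows <- rows[rows >= 1 & rows <= spec$height_px]
      f[rows, cols] <- spec$runner_intensity
      true_x <- mean(cols)
    }
  }
  if (spec$distractor_count > 0) {
    for (d in seq_len(spec$distractor_count)) {
      dr <- sample.int(spec$height_px - spec$distractor_size_px + 1, 1)
      dc <- sample.int(spec$width_px - spec$distractor_size_px + 1, 1)
      f[dr:(dr + spec$distractor_size_px - 1),
        dc:(dc + spec$distractor_size_px - 1)] <- spec$runner_intensity
    }
  }
  if (spec$noise_sd > 0) {
    f <- f + stats::rnorm(length(f), 0, spec$noise_sd)
    f <- round(pmin(pmax(f, 0), 255))
    dim(f) <- c(spec$height_px, spec$width_px)
  }
  list(frame = f, true_x_px = true_x)
}

camera_background <- function(spec) {
  matrix(spec$background_intensity, spec$height_px, spec$width_px)
}

#' Render a trajectory as four synchronized camera views
#'
#' For each camera the athlete's silhouette is drawn at the pixel column
#' given by the inverse calibration map whenever the true location is inside
#' the camera's segment (with 1 m of slack); Gaussian pixel noise and
#' optional distractor blobs are added. The per-frame true centroid column
#' is returned as ground truth. Each camera uses RNG seed
#' `spec$seed + camera index`, so outputs are fully reproducible.
#'
#' @param trajectory Data frame from [simulate_profile()].
#' @param spec A `RenderSpec`.
#' @param calibrations List of four `CameraCalibration` objects (default:
#'   [default_calibrations()]).
#' @return List with `sequences` (four `FrameSequence`s), `backgrounds`
#'   (named list of matrices), `calibrations`, and `truth` (data frame:
#'   `camera_id`, `frame`, `true_x_px`, `location_m`).
#' @export
render_cameras <- function(trajectory, spec,
                           calibrations = default_calibrations(spec)) {
  stopifnot(inherits(spec, "RenderSpec"))
  rate <- 1 / (trajectory$time_s[2] - trajectory$time_s[1])
  sequences <- list(); backgrounds <- list(); truth <- list()
  for (k in seq_along(calibrations)) {
    cal <- calibrations[[k]]
    bg <- camera_background(spec)
    set.seed(spec$seed + k)
    frames <- vector("list", nrow(trajectory))
    tx <- numeric(nrow(trajectory))
    for (i in seq_len(nrow(trajectory))) {
      r <- render_one_frame(bg, trajectory$location_m[i], cal, spec)
      frames[[i]] <- r$frame
      tx[i] <- r$true_x_px
    }
    id <- cal$camera_id
    sequences[[id]] <- frame_sequence(id, frames, rate)
    backgrounds[[id]] <- bg
    truth[[id]] <- data.frame(camera_id = id, frame = trajectory$frame,
                              true_x_px = tx,
                              location_m = trajectory$location_m)
  }
  list(sequences = sequences, backgrounds = backgrounds,
       calibrations = calibrations, truth = do.call(rbind, truth))
}

#' Write a self-contained synthetic fixture to disk
#'
#' Produces a directory loadable by the frame I/O layer:
#' `cam{1..4}/frame_%05d.png`, `cam{k}_background.png`, `config.json` (run
#' parameters plus the camera calibration block), `ground_truth.csv`
#' (per-frame time, location and speed) and `ground_truth_subtasks.csv`
#' (per-bin mean speeds from the fine-step integrator, both the
#' instantaneous truth and the truth of the configured windowed estimand).
#'
#' @param profile A `SprintProfile`.
#' @param spec A `RenderSpec`.
#' @param out_dir Output directory (created).
#' @param config Optional `RunConfig`; defaults to [run_config()] at the
#'   profile's frame rate.
#' @return Invisibly, `out_dir`.
#' @export
make_fixture <- function(profile, spec, out_dir, config = NULL) {
  if (is.null(config)) {
    config <- run_config(frame_rate_hz = profile$frame_rate_hz)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) sv_stop_io("cannot create ", out_dir)
  traj <- simulate_profile(profile)
  rc <- render_cameras(traj, spec)
  for (id in names(rc$sequences)) {
    write_frame_sequence(rc$sequences[[id]], file.path(out_dir, id))
    png::writePNG(rc$backgrounds[[id]] / 255,
                  file.path(out_dir, paste0(id, "_background.png")))
  }
  config$cameras <- lapply(rc$calibrations, function(cal) {
    list(camera_id = cal$camera_id,
         marker_start_px = cal$marker_start_px,
         marker_end_px = cal$marker_end_px,
         segment_span_m = cal$segment_span_m,
         segment_offset_m = cal$segment_offset_m)
  })
  names(config$cameras) <- NULL
  write_run_config(config, file.path(out_dir, "config.json"))
  utils::write.table(traj, file.path(out_dir, "ground_truth.csv"),
                     sep = ",", row.names = FALSE, na = "")
  gts <- ground_truth_subtasks(profile, config$subtask_length_m)
  gts$mean_speed_windowed_m_per_s <- ground_truth_subtasks(
    profile, config$subtask_length_m,
    window_s = config$velocity_window_frames / profile$frame_rate_hz
  )$mean_speed_m_per_s
  utils::write.table(gts, file.path(out_dir, "ground_truth_subtasks.csv"),
                     sep = ",", row.names = FALSE, na = "")
  invisible(out_dir)
}
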