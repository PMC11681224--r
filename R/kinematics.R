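#' Instantaneous velocity by fixed-window forward difference
#'
#' For each sample index i, speed is the secant slope
#' `(loc[i+w] - loc[i]) / (time[i+w] - time[i])` over a window of `w` frames
#' (4 frames at 30 Hz in the standard configuration). The sample is anchored
#' at index i and carries location `loc[i]`. Elapsed time is taken from the
#' actual timestamps, not assumed `w / frame_rate`, so variable frame rates
#' degrade gracefully.
#'
#' @param track A gap-free `WorldTrack`.
#' @param window_frames Forward-difference window, `>= 1` and shorter than
#'   the track.
#' @return A `VelocitySeries`: data frame with columns `frame`, `time_s`,
#'   `location_m`, `speed_m_per_s`; `nrow = track length - window_frames`.
#' @export
instantaneous_velocity <- function(track, window_frames = 4) {
  n <- nrow(track)
  w <- as.integer(window_frames)
  if (is.na(w) || w < 1) {
    sv_stop_validation("velocity window must be >= 1, got ", window_frames)
  }
  if (n < w + 1) {
    sv_stop_validation("track too short (", n, " samples) for a ",
                       w, "-frame velocity window")
  }
  if (anyNA(track$location_m)) {
    sv_stop_validation("velocity requires a gap-free track; ",
                       "run fill_missing first")
  }
  i <- seq_len(n - w)
  speed <- (track$location_m[i + w] - track$location_m[i]) /
    (track$time_s[i + w] - track$time_s[i])
  structure(data.frame(frame = track$frame[i],
                       time_s = track$time_s[i],
                       location_m = track$location_m[i],
                       speed_m_per_s = speed),
            frame_rate_hz = attr(track, "frame_rate_hz"),
            class = c("VelocitySeries", "data.frame"))
}

#' Mean speed per 10-m subtask (V1..V10)
#'
#' Velocity samples are binned by their anchored location into consecutive
#' `subtask_length_m` bins tiling `[0, track_length_m]`. Bins are half-open
#' `[start, end)` with the final bin closed at the finish line, so each
#' sample is counted exactly once. Empty bins are reported missing with
#' `n_samples = 0`.
#'
#' Also computes the overall time — the linearly interpolated first crossing
#' of `track_length_m`, measured from the first sample — and the
#' corresponding 100-m average speed.
#'
#' @param vel A `VelocitySeries`.
#' @param config A `RunConfig`.
#' @param track Optional gap-free `WorldTrack` the velocities came from;
#'   when supplied, the finish-line crossing is interpolated from the full
#'   track rather than from the velocity anchors, which stop one window
#'   short of the line.
#' @return A `SubtaskSpeeds` object: list with `bins` (data frame
#'   `start_m`, `end_m`, `mean_speed_m_per_s`, `n_samples`), `total_time_s`
#'   and `average_speed_m_per_s` (both `NA` if the finish line is never
#'   reached).
#' @export
segment_subtasks <- function(vel, config = run_config(), track = NULL) {
  width <- config$subtask_length_m
  total <- config$track_length_m
  nbins <- as.integer(round(total / width))
  starts <- width * (seq_len(nbins) - 1)
  ends <- starts + width
  k <- floor(vel$location_m / width) + 1
  k[vel$location_m >= total] <- nbins  # final bin closed at the finish line
  k[vel$location_m < 0 | vel$location_m > total] <- NA
  mean_speed <- rep(NA_real_, nbins)
  n_samples <- integer(nbins)
  for (b in seq_len(nbins)) {
    sel <- which(!is.na(k) & k == b)
    n_samples[b] <- length(sel)
    if (length(sel) > 0) mean_speed[b] <- mean(vel$speed_m_per_s[sel])
  }
  src <- if (is.null(track)) vel else track
  total_time <- crossing_time(src$time_s, src$location_m, total) -
    src$time_s[1]
  structure(
    list(bins = data.frame(start_m = starts, end_m = ends,
                           mean_speed_m_per_s = mean_speed,
                           n_samples = n_samples),
         total_time_s = total_time,
         average_speed_m_per_s = if (is.na(total_time) || total_time <= 0)
           NA_real_ else average_speed(total, total_time)),
    class = "SubtaskSpeeds"
  )
}

# Linearly interpolated time of the first crossing of `target` by the
# (time, location) series; NA if never reached.
crossing_time <- function(time_s, location_m, target) {
  at <- which(location_m >= target)
  if (length(at) == 0) return(NA_real_)
  i <- at[1]
  if (i == 1 || location_m[i] == target) return(time_s[i])
  j <- i - 1
  time_s[j] + (target - location_m[j]) /
    (location_m[i] - location_m[j]) * (time_s[i] - time_s[j])
}

#' @export
print.SubtaskSpeeds <- function(x, ...) {
  cat("100-m subtask speeds (m/s):\n")
  b <- x$bins
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  V%-2d (%3g-%3g m): %s  (n = %d)\n", i, b$start_m[i],
                b$end_m[i],
                if (is.na(b$mean_speed_m_per_s[i])) "   --" else
                  sprintf("%.3f", b$mean_speed_m_per_s[i]),
                b$n_samples[i]))
  }
  if (!is.na(x$total_time_s)) {
    cat(sprintf("  total: %.3f s, average %.3f m/s\n", x$total_time_s,
                x$average_speed_m_per_s))
  }
  invisible(x)
}

#' Average speed over a distance
#'
#' @param distance_m Distance in metres.
#' @param time_s Elapsed time in seconds; must be positive.
#' @return Speed in metres per second (full precision; use
#'   [format_speed()] for report rounding).
#' @export
average_speed <- function(distance_m, time_s) {
  if (any(!is.finite(time_s)) || any(time_s <= 0)) {
    sv_stop_validation("time_s must be positive, got ",
                       paste(time_s, collapse = ", "))
  }
  distance_m / time_s
}

#' Round a speed for report output
#'
#' Three decimals, round-half-up, matching the precision used in published
#' split-time tables. Internal values stay full precision.
#'
#' @param speed_m_per_s Numeric speed(s).
#' @return Numeric rounded to 3 decimals.
#' @export
format_speed <- function(speed_m_per_s) {
  floor(speed_m_per_s * 1000 + 0.5) / 1000
}

#' Write a subtask table to CSV
#'
#' @param subtasks A `SubtaskSpeeds` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_subtask_csv <- function(subtasks, path) {
  df <- subtasks$bins
  names(df) <- c("bin_start_m", "bin_end_m", "mean_speed", "n_samples")
  utils::write.table(df, path, sep = ",", row.names = FALSE, na = "")
  invisible(path)
}
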