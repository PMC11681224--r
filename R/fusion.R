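#' Stitch per-camera segment tracks into one world track
#'
#' Produces a single 0-100 m position series. For each frame the location is
#' taken from the camera whose segment contains the report; where two
#' cameras both report (the athlete crossing a marker line), the camera
#' whose segment midpoint is closer to the reported location wins, with ties
#' going to the lower-offset camera. Frames no camera reports carry the
#' missing sentinel.
#'
#' @param segments List of `SegmentTrack` objects whose nominal ranges tile
#'   `[0, track_length_m]` without overlap.
#' @param config A `RunConfig`.
#' @return A `WorldTrack`: data frame with columns `frame`, `time_s`,
#'   `location_m`, `source` (camera id or `NA`), and attribute
#'   `frame_rate_hz`. Locations are clamped to `[0, track_length_m]`.
#' @export
stitch_tracks <- function(segments, config = run_config()) {
  stopifnot(length(segments) >= 1)
  ranges <- t(vapply(segments, function(s) attr(s, "valid_range_m"),
                     numeric(2)))
  ord <- order(ranges[, 1])
  segments <- segments[ord]; ranges <- ranges[ord, , drop = FALSE]
  if (any(ranges[-1, 1] < ranges[-nrow(ranges), 2] - 1e-9)) {
    sv_stop_validation("camera segment ranges overlap beyond the allowed ",
                       "marker-line slack")
  }
  if (abs(ranges[1, 1]) > 1e-9 ||
      abs(ranges[nrow(ranges), 2] - config$track_length_m) > 1e-9 ||
      (nrow(ranges) > 1 &&
       any(abs(ranges[-1, 1] - ranges[-nrow(ranges), 2]) > 1e-9))) {
    sv_stop_validation("camera segments do not tile [0, ",
                       config$track_length_m, "] m")
  }
  rate <- attr(segments[[1]], "frame_rate_hz") %||% config$frame_rate_hz
  frames <- sort(unique(unlist(lapply(segments, function(s) s$frame))))
  loc_mat <- vapply(segments, function(s) {
    s$location_m[match(frames, s$frame)]
  }, numeric(length(frames)))
  loc_mat <- matrix(loc_mat, nrow = length(frames))
  mids <- rowMeans(ranges)
  ids <- vapply(segments, function(s) attr(s, "camera_id") %||% "?",
                character(1))
  loc <- rep(NA_real_, length(frames))
  src <- rep(NA_character_, length(frames))
  multi <- 0L
  for (i in seq_along(frames)) {
    cand <- which(!is.na(loc_mat[i, ]))
    if (length(cand) == 0) next
    if (length(cand) > 1) {
      multi <- multi + 1L
      d <- abs(loc_mat[i, cand] - mids[cand])
      # ties -> lower-offset camera: segments are sorted by offset, and
      # which.min returns the first minimum
      cand <- cand[which.min(d)]
    }
    loc[i] <- loc_mat[i, cand]
    src[i] <- ids[cand]
  }
  loc <- pmin(pmax(loc, 0), config$track_length_m)
  structure(data.frame(frame = frames, time_s = frames / rate,
                       location_m = loc, source = src),
            frame_rate_hz = rate,
            overlap_frames = multi,
            class = c("WorldTrack", "data.frame"))
}

#' Fill missing locations in a world track
#'
#' Interior gaps are filled by linear interpolation against frame index;
#' leading and trailing gaps take the nearest present value (no linear
#' extrapolation, so no motion is manufactured before the start signal).
#' Filled entries are marked `"interpolated"` in the `source` column.
#'
#' @param track A `WorldTrack` (possibly with `NA` locations).
#' @return A gap-free `WorldTrack`.
#' @export
fill_missing <- function(track) {
  present <- !is.na(track$location_m)
  if (sum(present) < 2) {
    sv_stop_validation("cannot interpolate a track with fewer than two ",
                       "present locations")
  }
  filled <- zoo::na.approx(track$location_m, x = track$frame, rule = 2)
  track$source[!present] <- "interpolated"
  track$location_m <- as.numeric(filled)
  track
}

#' Smooth a world track with a centred moving average
#'
#' The window shrinks symmetrically at the ends (half-width
#' `min((window-1)/2, i-1, n-i)`), so a linear trajectory is reproduced
#' exactly everywhere and no boundary samples are lost. Window 1 is the
#' identity.
#'
#' @param track A gap-free `WorldTrack`.
#' @param window_frames Odd window length in frames.
#' @return A `WorldTrack` with smoothed `location_m`; time and frame index
#'   unchanged.
#' @export
smooth_track <- function(track, window_frames = 5) {
  if (is.na(window_frames) || window_frames < 1 || window_frames %% 2 == 0) {
    sv_stop_validation("smoothing window must be an odd integer >= 1, got ",
                       window_frames)
  }
  if (window_frames == 1) return(track)
  x <- track$location_m
  if (anyNA(x)) {
    sv_stop_validation("smooth_track requires a gap-free track; ",
                       "run fill_missing first")
  }
  n <- length(x)
  half <- (window_frames - 1) / 2
  h <- pmin(half, seq_len(n) - 1, n - seq_len(n))
  cs <- c(0, cumsum(x))
  track$location_m <- (cs[seq_len(n) + h + 1] - cs[seq_len(n) - h]) /
    (2 * h + 1)
  track
}
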