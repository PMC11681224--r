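#' Two-marker linear camera calibration
#'
#' Each camera views one 25-m track segment bounded by two physical markers.
#' The metres-per-pixel factor is `segment_span_m / (marker_start_px -
#' marker_end_px)`; it is signed, so cameras in which the athlete moves in
#' decreasing pixel-x are supported without special-casing. `marker_end_px`
#' is the pixel column of the marker at the lower world position of the
#' segment (`segment_offset_m`).
#'
#' @param marker_start_px Pixel column of the marker at
#'   `segment_offset_m + segment_span_m`.
#' @param marker_end_px Pixel column of the marker at `segment_offset_m`.
#' @param segment_span_m Real distance between the two markers (default 25).
#' @param segment_offset_m World position of the `marker_end_px` marker; 0,
#'   25, 50 or 75 for cameras 1-4 of the standard layout.
#' @param camera_id Optional identifier carried through to tracks.
#' @return An object of class `CameraCalibration`.
#' @export
#' @examples
#' cal <- calibrate_camera(620, 120, 25, 50)
#' cal$metres_per_pixel  # 0.05
calibrate_camera <- function(marker_start_px, marker_end_px,
                             segment_span_m = 25, segment_offset_m = 0,
                             camera_id = NULL) {
  if (marker_start_px == marker_end_px) {
    sv_stop_validation("marker pixels coincide (", marker_start_px,
                       "): metres-per-pixel undefined")
  }
  if (!is.finite(segment_span_m) || segment_span_m <= 0) {
    sv_stop_validation("segment_span_m must be positive, got ", segment_span_m)
  }
  cal_volume <- marker_start_px - marker_end_px
  structure(
    list(camera_id = camera_id,
         marker_start_px = marker_start_px,
         marker_end_px = marker_end_px,
         segment_span_m = segment_span_m,
         segment_offset_m = segment_offset_m,
         metres_per_pixel = segment_span_m / cal_volume),
    class = "CameraCalibration"
  )
}

#' @export
print.CameraCalibration <- function(x, ...) {
  cat(sprintf(
    "<CameraCalibration %s: markers %g/%g px, %g m/px, world [%g, %g] m>\n",
    x$camera_id %||% "?", x$marker_start_px, x$marker_end_px,
    x$metres_per_pixel, x$segment_offset_m,
    x$segment_offset_m + x$segment_span_m))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a pixel column to track metres
#'
#' Affine map: `(x_px - marker_end_px) * metres_per_pixel +
#' segment_offset_m`. Only the horizontal pixel coordinate enters; the
#' vertical centroid is diagnostic only.
#'
#' @param x_px Pixel column(s) of the body centroid.
#' @param cal A `CameraCalibration`.
#' @return World location(s) in metres along the track.
#' @export
pixel_to_world <- function(x_px, cal) {
  (x_px - cal$marker_end_px) * cal$metres_per_pixel + cal$segment_offset_m
}

#' Inverse of [pixel_to_world()]
#'
#' @param location_m World location(s) in metres.
#' @param cal A `CameraCalibration`.
#' @return Pixel column(s).
#' @export
world_to_pixel <- function(location_m, cal) {
  (location_m - cal$segment_offset_m) / cal$metres_per_pixel +
    cal$marker_end_px
}

#' Convert a centroid track to world metres for one camera segment
#'
#' Applies [pixel_to_world()] to every present centroid; entries mapping
#' outside the camera's segment range (with `slack_m` of tolerance on each
#' side, since the centre of mass legitimately crosses a marker line
#' mid-frame) are set missing — the athlete is not yet, or no longer, in
#' view.
#'
#' @param track A `CentroidTrack` from [detect_track()].
#' @param cal The camera's `CameraCalibration`.
#' @param slack_m Out-of-range slack in metres (default 1).
#' @return A `SegmentTrack`: data frame with columns `frame`, `location_m`,
#'   and attributes `camera_id`, `valid_range_m`, `frame_rate_hz`.
#' @export
to_segment_track <- function(track, cal, slack_m = 1) {
  if (!is.null(cal$camera_id) &&
      !identical(attr(track, "camera_id"), cal$camera_id)) {
    sv_stop_validation("camera id mismatch: track ",
                       attr(track, "camera_id"), " vs calibration ",
                       cal$camera_id)
  }
  loc <- pixel_to_world(track$x_px, cal)
  lo <- cal$segment_offset_m
  hi <- cal$segment_offset_m + cal$segment_span_m
  loc[!is.na(loc) & (loc < lo - slack_m | loc > hi + slack_m)] <- NA_real_
  structure(data.frame(frame = track$frame, location_m = loc),
            camera_id = attr(track, "camera_id"),
            frame_rate_hz = attr(track, "frame_rate_hz"),
            valid_range_m = c(lo, hi),
            class = c("SegmentTrack", "data.frame"))
}

#' Build the standard four-camera calibration set
#'
#' Convenience constructor for the standard layout: four cameras covering
#' 0-25, 25-50, 50-75 and 75-100 m.
#'
#' @param entries List of per-camera lists with fields `camera_id`,
#'   `marker_start_px`, `marker_end_px`, `segment_span_m`,
#'   `segment_offset_m` (as stored in the JSON config `cameras` block).
#' @return Named list of `CameraCalibration` objects.
#' @export
calibrations_from_config <- function(entries) {
  if (is.null(entries) || length(entries) == 0) {
    sv_stop_validation("no camera calibration entries in config")
  }
  cals <- lapply(entries, function(e) {
    calibrate_camera(e$marker_start_px, e$marker_end_px,
                     e$segment_span_m %||% 25, e$segment_offset_m,
                     camera_id = e$camera_id)
  })
  names(cals) <- vapply(cals, function(c) c$camera_id %||% "", character(1))
  cals
}
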