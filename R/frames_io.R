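#' Run configuration
#'
#' Bundles the tunable parameters of the tracking pipeline. Defaults follow
#' the published system: grayscale difference threshold tau = 40, 3x3 median
#' denoising, a 4-frame velocity window at 30 Hz, and 10-m subtasks over a
#' 100-m track.
#'
#' @param threshold_tau Grayscale difference threshold in `[0, 255]`; a pixel
#'   is foreground when `|frame - background| > threshold_tau`.
#' @param median_kernel_px Odd side length of the square median-filter kernel
#'   (pixels).
#' @param velocity_window_frames Forward-difference window for instantaneous
#'   speed (frames).
#' @param subtask_length_m Width of one subtask bin (metres); must divide
#'   `track_length_m`.
#' @param track_length_m Total run distance (metres).
#' @param smoothing_window_frames Odd window of the centred moving average
#'   applied to the fused position series; 1 disables smoothing.
#' @param min_blob_area_px Smallest connected component (pixels) accepted as
#'   the athlete.
#' @param frame_rate_hz Nominal capture rate shared by all cameras (Hz).
#' @param cameras Optional list of per-camera calibration entries (see
#'   [calibrate_camera()]); each entry is a list with `camera_id`,
#'   `marker_start_px`, `marker_end_px`, `segment_span_m`, `segment_offset_m`.
#'
#' @return An object of class `RunConfig` (a named list).
#' @seealso [load_run_config()]
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$threshold_tau
run_config <- function(threshold_tau = 40,
                       median_kernel_px = 3,
                       velocity_window_frames = 4,
                       subtask_length_m = 10,
                       track_length_m = 100,
                       smoothing_window_frames = 5,
                       min_blob_area_px = 25,
                       frame_rate_hz = 30,
                       cameras = NULL) {
  cfg <- list(
    threshold_tau = as.numeric(threshold_tau),
    median_kernel_px = as.integer(median_kernel_px),
    velocity_window_frames = as.integer(velocity_window_frames),
    subtask_length_m = as.numeric(subtask_length_m),
    track_length_m = as.numeric(track_length_m),
    smoothing_window_frames = as.integer(smoothing_window_frames),
    min_blob_area_px = as.integer(min_blob_area_px),
    frame_rate_hz = as.numeric(frame_rate_hz),
    cameras = cameras
  )
  class(cfg) <- "RunConfig"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.finite(cfg$threshold_tau) ||
      cfg$threshold_tau < 0 || cfg$threshold_tau > 255) {
    sv_stop_validation("threshold_tau must lie in [0, 255], got ",
                       cfg$threshold_tau)
  }
  if (is.na(cfg$median_kernel_px) || cfg$median_kernel_px < 1 ||
      cfg$median_kernel_px %% 2 == 0) {
    sv_stop_validation("median_kernel_px must be an odd integer >= 1, got ",
                       cfg$median_kernel_px)
  }
  if (is.na(cfg$velocity_window_frames) || cfg$velocity_window_frames < 1) {
    sv_stop_validation("velocity_window_frames must be >= 1, got ",
                       cfg$velocity_window_frames)
  }
  if (!is.finite(cfg$track_length_m) || cfg$track_length_m <= 0) {
    sv_stop_validation("track_length_m must be positive, got ",
                       cfg$track_length_m)
  }
  if (!is.finite(cfg$subtask_length_m) || cfg$subtask_length_m <= 0 ||
      abs(cfg$track_length_m / cfg$subtask_length_m -
          round(cfg$track_length_m / cfg$subtask_length_m)) > 1e-9) {
    sv_stop_validation("subtask_length_m (", cfg$subtask_length_m,
                       ") must divide track_length_m (",
                       cfg$track_length_m, ")")
  }
  if (is.na(cfg$smoothing_window_frames) || cfg$smoothing_window_frames < 1 ||
      cfg$smoothing_window_frames %% 2 == 0) {
    sv_stop_validation("smoothing_window_frames must be an odd integer >= 1, ",
                       "got ", cfg$smoothing_window_frames)
  }
  if (is.na(cfg$min_blob_area_px) || cfg$min_blob_area_px < 1) {
    sv_stop_validation("min_blob_area_px must be >= 1, got ",
                       cfg$min_blob_area_px)
  }
  if (!is.finite(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0) {
    sv_stop_validation("frame_rate_hz must be positive, got ",
                       cfg$frame_rate_hz)
  }
  invisible(cfg)
}

#' Load a run configuration from JSON
#'
#' Reads a JSON object whose keys match the arguments of [run_config()];
#' unspecified keys take the defaults. An optional `cameras` array carries the
#' per-camera marker calibration block.
#'
#' @param path Path to a JSON configuration file.
#' @return A `RunConfig` object.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    sv_stop_io("config file not found: ", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  known <- setdiff(names(formals(run_config)), "cameras")
  unknown <- setdiff(names(raw), c(known, "cameras"))
  if (length(unknown) > 0) {
    sv_stop_validation("unknown config field(s): ",
                       paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#'
#' @param cfg A `RunConfig` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  x <- unclass(cfg)
  if (is.null(x$cameras)) x$cameras <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Construct a frame sequence
#'
#' An ordered set of grayscale frames from one camera. Frames are matrices in
#' row-column (y, x) orientation with intensities in `[0, 255]`.
#'
#' @param camera_id Camera identifier (e.g. `"cam1"`).
#' @param frames List of numeric or integer matrices, all the same size.
#' @param frame_rate_hz Frames per second.
#' @return An object of class `FrameSequence`.
#' @export
frame_sequence <- function(camera_id, frames, frame_rate_hz = 30) {
  if (length(frames) < 1) {
    sv_stop_validation("no frames for camera ", camera_id)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    sv_stop_validation("mixed frame dimensions for camera ", camera_id)
  }
  rng <- range(vapply(frames, function(f) range(f), numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    sv_stop_validation("frame intensities outside [0, 255] for camera ",
                       camera_id)
  }
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    sv_stop_validation("frame_rate_hz must be positive for camera ", camera_id)
  }
  structure(
    list(camera_id = camera_id, frames = frames,
         frame_rate_hz = frame_rate_hz,
         width_px = dims[2, 1], height_px = dims[1, 1]),
    class = "FrameSequence"
  )
}

#' @export
print.FrameSequence <- function(x, ...) {
  cat(sprintf("<FrameSequence %s: %d frames, %dx%d px, %g Hz>\n",
              x$camera_id, length(x$frames), x$width_px, x$height_px,
              x$frame_rate_hz))
  invisible(x)
}

# PNG (0..1) -> grayscale 0..255 matrix. Colour planes are collapsed by the
# Rec.601 luma weighting; the pipeline is defined on grayscale intensities.
png_to_gray <- function(arr) {
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    if (ch >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  round(arr * 255)
}

#' Read a directory of PNG frames as a frame sequence
#'
#' Frames are ordered lexicographically by filename; zero-padded integer
#' filenames (`frame_00001.png`, ...) therefore define the temporal order.
#' Colour PNGs are converted to grayscale by the standard luma weighting.
#'
#' @param path Directory containing `.png` frames.
#' @param camera_id Camera identifier used in messages and downstream tracks.
#' @param frame_rate_hz Capture rate; PNG carries no rate metadata, so this
#'   must come from the run configuration.
#' @return A `FrameSequence`.
#' @export
read_frame_sequence <- function(path, camera_id, frame_rate_hz = 30) {
  if (!dir.exists(path)) {
    sv_stop_io("frame directory not found for camera ", camera_id, ": ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) {
    sv_stop_io("no frames for camera ", camera_id, " in ", path)
  }
  frames <- lapply(files, function(f) png_to_gray(png::readPNG(f)))
  frame_sequence(camera_id, frames, frame_rate_hz)
}

#' Write a frame sequence as PNG files
#'
#' @param seq A `FrameSequence`.
#' @param path Output directory (created if needed); frames are written as
#'   `frame_%05d.png`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frame_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "FrameSequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    paths[i] <- file.path(path, sprintf("frame_%05d.png", i))
    png::writePNG(seq$frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}

#' Check the four-camera synchronization contract
#'
#' All sequences must share the same frame rate and frame count, with frame 0
#' corresponding to the common start signal.
#'
#' @param sequences List of `FrameSequence` objects.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_synchronized <- function(sequences) {
  rates <- vapply(sequences, function(s) s$frame_rate_hz, numeric(1))
  if (length(unique(rates)) != 1) {
    sv_stop_validation("cameras disagree on frame rate: ",
                       paste(rates, collapse = ", "))
  }
  ns <- vapply(sequences, function(s) length(s$frames), integer(1))
  if (length(unique(ns)) != 1) {
    sv_stop_validation("cameras disagree on frame count: ",
                       paste(ns, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a track to CSV
#'
#' Serializes a centroid, segment, or world track as CSV with a header row and
#' empty fields for missing values, so a write/read round trip is lossless.
#'
#' @param track A data frame (e.g. from [detect_track()], [to_segment_track()]
#'   or [stitch_tracks()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_track_csv <- function(track, path) {
  df <- as.data.frame(track)
  if (nrow(df) == 0) {
    sv_stop_validation("refusing to write an empty track")
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE, na = "",
                       qmethod = "double")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sv_stop_io("cannot write track to ", path)
  invisible(path)
}

#' Read a track CSV written by [write_track_csv()]
#'
#' @param path CSV path.
#' @return A data frame; empty fields become `NA`.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) sv_stop_io("track file not found: ", path)
  utils::read.csv(path, na.strings = "")
}
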