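#' Background subtraction
#'
#' Absolute per-pixel difference between a frame and the pre-captured empty
#' background. The absolute value makes detection insensitive to whether the
#' athlete is darker or lighter than the track behind them.
#'
#' @param frame,background Grayscale matrices of identical dimensions with
#'   values in `[0, 255]`.
#' @return A numeric matrix of absolute differences in `[0, 255]`.
#' @export
#' @examples
#' subtract_background(matrix(200, 2, 2), matrix(160, 2, 2))
subtract_background <- function(frame, background) {
  if (!identical(dim(frame), dim(background))) {
    sv_stop_validation("frame (", paste(dim(frame), collapse = "x"),
                       ") and background (",
                       paste(dim(background), collapse = "x"),
                       ") dimensions differ")
  }
  abs(frame - background)
}

#' Threshold a difference image into a binary foreground mask
#'
#' A pixel is foreground (1) when its background-subtracted difference
#' strictly exceeds `tau`, background (0) otherwise. Single pass, no
#' hysteresis.
#'
#' @param diff Difference matrix from [subtract_background()].
#' @param tau Threshold in `[0, 255]`; the system default is 40.
#' @return An integer matrix of 0/1 values, same dimensions as `diff`.
#' @export
threshold_and_binarize <- function(diff, tau = 40) {
  if (!is.finite(tau) || tau < 0 || tau > 255) {
    sv_stop_validation("tau must lie in [0, 255], got ", tau)
  }
  mask <- (diff > tau) + 0L
  dim(mask) <- dim(diff)
  mask
}

# Pad a matrix by edge replication: pad rows/cols repeat the border values.
pad_replicate <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rep(1L, pad), seq_len(nr), rep(nr, pad))
  cidx <- c(rep(1L, pad), seq_len(nc), rep(nc, pad))
  m[ridx, cidx, drop = FALSE]
}

#' Median-filter a binary mask
#'
#' Per-pixel median over a `kernel_px` x `kernel_px` neighbourhood with the
#' border handled by edge replication. For a binary mask the median is 1
#' exactly when more than half of the window is foreground, which is computed
#' with a summed-area table; isolated salt-and-pepper pixels are removed.
#'
#' @param mask Binary 0/1 matrix.
#' @param kernel_px Odd kernel side length (default 3).
#' @return A binary 0/1 integer matrix of the same dimensions.
#' @export
denoise_mask <- function(mask, kernel_px = 3) {
  if (is.na(kernel_px) || kernel_px < 1 || kernel_px %% 2 == 0) {
    sv_stop_validation("median kernel must be an odd integer >= 1, got ",
                       kernel_px)
  }
  if (kernel_px == 1) return(mask + 0L)
  pad <- (kernel_px - 1L) / 2L
  p <- pad_replicate(mask, pad)
  nr <- nrow(mask); nc <- ncol(mask)
  k <- as.integer(kernel_px)
  npr <- nr + 2L * pad
  fg <- which(p == 1L)
  need <- (k * k + 1L) / 2L
  if (length(fg) * k * k < nr * nc / 4) {
    # sparse path: masks are mostly empty, so scatter each padded
    # foreground pixel into the counts of the <= k^2 windows covering it.
    # The window anchored at output (i, j) spans padded rows i..i+k-1 and
    # padded cols j..j+k-1, so padded pixel (rp, cp) feeds anchors
    # (rp - dr, cp - dc) for dr, dc in 0..k-1.
    rp <- (fg - 1L) %% npr + 1L
    cp <- (fg - 1L) %/% npr + 1L
    idx <- vector("list", k * k)
    t <- 0L
    for (dr in 0:(k - 1)) {
      i <- rp - dr
      for (dc in 0:(k - 1)) {
        j <- cp - dc
        ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
        t <- t + 1L
        idx[[t]] <- (j[ok] - 1L) * nr + i[ok]
      }
    }
    counts <- tabulate(unlist(idx), nbins = nr * nc)
    out <- (counts >= need) + 0L
    dim(out) <- dim(mask)
    return(out)
  }
  # dense path: window sum as the sum of the k^2 shifted views
  wins <- matrix(0L, nr, nc)
  for (dr in 0:(k - 1)) {
    rows <- dr + seq_len(nr)
    for (dc in 0:(k - 1)) {
      wins <- wins + p[rows, dc + seq_len(nc)]
    }
  }
  out <- (wins >= need) + 0L
  dim(out) <- dim(mask)
  out
}

#' Label connected components of a binary mask
#'
#' 8-connected component labelling (diagonal neighbours join), implemented as
#' run-length encoding of foreground runs per row followed by union-find
#' merging of runs that touch between adjacent rows.
#'
#' @param mask Binary 0/1 matrix.
#' @return An integer matrix where background is 0 and each component carries
#'   a distinct positive label.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  # runs of 1s per row: for each row, starts/ends of maximal 1-runs
  run_row <- integer(0); run_start <- integer(0); run_end <- integer(0)
  run_id <- integer(0)
  nruns <- 0L
  occupied <- which(rowSums(mask) > 0)
  for (r in occupied) {
    v <- mask[r, ]
    d <- diff(c(0L, v, 0L))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    for (k in seq_along(st)) {
      nruns <- nruns + 1L
      run_row[nruns] <- r; run_start[nruns] <- st[k]; run_end[nruns] <- en[k]
    }
  }
  if (nruns == 0L) return(labels)
  parent <- seq_len(nruns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # union runs in adjacent rows whose column spans touch (8-connectivity
  # extends the previous run's span by one column on each side)
  by_row <- split(seq_len(nruns), run_row)
  row_keys <- as.integer(names(by_row))
  for (ri in seq_along(row_keys)) {
    r <- row_keys[ri]
    prev <- by_row[[as.character(r - 1L)]]
    if (is.null(prev)) next
    for (i in by_row[[ri]]) {
      touching <- prev[run_start[prev] <= run_end[i] + 1L &
                       run_end[prev] >= run_start[i] - 1L]
      for (j in touching) {
        ri_ <- find(i); rj_ <- find(j)
        if (ri_ != rj_) parent[ri_] <- rj_
      }
    }
  }
  roots <- vapply(seq_len(nruns), find, integer(1))
  comp <- match(roots, unique(roots))
  for (k in seq_len(nruns)) {
    labels[run_row[k], run_start[k]:run_end[k]] <- comp[k]
  }
  labels
}

#' Locate the athlete's centroid in a binary mask
#'
#' Components smaller than `min_blob_area_px` are discarded; the largest
#' surviving component is taken as the body and its centroid is the
#' arithmetic mean of the member pixel coordinates (the geometric centre of
#' mass of the blob). Area ties are broken by the smaller top-left corner of
#' the bounding box (row, then column).
#'
#' @param mask Binary 0/1 matrix.
#' @param min_blob_area_px Smallest accepted component area in pixels.
#' @return Named numeric vector `c(x = column, y = row)` of the centroid, or
#'   `c(x = NA, y = NA)` when no component survives — a missing detection is
#'   a value, not an error.
#' @export
locate_centroid <- function(mask, min_blob_area_px = 25) {
  labels <- label_components(mask)
  ncomp <- max(labels)
  if (ncomp == 0L) return(c(x = NA_real_, y = NA_real_))
  areas <- tabulate(labels[labels > 0L], nbins = ncomp)
  keep <- which(areas >= min_blob_area_px)
  if (length(keep) == 0L) return(c(x = NA_real_, y = NA_real_))
  if (length(keep) > 1L) {
    amax <- max(areas[keep])
    cand <- keep[areas[keep] == amax]
    if (length(cand) > 1L) {
      corners <- t(vapply(cand, function(k) {
        w <- which(labels == k, arr.ind = TRUE)
        c(min(w[, 1]), min(w[, 2]))
      }, numeric(2)))
      cand <- cand[order(corners[, 1], corners[, 2])]
    }
    best <- cand[1]
  } else {
    best <- keep
  }
  w <- which(labels == best, arr.ind = TRUE)
  c(x = mean(w[, 2]), y = mean(w[, 1]))
}

# One frame through subtract -> threshold -> denoise -> centroid.
detect_frame <- function(frame, background, config) {
  d <- subtract_background(frame, background)
  m <- threshold_and_binarize(d, config$threshold_tau)
  m <- denoise_mask(m, config$median_kernel_px)
  locate_centroid(m, config$min_blob_area_px)
}

#' Detect the athlete in every frame of a sequence
#'
#' Applies background subtraction, thresholding, median denoising and
#' largest-blob centroid extraction to each frame. Frames where no component
#' survives the area filter yield missing entries.
#'
#' @param seq A `FrameSequence`.
#' @param background Grayscale background matrix captured before the run,
#'   same dimensions as the frames.
#' @param config A `RunConfig`.
#' @return A `CentroidTrack`: data frame with columns `frame` (0-based index;
#'   frame 0 is the start signal), `x_px`, `y_px`, plus attributes
#'   `camera_id` and `frame_rate_hz`. Missing detections are `NA`.
#' @export
detect_track <- function(seq, background, config = run_config()) {
  stopifnot(inherits(seq, "FrameSequence"))
  if (!identical(as.integer(dim(background)),
                 c(seq$height_px, seq$width_px))) {
    sv_stop_validation("background dimensions do not match frames for ",
                       "camera ", seq$camera_id)
  }
  n <- length(seq$frames)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    cen <- detect_frame(seq$frames[[i]], background, config)
    xs[i] <- cen[["x"]]; ys[i] <- cen[["y"]]
  }
  centroid_track(seq$camera_id, data.frame(frame = 0:(n - 1),
                                           x_px = xs, y_px = ys),
                 seq$frame_rate_hz)
}

centroid_track <- function(camera_id, entries, frame_rate_hz) {
  stopifnot(all(diff(entries$frame) > 0))
  structure(entries, camera_id = camera_id, frame_rate_hz = frame_rate_hz,
            class = c("CentroidTrack", "data.frame"))
}
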