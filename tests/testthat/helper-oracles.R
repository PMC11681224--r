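# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: exhaustive pixel loops, recursive flood fill, and
# naive interpolation, usable only on small inputs.

oracle_abs_diff <- function(frame, background) {
  out <- frame
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      out[i, j] <- abs(frame[i, j] - background[i, j])
    }
  }
  out
}

oracle_threshold_count <- function(diff, tau) {
  n <- 0L
  for (i in seq_len(nrow(diff))) {
    for (j in seq_len(ncol(diff))) {
      if (diff[i, j] > tau) n <- n + 1L
    }
  }
  n
}

# sliding-window median with edge replication
oracle_median_filter <- function(mask, k) {
  pad <- (k - 1) / 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - pad):(i + pad), 1), nr)
      ci <- pmin(pmax((j - pad):(j + pad), 1), nc)
      out[i, j] <- as.integer(stats::median(mask[ri, ci]))
    }
  }
  out
}

# 8-connected labelling by iterative stack-based flood fill
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (mask[i0, j0] == 1L && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
              mask[i, j] == 1L && lab[i, j] == 0L) {
            lab[i, j] <- cur
            stack[[length(stack) + 1]] <- c(i, j)
          }
        }
      }
    }
  }
  lab
}

# largest surviving blob centroid via the flood-fill labels
oracle_centroid <- function(mask, min_area) {
  lab <- oracle_label(mask)
  if (max(lab) == 0) return(c(x = NA_real_, y = NA_real_))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(c(x = NA_real_, y = NA_real_))
  best <- keep[which.max(areas[keep])]
  w <- which(lab == best, arr.ind = TRUE)
  c(x = mean(w[, 2]), y = mean(w[, 1]))
}

# two-neighbour linear interpolation against frame index
oracle_fill <- function(frame, loc) {
  out <- loc
  present <- which(!is.na(loc))
  for (i in seq_along(loc)) {
    if (is.na(loc[i])) {
      before <- present[present < i]
      after <- present[present > i]
      if (length(before) == 0) {
        out[i] <- loc[after[1]]
      } else if (length(after) == 0) {
        out[i] <- loc[before[length(before)]]
      } else {
        a <- before[length(before)]; b <- after[1]
        out[i] <- loc[a] + (loc[b] - loc[a]) *
          (frame[i] - frame[a]) / (frame[b] - frame[a])
      }
    }
  }
  out
}

# filter-and-mean subtask oracle on velocity samples
oracle_bin_means <- function(loc, speed, width, total) {
  nb <- total / width
  out <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1) * width; hi <- b * width
    sel <- if (b == nb) loc >= lo & loc <= hi else loc >= lo & loc < hi
    if (any(sel)) out[b] <- mean(speed[sel])
  }
  out
}
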