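test_that("background subtraction matches the exhaustive per-pixel oracle", {
  expect_equal(subtract_background(matrix(7, 4, 4), matrix(7, 4, 4)),
               matrix(0, 4, 4))
  expect_equal(subtract_background(matrix(200, 1, 1), matrix(160, 1, 1)),
               matrix(40, 1, 1))
  set.seed(21)
  f <- matrix(sample(0:255, 400, TRUE), 20, 20)
  b <- matrix(sample(0:255, 400, TRUE), 20, 20)
  expect_identical(subtract_background(f, b), oracle_abs_diff(f, b))
  expect_error(subtract_background(matrix(0, 2, 3), matrix(0, 3, 2)),
               "dimensions differ")
})

test_that("thresholding is strict, binary, and count-exact against the oracle", {
  expect_equal(threshold_and_binarize(matrix(41, 1, 1), 40)[1, 1], 1L)
  expect_equal(threshold_and_binarize(matrix(40, 1, 1), 40)[1, 1], 0L)
  expect_equal(sum(threshold_and_binarize(matrix(0, 8, 8), 40)), 0L)
  set.seed(22)
  for (tau in c(0, 40, 254)) {
    d <- matrix(sample(0:255, 900, TRUE), 30, 30)
    m <- threshold_and_binarize(d, tau)
    expect_true(all(m %in% c(0L, 1L)))
    expect_equal(sum(m), oracle_threshold_count(d, tau))
  }
  expect_error(threshold_and_binarize(matrix(0, 2, 2), 256), "\\[0, 255\\]")
})

test_that("raising the threshold never increases the foreground count", {
  set.seed(23)
  d <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  counts <- vapply(seq(0, 250, by = 10),
                   function(tau) sum(threshold_and_binarize(d, tau)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("median denoising removes speckle, keeps solids, and matches the naive filter", {
  lone <- matrix(0L, 9, 9); lone[5, 5] <- 1L
  expect_equal(sum(denoise_mask(lone, 3)), 0L)

  solid <- matrix(0L, 14, 14); solid[3:12, 3:12] <- 1L
  expect_equal(denoise_mask(solid, 3)[4:11, 4:11], solid[4:11, 4:11])

  # salt-and-pepper at several densities exercises both the sparse scatter
  # path and the dense shifted-sum path, including border replication
  set.seed(24)
  for (dens in c(0.01, 0.08, 0.5, 0.9)) {
    m <- matrix(rbinom(35 * 28, 1, dens), 35, 28)
    for (k in c(3L, 5L)) {
      out <- denoise_mask(m, k)
      expect_identical(out, oracle_median_filter(m, k))
      expect_true(all(out %in% c(0L, 1L)))
    }
  }
  expect_identical(denoise_mask(lone, 1), lone)
  expect_error(denoise_mask(lone, 4), "odd")
})

test_that("component labelling is 8-connected and equivalent to flood fill", {
  diag2 <- matrix(0L, 5, 5); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(max(label_components(diag2)), 1L)  # diagonal touch joins

  set.seed(25)
  for (rep in 1:8) {
    m <- matrix(rbinom(50 * 50, 1, runif(1, 0.1, 0.5)), 50, 50)
    mine <- label_components(m)
    ref <- oracle_label(m)
    expect_equal(max(mine), max(ref))
    # identical partitions up to label permutation: the (mine, ref) label
    # pairs over foreground pixels must form a bijection
    pairs <- unique(paste(mine[mine > 0], ref[mine > 0]))
    expect_length(pairs, max(ref))
  }
})

test_that("centroid extraction picks the largest surviving blob, mean of its pixels", {
  one <- matrix(0L, 10, 10); one[7, 5] <- 1L
  expect_equal(locate_centroid(one, 1), c(x = 5, y = 7))

  block <- matrix(0L, 10, 20); block[2:4, 10:12] <- 1L
  expect_equal(locate_centroid(block, 1), c(x = 11, y = 3))

  two <- matrix(0L, 30, 30)
  two[2:6, 2:11] <- 1L            # area 50
  two[20:23, 20:22] <- 1L         # area 12, below the filter
  got <- locate_centroid(two, 20)
  expect_equal(got, oracle_centroid(two, 20))
  expect_equal(got, c(x = mean(2:11), y = mean(2:6)))

  expect_equal(locate_centroid(matrix(0L, 5, 5), 1),
               c(x = NA_real_, y = NA_real_))
  # everything below the area filter is a missing value, not an error
  expect_equal(locate_centroid(one, 2), c(x = NA_real_, y = NA_real_))

  set.seed(26)
  for (rep in 1:6) {
    m <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
    expect_equal(locate_centroid(m, 5), oracle_centroid(m, 5))
  }
})

test_that("a returned centroid lies inside the selected component's bounding box", {
  set.seed(27)
  for (rep in 1:10) {
    m <- matrix(0L, 30, 30)
    r0 <- sample(1:20, 1); c0 <- sample(1:20, 1)
    m[r0:(r0 + sample(3:9, 1)), c0:(c0 + sample(3:9, 1))] <- 1L
    cen <- locate_centroid(m, 1)
    w <- which(m == 1L, arr.ind = TRUE)
    expect_gte(cen[["x"]], min(w[, 2])); expect_lte(cen[["x"]], max(w[, 2]))
    expect_gte(cen[["y"]], min(w[, 1])); expect_lte(cen[["y"]], max(w[, 1]))
  }
})

test_that("a translating dark rectangle is tracked at its true per-frame centroid", {
  bg <- matrix(160, 120, 260)
  cfg <- run_config()
  mk <- function(x0) {
    f <- bg
    f[30:89, x0:(x0 + 19)] <- 30  # 20 px wide, 60 px tall
    f
  }
  xs <- 10 + 4 * (0:39)
  seq1 <- frame_sequence("camT", lapply(xs, mk), 30)
  trk <- detect_track(seq1, bg, cfg)
  expect_false(anyNA(trk$x_px))
  expect_equal(diff(trk$x_px), rep(4, 39), tolerance = 0.5)
  expect_equal(trk$x_px, xs + 9.5, tolerance = 1e-9)
  expect_equal(trk$y_px, rep(59.5, 40), tolerance = 1e-9)

  # frames identical to the background carry only missing entries
  still <- frame_sequence("camT", rep(list(bg), 5), 30)
  trk0 <- detect_track(still, bg, cfg)
  expect_true(all(is.na(trk0$x_px)))
})

test_that("detection survives 5% salt-and-pepper noise with small centroid error", {
  bg <- matrix(160, 120, 260)
  cfg <- run_config()
  set.seed(28)
  xs <- 10 + 4 * (0:39)
  frames <- lapply(xs, function(x0) {
    f <- bg
    f[30:89, x0:(x0 + 19)] <- 30
    flip <- matrix(stats::runif(length(f)) < 0.05, nrow(f), ncol(f))
    f[flip] <- sample(c(0, 255), sum(flip), TRUE)
    f
  })
  trk <- detect_track(frame_sequence("camN", frames, 30), bg, cfg)
  detected <- !is.na(trk$x_px)
  expect_gte(mean(detected), 0.95)
  expect_lte(max(abs(trk$x_px[detected] - (xs + 9.5)[detected])), 2)
})
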