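# Image preparation operations.

test_that("max_project takes the per-pixel maximum and inherits calibration", {
  s1 <- raster_image(matrix(c(0, 5), 1, 2), pixel_size_um = 3)
  s2 <- raster_image(matrix(c(3, 2), 1, 2), pixel_size_um = 3)
  out <- max_project(zstack(list(s1, s2), step_um = 25.2))
  expect_equal(out$values, matrix(c(3, 5), 1, 2))
  expect_equal(out$pixel_size_um, 3)

  # single-slice identity
  expect_equal(max_project(zstack(list(s1)))$values, s1$values)

  # brute-force loop oracle on random 16x16 stacks, any slice order
  set.seed(7)
  slices <- lapply(1:3, function(i)
    raster_image(matrix(sample(0:255, 256, TRUE), 16, 16)))
  oracle <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16)
    oracle[r, c] <- max(vapply(slices, function(s) s$values[r, c], numeric(1)))
  expect_equal(max_project(zstack(slices))$values, oracle)
  expect_equal(max_project(zstack(rev(slices)))$values, oracle)
})

test_that("auto_contrast rescales quantiles to the full range", {
  const <- raster_image(matrix(40, 8, 8))
  expect_equal(auto_contrast(const)$values, const$values)

  ramp <- raster_image(matrix(seq(0, 100, length.out = 101), 1, 101))
  out <- auto_contrast(ramp, saturation_fraction = 0)
  expect_equal(out$values, matrix(seq(0, 100, length.out = 101) / 100 * 255, 1, 101))

  full <- raster_image(matrix(seq(0, 255, length.out = 256), 16, 16))
  expect_equal(auto_contrast(full, 0)$values, full$values)
  expect_error(auto_contrast(full, 0.6), "saturation")

  # dimensions and calibration preserved
  img <- raster_image(matrix(runif(96, 10, 200), 8, 12), pixel_size_um = 1.7)
  out <- auto_contrast(img)
  expect_equal(dim(out$values), c(8, 12))
  expect_equal(out$pixel_size_um, 1.7)
})

test_that("sharpen applies the 3x3 (12, -1)/4 kernel with replicate padding", {
  const <- raster_image(matrix(77, 9, 9))
  expect_equal(sharpen(const)$values, const$values)

  one <- matrix(0, 7, 7); one[4, 4] <- 4
  out <- sharpen(raster_image(one))
  expect_equal(out$values[4, 4], 12)        # 4 * 12 / 4
  expect_equal(out$values[3, 3], 0)         # -4/4 clipped to 0
  expect_equal(sum(out$values), 12)

  # border pixels unchanged under replicate padding of a constant image
  expect_equal(sharpen(const)$values[1, ], rep(77, 9))
})

test_that("reduce_haze subtracts the morphological opening", {
  zero <- raster_image(matrix(0, 30, 30))
  expect_equal(reduce_haze(zero, 5)$values, zero$values)

  const <- raster_image(matrix(50, 30, 30))
  expect_equal(reduce_haze(const, 5)$values, matrix(0, 30, 30))

  # 3-px bright line on background 50: line survives, background vanishes
  m <- matrix(50, 40, 60); m[19:21, ] <- 200
  out <- reduce_haze(raster_image(m), 10)
  expect_true(all(out$values[19:21, 20:40] > 100))
  expect_true(all(out$values[c(1:10, 30:40), ] == 0))
  # direct double-loop opening oracle on a small image
  small <- matrix(50, 12, 12); small[6, 3:9] <- 130
  r <- 3
  ero <- matrix(NA_real_, 12, 12); dil <- matrix(NA_real_, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      if (di^2 + dj^2 <= r^2 && i + di >= 1 && i + di <= 12 &&
          j + dj >= 1 && j + dj <= 12)
        vals <- c(vals, small[i + di, j + dj])
    ero[i, j] <- min(vals)
  }
  for (i in 1:12) for (j in 1:12) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      if (di^2 + dj^2 <= r^2 && i + di >= 1 && i + di <= 12 &&
          j + dj >= 1 && j + dj <= 12)
        vals <- c(vals, ero[i + di, j + dj])
    dil[i, j] <- max(vals)
  }
  expect_equal(reduce_haze(raster_image(small), r)$values,
               pmax(small - dil, 0))
  expect_error(reduce_haze(raster_image(matrix(0, 5, 5)), 10), "larger")
})

test_that("extract_polygon_roi crops and masks by pixel-center inclusion", {
  img <- raster_image(matrix(255, 10, 10))
  whole <- polygon_roi(rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9)))
  expect_equal(extract_polygon_roi(img, whole)$values, img$values)

  left <- polygon_roi(rbind(c(0, 0), c(4, 0), c(4, 9), c(0, 9)))
  out <- extract_polygon_roi(img, left)
  expect_equal(dim(out$values), c(10, 5))
  expect_true(all(out$values == 255))

  # triangle: retained pixel count equals the winding-number oracle
  tri <- polygon_roi(rbind(c(1, 1), c(8, 2), c(4, 8)))
  got <- extract_polygon_roi(img, tri)
  xs <- rep(0:9, each = 10); ys <- rep(0:9, times = 10)
  n_oracle <- sum(oracle_in_polygon(xs, ys, tri$vertices))
  expect_equal(sum(got$values > 0), n_oracle)

  far <- polygon_roi(rbind(c(100, 100), c(120, 100), c(110, 120)))
  expect_error(extract_polygon_roi(img, far), "outside")
})

test_that("points_in_polygon matches the winding-number oracle on random polygons", {
  set.seed(11)
  for (rep in 1:5) {
    # star-shaped random polygon (simple by construction)
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 3, 9)
    v <- cbind(10 + rad * cos(ang), 10 + rad * sin(ang))
    roi <- polygon_roi(v)
    xs <- rep(0:20, each = 21); ys <- rep(0:20, times = 21)
    expect_equal(points_in_polygon(xs, ys, roi),
                 oracle_in_polygon(xs, ys, v))
  }
})

test_that("binarize with Otsu maximizes between-class variance", {
  expect_warning(m0 <- binarize(raster_image(matrix(0, 5, 5)), "otsu"),
                 "constant")
  expect_false(any(m0$foreground))

  # bimodal: exhaustive 256-level search oracle
  vals <- c(rep(10, 100), rep(200, 100))
  img <- raster_image(matrix(vals, 10, 20))
  mask <- binarize(img, "otsu")
  expect_equal(sum(mask$foreground), 100)
  expect_true(all(img$values[mask$foreground] == 200))
  bcv <- vapply(1:255, function(t) {
    n0 <- sum(vals < t); n1 <- sum(vals >= t)
    if (n0 == 0 || n1 == 0) return(-1)
    (n0 / 200) * (n1 / 200) * (mean(vals[vals < t]) - mean(vals[vals >= t]))^2
  }, numeric(1))
  t_star <- otsu_threshold(img$values)
  expect_gt(t_star, 10); expect_lte(t_star, 200)
  expect_equal(bcv[t_star], max(bcv))

  # Otsu equals brute-force search on random images
  set.seed(3)
  for (rep in 1:5) {
    v <- sample(0:255, 400, TRUE)
    bcv <- vapply(1:255, function(t) {
      n0 <- sum(v < t); n1 <- sum(v >= t)
      if (n0 == 0 || n1 == 0) return(-1)
      (n0 / 400) * (n1 / 400) * (mean(v[v < t]) - mean(v[v >= t]))^2
    }, numeric(1))
    expect_equal(bcv[otsu_threshold(v)], max(bcv))
  }

  expect_true(all(binarize(raster_image(matrix(255, 4, 4)),
                           "fixed", threshold = 128)$foreground))
})

test_that("16-bit images rescale to 8-bit before preparation", {
  img <- raster_image(matrix(c(0, 65535, 32768), 1, 3), bit_depth = 16)
  out <- to_8bit(img)
  expect_equal(out$bit_depth, 8L)
  expect_equal(out$values[1, 1:2], c(0, 255))
})
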