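# Cost image, live-wire tracing, snapping, refinement, rasterization.

test_that("compute_cost_image blends ridge and intensity terms", {
  const <- raster_image(matrix(128, 32, 32))
  cost <- compute_cost_image(const)
  expect_equal(max(cost) - min(cost), 0)          # uniform on constant input

  # analytic Gaussian ridge: cost minimized along the centerline row
  x <- matrix(rep(1:64, each = 64), 64)
  y <- matrix(rep(1:64, times = 64), 64)
  ridge <- 220 * exp(-((y - 32)^2) / (2 * 2^2))
  img <- raster_image(round(ridge))
  cost <- compute_cost_image(img, tracing_params(hessian_scale = 2))
  inner <- 10:54
  for (cc in c(16, 32, 48))
    expect_equal(which.min(cost[inner, cc]) + inner[1] - 1, 32)

  # gamma = 0: intensity only (independent of any ridge structure)
  p0 <- tracing_params(cost_weight = 0)
  c0 <- compute_cost_image(img, p0)
  expect_equal(unclass(c0), pmax(1 - img$values / 255, 1e-3),
               ignore_attr = TRUE)
  expect_error(tracing_params(cost_weight = 1.2), "cost_weight")
})

test_that("trace_segment finds the optimum (value-iteration oracle) and is symmetric", {
  # uniform cost: straight horizontal path
  cost <- matrix(0.5, 9, 20)
  p <- trace_segment(cost, c(2, 4), c(17, 4))
  expect_equal(unique(p[, 2]), 4)
  expect_equal(p[, 1], 2:17)

  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    cm <- matrix(runif(n * n, 0.05, 1), n, n)
    a <- c(0, 0); b <- c(n - 1, n - 1)
    got <- attr(trace_segment(cm, a, b), "cost")
    expect_equal(got, oracle_shortest_cost(cm, a, b), tolerance = 1e-9)
    # symmetry
    expect_equal(got, attr(trace_segment(cm, b, a), "cost"), tolerance = 1e-12)
  }
})

test_that("trace_segment respects the search window", {
  cost <- matrix(1, 50, 50)
  par <- tracing_params(search_window = c(11, 11))
  expect_error(trace_segment(cost, c(2, 2), c(40, 40), par), "window")
  p <- trace_segment(cost, c(20, 20), c(26, 20), par)
  expect_equal(nrow(p), 7)
})

test_that("tracing follows a curved vessel within 2 px of ground truth", {
  res <- generate_tree(tree_spec(depth = 0, curvature_amplitude_px = 10,
                                 background_level = 20))
  gt <- res$truth$branches[[1]]$polyline
  cost <- compute_cost_image(res$image)
  path <- trace_segment(cost, round(gt[1, ]), round(gt[nrow(gt), ]))
  dmin <- vapply(seq_len(nrow(path)), function(i)
    min(sqrt((gt[, 1] - path[i, 1])^2 + (gt[, 2] - path[i, 2])^2)), numeric(1))
  expect_gte(mean(dmin <= 2), 0.95)
})

test_that("snap_point returns the nearest lowest-cost pixel", {
  cost <- matrix(1, 21, 21)
  par <- tracing_params(snap_window = c(9, 9))
  expect_equal(snap_point(cost, c(10, 10), par), c(10, 10))  # uniform: unchanged

  cost[8, 11] <- 0.1                       # minimum at (x=10, y=7)
  expect_equal(snap_point(cost, c(10, 10), par), c(10, 7))
  # click exactly on the minimum: unchanged
  expect_equal(snap_point(cost, c(10, 7), par), c(10, 7))
  # argmin scan oracle over the window
  win <- expand.grid(x = 6:14, y = 6:14)
  costs <- cost[cbind(win$y + 1, win$x + 1)]
  best <- win[which.min(costs), ]
  expect_equal(snap_point(cost, c(10, 10), par), c(best$x, best$y))
})

test_that("refine_tracing smooths, subsamples and re-rasterizes", {
  straight <- cbind(x = 0:99, y = rep(5, 100))
  par <- tracing_params(smoothing_range = 5, subsampling_factor = 5)
  out <- refine_tracing(straight, par)
  expect_equal(out, straight, ignore_attr = TRUE)   # collinear: unchanged

  # subsample counting: 100 vertices, factor 5 -> 21 control vertices
  keep <- unique(c(seq(1, 100, by = 5), 100))
  expect_length(keep, 21)

  # square-wave zig-zag: smoothed path shorter than input, >= chord
  zig <- cbind(x = 0:59, y = rep(c(0, 3), 30))
  pathlen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  sm <- refine_tracing(zig, par)
  expect_lt(pathlen(sm), pathlen(zig))
  expect_gte(pathlen(sm) + 1e-9, sqrt(sum((zig[60, ] - zig[1, ])^2)))
  # endpoints kept
  expect_equal(sm[1, ], zig[1, ], ignore_attr = TRUE)
  expect_equal(sm[nrow(sm), ], zig[60, ], ignore_attr = TRUE)
  # 8-connected output
  d <- abs(diff(sm))
  expect_true(all(d <= 1) && all(rowSums(d) >= 1))
})

test_that("rasterize_tracing paints strokes of the requested width", {
  seg <- cbind(x = 5:25, y = rep(10, 21))
  tr <- tracing(list(seg), dims = c(21, 31))
  m1 <- rasterize_tracing(tr, line_width = 1)
  expect_equal(sum(m1$foreground), 21)
  expect_equal(unique(which(m1$foreground, arr.ind = TRUE)[, 1]), 11)

  m3 <- rasterize_tracing(tr, line_width = 3)
  expect_equal(sort(unique(which(m3$foreground, arr.ind = TRUE)[, 1])), 10:12)

  # round trip: thinning the width-3 stroke stays within 1 px of the path
  sk <- thin_mask(m3)
  co <- mask_coords(sk)
  expect_lte(hausdorff(co, seg), 1)
})

test_that("trace_branches runs the full seed-driven workflow", {
  res <- generate_tree(tree_spec(depth = 0, background_level = 20))
  gt <- res$truth$branches[[1]]$polyline
  seeds <- list(trunk = rbind(round(gt[1, ]), round(gt[nrow(gt), ])))
  tr <- trace_branches(res$image, seeds, snap = FALSE)  # anchors are exact
  expect_s3_class(tr, "tracing")
  mask <- rasterize_tracing(tr)
  g <- build_skeleton_graph(thin_mask(mask))
  meas <- measure_branches(g, length_estimator = "corrected")
  expect_equal(sum(meas$length_um), res$truth$branches[[1]]$length_px,
               tolerance = 0.05)
})
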