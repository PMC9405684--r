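# Thinning, pixel tagging, branch graph, measurements, collaterals.

test_that("thin_mask is idempotent and recovers the centerline of a bar", {
  line <- matrix(FALSE, 9, 30); line[5, 3:27] <- TRUE
  sk <- thin_mask(binary_mask(line))
  expect_equal(sk$foreground, line)              # already 1-px: unchanged

  bar <- matrix(FALSE, 20, 110); bar[8:12, 6:105] <- TRUE
  skb <- thin_mask(binary_mask(bar))
  co <- mask_coords(skb)
  expect_equal(unique(co[, 2]), 9)               # medial row (0-based)
  expect_lte(abs(min(co[, 1]) - 5), 2)           # ends within 2 px
  expect_lte(abs(max(co[, 1]) - 104), 2)
  expect_identical(thin_mask(skb)$foreground, skb$foreground)
})

test_that("thin_mask preserves components and holes (annulus keeps its hole)", {
  a <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    d <- sqrt((r - 20.5)^2 + (c - 20.5)^2)
    a[r, c] <- d >= 6 && d <= 14
  }
  m <- binary_mask(a)
  sk <- thin_mask(m)
  expect_equal(count_components(sk), count_components(m))
  expect_equal(count_holes(sk), 1)
  # Euler characteristic (components - holes) preserved
  expect_equal(count_components(m) - count_holes(m),
               count_components(sk) - count_holes(sk))
})

test_that("classify_pixels tags by 8-neighbour count and partitions exactly", {
  line <- matrix(FALSE, 5, 15); line[3, 3:13] <- TRUE    # 11-px line
  cl <- classify_pixels(binary_mask(line))
  expect_equal(unname(attr(cl, "counts")), c(2, 9, 0))

  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE           # crossing 9-px lines
  cp <- classify_pixels(binary_mask(plus))
  counts <- attr(cp, "counts")
  # hand enumeration: the crossing pixel has 4 neighbours and each of its 4
  # arm neighbours picks up 2 diagonal contacts with the other arm, so the
  # junction CLUSTER spans 5 pixels; merged it is a single junction vertex
  expect_equal(unname(counts["junction"]), 5)
  expect_equal(unname(counts["endpoint"]), 4)
  expect_equal(sum(counts), sum(plus))
  expect_true(61 %in% which(unclass(cp) == 3L))          # the crossing itself
  sp <- summarize_skeleton(build_skeleton_graph(binary_mask(plus)))
  expect_equal(sp$junction_count, 1)
  expect_equal(sp$endpoint_count, 4)
  expect_equal(sp$branch_count, 4)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  cs <- classify_pixels(binary_mask(single))
  expect_equal(unname(attr(cs, "counts")), c(1, 0, 0))
})

test_that("build_skeleton_graph resolves Y-shapes, lines and cycles", {
  y <- matrix(FALSE, 16, 16)
  y[8:14, 8] <- TRUE                      # stem down
  for (i in 1:6) { y[8 - i, 8 - i] <- TRUE; y[8 - i, 8 + i] <- TRUE }
  g <- build_skeleton_graph(binary_mask(y))
  expect_equal(length(g$edges), 3)
  expect_equal(sum(g$vertices$kind == "junction"), 1)
  expect_equal(sum(g$vertices$kind == "endpoint"), 3)

  line <- matrix(FALSE, 4, 12); line[2, 2:11] <- TRUE
  gl <- build_skeleton_graph(binary_mask(line))
  expect_equal(length(gl$edges), 1)
  expect_equal(sum(gl$vertices$kind == "junction"), 0)

  # discrete diamond |x| + |y| = r: a clean closed 8-connected loop
  r <- 5
  ring <- matrix(FALSE, 15, 15)
  for (x in -r:r) {
    yv <- r - abs(x)
    ring[8 + yv, 8 + x] <- TRUE; ring[8 - yv, 8 + x] <- TRUE
  }
  gr <- build_skeleton_graph(binary_mask(ring))
  expect_equal(length(gr$edges), 1)
  expect_true(gr$edges[[1]]$is_cycle)
  expect_equal(nrow(gr$vertices), 0)
  mm <- measure_branches(gr)
  expect_true(is.na(mm$tortuosity))
})

test_that("measure_branches follows the step-sum and tortuosity conventions", {
  # horizontal 10-step branch (11 px)
  h <- matrix(FALSE, 5, 15); h[3, 3:13] <- TRUE
  mh <- measure_branches(build_skeleton_graph(binary_mask(h, 1)))
  expect_equal(mh$length_um, 10)
  expect_equal(mh$euclidean_um, 10)
  expect_equal(mh$tortuosity, 1)

  # L-path: 5 right + 5 up steps, measured as an explicit path (an
  # axis-aligned corner rendered into a mask acquires a diagonal contact
  # and would be tagged a junction under the 8-neighbour rule)
  lpath <- rbind(cbind(0:5, 7), cbind(5, 7 - (1:5)))
  ml <- measure_path(lpath)
  expect_equal(ml$length_um, 10)
  expect_equal(ml$euclidean_um, sqrt(50))
  expect_equal(ml$tortuosity, sqrt(2), tolerance = 1e-9)

  # diagonal 10-step branch
  d <- matrix(FALSE, 14, 14)
  for (i in 0:10) d[2 + i, 2 + i] <- TRUE
  md <- measure_branches(build_skeleton_graph(binary_mask(d, 1)))
  expect_equal(md$length_um, 10 * sqrt(2))
  expect_equal(md$euclidean_um, 10 * sqrt(2))
  expect_equal(md$tortuosity, 1)

  # calibration scales lengths
  mh2 <- measure_branches(build_skeleton_graph(binary_mask(h, 2.5)))
  expect_equal(mh2$length_um, 25)
})

test_that("summarize_skeleton counts match full-binary-tree combinatorics", {
  empty <- summarize_skeleton(
    build_skeleton_graph(binary_mask(matrix(FALSE, 5, 5))))
  expect_equal(empty$branch_count, 0)
  expect_equal(empty$junction_count, 0)
  expect_equal(empty$endpoint_count, 0)

  res <- generate_tree(tree_spec(depth = 2))
  g <- build_skeleton_graph(thin_mask(res$truth$stroke_mask),
                            merge_junctions_px = 6)
  s <- summarize_skeleton(g)
  expect_equal(s$branch_count, 7)        # 2^(d+1) - 1
  expect_equal(s$junction_count, 3)      # 2^d - 1
  expect_equal(s$endpoint_count, 5)      # 2^d + 1
  expect_equal(s$triple_point_count, 3)  # all bifurcations are triple points
  expect_equal(s$quadruple_point_count, 0)
  meas <- measure_branches(g)
  expect_equal(s$max_branch_length_um, max(meas$length_um))
  expect_lte(s$avg_branch_length_um, s$max_branch_length_um)
})

test_that("a grid crossing is a quadruple point", {
  plus <- matrix(FALSE, 21, 21)
  plus[11, 2:20] <- TRUE; plus[2:20, 11] <- TRUE
  s <- summarize_skeleton(build_skeleton_graph(binary_mask(plus)))
  expect_equal(s$junction_count, 1)
  expect_equal(s$quadruple_point_count, 1)
  expect_equal(s$branch_count, 4)
})

test_that("analyze_collaterals scopes branches to the anastomosis ROI", {
  res <- generate_tree(tree_spec(depth = 1, n_collaterals = 3))
  g <- build_skeleton_graph(thin_mask(res$truth$stroke_mask),
                            merge_junctions_px = 6)
  meas <- measure_branches(g)
  roi <- res$truth$collateral_roi
  rep_ <- analyze_collaterals(g, meas, roi)
  expect_equal(rep_$count, 3)
  gt_len <- vapply(res$truth$branches, function(b)
    if (b$label == "collateral") b$length_px else NA_real_, numeric(1))
  gt_len <- gt_len[!is.na(gt_len)]
  expect_equal(sort(rep_$lengths_um), sort(gt_len), tolerance = 0.05)
  # straight collaterals: mean tortuosity 1
  expect_equal(rep_$mean_tortuosity, 1, tolerance = 0.01)

  far <- polygon_roi(rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3)))
  expect_equal(analyze_collaterals(g, meas, far)$count, 0)
})

test_that("junction merging contracts sub-resolution internal branches only", {
  # two plus-signs joined by a long bar: merging must not fuse them
  m <- matrix(FALSE, 21, 61)
  m[11, 2:60] <- TRUE
  m[2:20, 11] <- TRUE
  m[2:20, 51] <- TRUE
  g0 <- build_skeleton_graph(binary_mask(m))
  g1 <- build_skeleton_graph(binary_mask(m), merge_junctions_px = 6)
  expect_equal(sum(g0$vertices$kind == "junction"), 2)
  expect_equal(sum(g1$vertices$kind == "junction"), 2)
  expect_equal(length(g1$edges), length(g0$edges))
})

test_that("spur suppression drops short endpoint branches when enabled", {
  m <- matrix(FALSE, 15, 40)
  m[8, 2:38] <- TRUE
  m[5:7, 20] <- TRUE                      # 3-px spur off the line
  g0 <- build_skeleton_graph(binary_mask(m))
  expect_equal(length(g0$edges), 3)
  g1 <- build_skeleton_graph(binary_mask(m), min_branch_px = 6)
  expect_equal(length(g1$edges), 2)
  expect_equal(sum(g1$vertices$kind == "endpoint"), 2)
})
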