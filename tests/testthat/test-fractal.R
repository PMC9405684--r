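# Box counting, LFD maps, histograms and complexity features.

test_that("box_count_dimension matches hand-countable occupancy", {
  line <- generate_fractal_fixture("line", size = 1024)
  d <- box_count_dimension(line, 2^(1:8))
  # regression oracle on N(s) = ceiling(1024 / s)
  s <- 2^(1:8)
  expect_equal(attr(d, "counts"), ceiling(1024 / s))
  oracle <- unname(coef(lm(log(ceiling(1024 / s)) ~ log(1 / s)))[2])
  expect_equal(as.numeric(d), oracle)
  expect_gt(as.numeric(d), 0.95); expect_lt(as.numeric(d), 1.05)

  sq <- generate_fractal_fixture("filled_square", size = 512)
  d2 <- box_count_dimension(sq, 2^(1:8))
  expect_equal(attr(d2, "counts"), (512 / 2^(1:8))^2)
  expect_equal(as.numeric(d2), 2, tolerance = 1e-9)

  expect_error(box_count_dimension(binary_mask(matrix(FALSE, 8, 8))), "empty")
  expect_error(box_count_dimension(sq, 4), "two box sizes")
})

test_that("box counting is grid-shift and rotation invariant where promised", {
  si <- generate_fractal_fixture("sierpinski_triangle", depth = 6)
  d <- as.numeric(box_count_dimension(si, 2^(1:5)))
  expect_equal(d, log(3) / log(2), tolerance = 0.05 * log(3) / log(2))

  # translation by a multiple of the largest box size
  fg <- si$foreground
  big <- matrix(FALSE, nrow(fg) + 64, ncol(fg) + 64)
  big[65:(64 + nrow(fg)), 65:(64 + ncol(fg))] <- fg
  expect_equal(as.numeric(box_count_dimension(binary_mask(big), 2^(1:5))), d)

  # 90-degree rotation
  rot <- t(fg)[, rev(seq_len(nrow(fg)))]
  expect_equal(as.numeric(box_count_dimension(binary_mask(rot), 2^(1:5))), d)
})

test_that("local_fractal_map evaluates qualifying windows only", {
  line <- generate_fractal_fixture("line", size = 512)
  lfd <- local_fractal_map(line, window_size = 128, stride = 64,
                           min_foreground = 50)
  expect_gt(nrow(lfd), 0)
  expect_true(all(lfd$lfd > 0.9 & lfd$lfd < 1.1))
  # per-window regression oracle for the first entry
  w <- 128
  win <- line$foreground[(lfd$y[1] + 1):(lfd$y[1] + w),
                         (lfd$x[1] + 1):(lfd$x[1] + w)]
  co <- which(win, arr.ind = TRUE) - 1L
  s <- 2^(1:6)
  counts <- vapply(s, function(ss)
    length(unique((co[, 2] %/% ss) * 1e5 + co[, 1] %/% ss)), numeric(1))
  oracle <- unname(coef(lm(log(counts) ~ log(1 / s)))[2])
  expect_equal(lfd$lfd[1], oracle)

  # entry count equals an independent window scan
  n_windows <- 0
  for (y0 in seq(0, 512 - w, 64)) for (x0 in seq(0, 512 - w, 64))
    if (sum(line$foreground[(y0 + 1):(y0 + w), (x0 + 1):(x0 + w)]) >= 50)
      n_windows <- n_windows + 1
  expect_equal(nrow(lfd), n_windows)

  blank <- binary_mask(matrix(FALSE, 256, 256))
  expect_warning(empty <- local_fractal_map(blank, 128, 64, 50), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("LFD of a window inside a filled region is about 2, and mean LFD
           rises with tree depth", {
  sq <- generate_fractal_fixture("filled_square", size = 128)
  lfd <- local_fractal_map(sq, window_size = 128, stride = 128,
                           min_foreground = 50)
  expect_equal(lfd$lfd[1], 2, tolerance = 0.01)

  mean_lfd <- vapply(c(1, 3), function(d) {
    res <- generate_tree(tree_spec(depth = d))
    m <- local_fractal_map(res$truth$stroke_mask, window_size = 64,
                           stride = 64, min_foreground = 30)
    mean(m$lfd)
  }, numeric(1))
  expect_gt(mean_lfd[2], mean_lfd[1])
})

test_that("build_lfd_histogram conserves counts and bins correctly", {
  h <- build_lfd_histogram(rep(1.25, 40), bin_width = 0.01, range = c(1, 2))
  expect_equal(length(h$counts), 100)
  expect_equal(sum(h$counts), 40)
  expect_equal(sum(h$counts > 0), 1)

  set.seed(4)
  vals <- runif(500, 1.05, 1.6)
  h2 <- build_lfd_histogram(vals, 0.01, c(1, 2))
  expect_equal(sum(h2$counts), 500)
  hn <- build_lfd_histogram(vals, 0.01, c(1, 2), normalize = TRUE)
  expect_equal(sum(hn$counts), 1)

  expect_warning(build_lfd_histogram(c(0.5, 1.5), 0.1, c(1, 2)), "outside")
})

test_that("average_lfd_histograms takes the per-bin mean of frequencies", {
  h1 <- build_lfd_histogram(rep(1.05, 10), 0.1, c(1, 2))
  h2 <- build_lfd_histogram(rep(1.95, 30), 0.1, c(1, 2))
  avg <- average_lfd_histograms(list(h1, h2))
  expect_equal(avg$counts[1], 0.5)
  expect_equal(avg$counts[10], 0.5)
  expect_equal(sum(avg$counts), 1)
})

test_that("extract_features computes the four histogram features", {
  # symmetric distribution -> zero skewness
  vals <- c(1.2, 1.3, 1.3, 1.4, 1.4, 1.4, 1.5, 1.5, 1.6)
  f <- extract_features(build_lfd_histogram(vals, 0.05, c(1, 2)))
  expect_equal(f$skewness, 0, tolerance = 1e-9)

  # moment formulas on a large normal sample (pseudo-LFD values)
  set.seed(8)
  z <- rnorm(1e5)
  fz <- extract_features(build_lfd_histogram(z / 20 + 1.5, 0.005, c(1, 2)))
  expect_lt(abs(fz$skewness), 0.05)
  expect_lt(abs(fz$kurtosis), 0.05)

  # all mass in the top bin
  top <- build_lfd_histogram(rep(1.999, 25), 0.01, c(1, 2))
  ft <- extract_features(top)
  expect_equal(ft$max_lfd, 2)
  expect_equal(ft$peak_frequency, 25)
  expect_false(ft$moments_defined)
})
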