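# Group-comparison statistics cross-validated against base R references.

test_that("one-way ANOVA matches hand arithmetic and identical groups give F = 0", {
  r <- compare_one_way(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$table$F[1], 0)
  expect_equal(r$table$p[1], 1)

  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, MSB = 3, MSW = 1 -> F = 3
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  r2 <- compare_one_way(y, g)
  expect_equal(r2$table$sum_sq, c(6, 6))
  expect_equal(r2$table$F[1], 3)

  expect_error(compare_one_way(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("one-way ANOVA and Tukey match stats::aov / TukeyHSD on random data", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n_i <- sample(4:9, k, TRUE)
    g <- factor(rep(letters[1:k], n_i))
    y <- rnorm(sum(n_i), mean = as.integer(g) * runif(1))
    r <- compare_one_way(y, g)
    fit <- aov(y ~ g)
    ref <- summary(fit)[[1]]
    expect_equal(r$table$F[1], ref$`F value`[1], tolerance = 1e-6)
    expect_equal(r$table$p[1], ref$`Pr(>F)`[1], tolerance = 1e-6)
    tk <- TukeyHSD(fit)$g
    ours <- r$posthoc$p_adj[order(paste(r$posthoc$group2, r$posthoc$group1))]
    refs <- tk[order(rownames(tk)), "p adj"]
    expect_equal(unname(ours), unname(refs), tolerance = 1e-6)
  }
})

test_that("two groups satisfy F = t^2 against the pooled t statistic", {
  set.seed(32)
  for (rep in 1:10) {
    y <- rnorm(24); g <- rep(c("a", "b"), each = 12)
    r <- compare_one_way(y, g)
    t <- t.test(y ~ g, var.equal = TRUE)$statistic
    expect_equal(r$table$F[1], unname(t)^2, tolerance = 1e-9)
  }
})

test_that("two-way ANOVA (balanced) matches aov and handles degenerate cells", {
  set.seed(33)
  y <- rnorm(48, mean = rep(c(0, 1, 0.5, 2), each = 12))
  A <- rep(c("a1", "a2"), each = 24)
  B <- rep(rep(c("f", "m"), each = 12), 2)
  r <- compare_two_way(y, A, B)
  ref <- summary(aov(y ~ factor(A) * factor(B)))[[1]]
  expect_equal(r$table$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(r$table$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
  # Type III on balanced data agrees with Type II
  r3 <- compare_two_way(y, A, B, ss_type = "III")
  expect_equal(r3$table$sum_sq, r$table$sum_sq, tolerance = 1e-8)

  # identical cells: all F = 0
  y0 <- rep(c(1, 2, 3, 4), 4)
  A0 <- rep(c("x", "y"), each = 8)
  B0 <- rep(rep(c("f", "m"), each = 4), 2)
  r0 <- compare_two_way(y0, A0, B0)
  expect_equal(r0$table$F[1:3], rep(0, 3))

  expect_error(
    compare_two_way(1:6, c("a", "a", "a", "b", "b", "b"),
                    c("f", "f", "m", "f", "f", "f")),
    "empty cell")
})

test_that("Sidak within-age sex comparisons use the model MSE and family size", {
  set.seed(34)
  ages <- rep(c("a1", "a2", "a3", "a4"), each = 12)
  sex <- rep(rep(c("f", "m"), each = 6), 4)
  y <- rnorm(48)
  y[ages == "a2" & sex == "m"] <- y[ages == "a2" & sex == "m"] + 3
  r <- compare_two_way(y, ages, sex)
  expect_equal(nrow(r$posthoc), 4)
  expect_true(all(r$posthoc$p_sidak >= r$posthoc$p_raw - 1e-12))
  expect_equal(r$posthoc$p_sidak, 1 - (1 - r$posthoc$p_raw)^4)
  expect_lt(r$posthoc$p_sidak[r$posthoc$level_a == "a2"], 0.05)
})

test_that("covariance_ellipse recovers orientation, axes and sign", {
  set.seed(35)
  # isotropic data: near-circular
  x <- rnorm(4000); y <- rnorm(4000)
  e <- covariance_ellipse(x, y)
  expect_equal(e$semi_axes[1] / e$semi_axes[2], 1, tolerance = 0.1)

  # rank-1: points on y = x
  z <- seq(-3, 3, length.out = 50)
  e1 <- covariance_ellipse(z, z)
  expect_equal(e1$semi_axes[2], 0, tolerance = 1e-9)
  expect_equal(e1$orientation_deg, 45, tolerance = 1e-9)
  expect_equal(e1$covariance_sign, 1)

  # known 2x2 covariance: orientation within 2 degrees of the analytic axis
  S <- matrix(c(4, 1.5, 1.5, 1), 2)
  L <- chol(S)
  xy <- matrix(rnorm(2e4), ncol = 2) %*% L
  e2 <- covariance_ellipse(xy[, 1], xy[, 2])
  ev <- eigen(S)$vectors[, 1]
  truth <- atan2(ev[2], ev[1]) * 180 / pi
  if (truth >= 90) truth <- truth - 180
  if (truth < -90) truth <- truth + 180
  expect_lt(abs(e2$orientation_deg - truth), 2)

  # sign matches Pearson correlation sign
  expect_equal(e2$covariance_sign, sign(cor(xy[, 1], xy[, 2])))
  expect_error(covariance_ellipse(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("normality checks agree with shapiro.test and flag skewed data", {
  set.seed(36)
  z <- rnorm(60)
  nc <- normality_checks(z)
  sw <- shapiro.test(z)
  expect_equal(nc$p[nc$test == "shapiro_wilk"], sw$p.value)
  expect_true(all(nc$p > 0.01))
  skewed <- rexp(200)
  nc2 <- normality_checks(skewed)
  expect_true(all(nc2$p < 0.01))
})
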