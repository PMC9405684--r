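# Group-comparison statistics for the extracted vascular metrics: one-way
# ANOVA with Tukey HSD, two-way (age x sex) ANOVA with Sidak-adjusted
# within-age sex comparisons, and covariance ellipses for metric scatter
# plots. Sums of squares are computed in-package (the test suite
# cross-validates them against stats::aov / TukeyHSD as an independent
# reference); base distribution functions supply the p-values.

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical decomposition: `F = MSB / MSW` with `k - 1` and `N - k` degrees
#' of freedom; pairwise Tukey honest-significant-difference p-values via the
#' studentized range distribution.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 values each.
#' @return An `anova_result`: list with `table` (effect, df, sum_sq, mean_sq,
#'   F, p) and `posthoc` (pairwise comparisons with Tukey-adjusted p).
#' @export
compare_one_way <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("one-way ANOVA needs >= 2 groups")
  n_i <- tapply(values, groups, length)
  if (any(n_i < 2)) stop("every group needs >= 2 values")
  N <- length(values)
  gm <- mean(values)
  m_i <- tapply(values, groups, mean)
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum((values - m_i[groups])^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- if (msw > 0) msb / msw else ifelse(msb > 0, Inf, 0)
  p <- if (msw > 0) pf(f, df1, df2, lower.tail = FALSE) else
    ifelse(msb > 0, 0, 1)
  tab <- data.frame(effect = c("group", "residual"),
                    df = c(df1, df2), sum_sq = c(ssb, ssw),
                    mean_sq = c(msb, msw), F = c(f, NA), p = c(p, NA))
  pairs <- utils::combn(levels(groups), 2)
  posthoc <- do.call(rbind, apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- m_i[j] - m_i[i]
    se <- sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- if (se > 0) abs(diff) / se else ifelse(diff != 0, Inf, 0)
    p_adj <- if (se > 0) ptukey(q, k, df2, lower.tail = FALSE) else
      ifelse(diff != 0, 0, 1)
    data.frame(group1 = i, group2 = j, diff = unname(diff),
               se_tukey = unname(se), p_adj = unname(p_adj))
  }, simplify = FALSE))
  structure(list(design = "one-way", table = tab, posthoc = posthoc,
                 mse = msw, df_residual = df2),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s ANOVA\n", x$design))
  print(x$table, row.names = FALSE)
  cat("post hoc:\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way (factor A x factor B) ANOVA with Sidak post hoc
#'
#' Main effects and interaction with Type II sums of squares by default
#' (`SS(A | B)`, `SS(B | A)`, `SS(AB | A, B)` via nested model comparisons;
#' Type II is the standard choice for mildly unbalanced designs when the
#' interaction is secondary). Type III (sum-to-zero contrasts) is available
#' by flag. The post hoc family is the within-A B-level comparison at each
#' level of A (e.g. male vs female at each age bin), Sidak-adjusted over the
#' number of A levels, using the full-model MSE.
#'
#' @param values numeric response vector.
#' @param factor_a primary factor (e.g. age bin).
#' @param factor_b secondary two-level factor (e.g. sex) for the post hoc.
#' @param ss_type `"II"` (default) or `"III"`.
#' @return An `anova_result` with `table` (A, B, interaction, residual) and
#'   `posthoc` (B-comparison within each A level, Sidak-adjusted).
#' @export
compare_two_way <- function(values, factor_a, factor_b, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  a <- factor(factor_a); b <- factor(factor_b)
  ok <- !is.na(values) & !is.na(a) & !is.na(b)
  values <- values[ok]; a <- droplevels(a[ok]); b <- droplevels(b[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("both factors need >= 2 levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s x %s", rownames(cells)[empty[1]],
                 colnames(cells)[empty[2]]))
  }
  df <- data.frame(y = values, A = a, B = b)
  opts <- list(contrasts = c(unordered = "contr.sum", ordered = "contr.poly"))
  old <- options(opts); on.exit(options(old))
  X_full <- stats::model.matrix(~ A * B, df)
  X_ab <- stats::model.matrix(~ A + B, df)
  X_a <- stats::model.matrix(~ A, df)
  X_b <- stats::model.matrix(~ B, df)
  rss_full <- rss_of(values, X_full)
  df_res <- length(values) - ncol(X_full)
  mse <- rss_full / df_res
  if (ss_type == "II") {
    ss_a <- rss_of(values, X_b) - rss_of(values, X_ab)
    ss_b <- rss_of(values, X_a) - rss_of(values, X_ab)
    ss_ab <- rss_of(values, X_ab) - rss_full
  } else {
    cols <- attr(X_full, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
    drop_rss <- function(term) rss_of(values, X_full[, cols != term, drop = FALSE])
    ss_a <- drop_rss(1) - rss_full
    ss_b <- drop_rss(2) - rss_full
    ss_ab <- drop_rss(3) - rss_full
  }
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1; df_ab <- df_a * df_b
  mk <- function(ss, d) {
    ms <- ss / d
    f <- if (mse > 0) ms / mse else ifelse(ms > 0, Inf, 0)
    p <- if (mse > 0) pf(f, d, df_res, lower.tail = FALSE) else
      ifelse(ms > 0, 0, 1)
    c(d, ss, ms, f, p)
  }
  tab <- rbind(mk(ss_a, df_a), mk(ss_b, df_b), mk(ss_ab, df_ab),
               c(df_res, rss_full, mse, NA, NA))
  tab <- data.frame(effect = c("A", "B", "A:B", "residual"),
                    df = tab[, 1], sum_sq = tab[, 2], mean_sq = tab[, 3],
                    F = tab[, 4], p = tab[, 5])
  # Sidak family: B comparison within each A level (first two B levels)
  lev_b <- levels(b)
  m <- nlevels(a)
  posthoc <- do.call(rbind, lapply(levels(a), function(al) {
    y1 <- values[a == al & b == lev_b[1]]
    y2 <- values[a == al & b == lev_b[2]]
    diff <- mean(y2) - mean(y1)
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    t <- if (se > 0) diff / se else ifelse(diff != 0, Inf, 0)
    p_raw <- if (se > 0) 2 * pt(-abs(t), df_res) else ifelse(diff != 0, 0, 1)
    data.frame(level_a = al, comparison = paste(lev_b[2], "vs", lev_b[1]),
               diff = diff, se = se, t = t, p_raw = p_raw,
               p_sidak = 1 - (1 - p_raw)^m)
  }))
  structure(list(design = sprintf("two-way (type %s)", ss_type), table = tab,
                 posthoc = posthoc, mse = mse, df_residual = df_res),
            class = "anova_result")
}

#' Covariance ellipse of paired metrics
#'
#' Ellipse of the sample covariance: center at the means, semi-axes
#' `k * sqrt(eigenvalue)`, orientation of the principal eigenvector in
#' degrees within `[-90, 90)`; the covariance sign is reported so positive
#' association is explicit.
#'
#' @param x,y paired metric values (>= 3 complete pairs, not all identical).
#' @param k coverage multiplier on the axis lengths (default 2).
#' @return A `covariance_ellipse`: list with `center`, `semi_axes` (major,
#'   minor), `orientation_deg`, `k`, `covariance_sign`, `correlation`.
#' @export
covariance_ellipse <- function(x, y, k = 2) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired points")
  S <- cov(cbind(x, y))
  if (all(abs(S) < 1e-300)) stop("degenerate input: all points identical")
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  structure(list(center = c(mean(x), mean(y)),
                 semi_axes = k * sqrt(pmax(e$values, 0)),
                 orientation_deg = ang, k = k,
                 covariance_sign = sign(S[1, 2]),
                 correlation = suppressWarnings(stats::cor(x, y))),
            class = "covariance_ellipse")
}

#' @export
print.covariance_ellipse <- function(x, ...) {
  cat(sprintf(
    "<covariance_ellipse> center (%.3g, %.3g), semi-axes %.3g / %.3g, %.1f deg, cov sign %+d\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$orientation_deg, x$covariance_sign))
  invisible(x)
}

#' Normality checks (advisory only)
#'
#' Shapiro-Wilk and D'Agostino-Pearson omnibus tests, reported as advisory
#' outputs alongside the ANOVAs; they never gate the analysis.
#'
#' @param values numeric vector (n >= 8 for the omnibus test).
#' @return data.frame with one row per test: `test, statistic, p`.
#' @export
normality_checks <- function(values) {
  values <- values[!is.na(values)]
  out <- list()
  if (length(values) >= 3 && length(values) <= 5000) {
    sw <- shapiro.test(values)
    out$sw <- data.frame(test = "shapiro_wilk",
                         statistic = unname(sw$statistic), p = sw$p.value)
  }
  n <- length(values)
  if (n >= 8) {
    # D'Agostino-Pearson K^2: normalizing transforms of skewness and kurtosis
    g1 <- sample_skewness(values) * (n - 2) / sqrt(n * (n - 1))  # back to g1
    Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
      ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- -1 + sqrt(2 * (b2 - 1))
    delta <- 1 / sqrt(log(sqrt(W2)))
    alpha <- sqrt(2 / (W2 - 1))
    Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
    m <- mean(values)
    g2 <- sum((values - m)^4) / n / (sum((values - m)^2) / n)^2 - 3
    Eb2 <- 3 * (n - 1) / (n + 1)
    Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xq <- (g2 + 3 - Eb2) / sqrt(Vb2)
    beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
      sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
    Zg2 <- ((1 - 2 / (9 * A)) -
              ((1 - 2 / A) / (1 + xq * sqrt(2 / (A - 4))))^(1 / 3)) /
      sqrt(2 / (9 * A))
    K2 <- Zg1^2 + Zg2^2
    out$dp <- data.frame(test = "dagostino_pearson", statistic = K2,
                         p = pchisq(K2, 2, lower.tail = FALSE))
  }
  if (length(out) == 0)
    return(data.frame(test = character(0), statistic = numeric(0),
                      p = numeric(0)))
  do.call(rbind, out)
}
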