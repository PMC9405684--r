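# Box-counting fractal analysis: global dimension, sliding-window local
# fractal dimension (LFD) maps, LFD histograms and the four summary features
# used for group comparison (skewness, kurtosis, peak frequency, max LFD).

dyadic_box_sizes <- function(max_size) {
  s <- 2^(1:30)
  s[s <= max_size]
}

#' Box-counting fractal dimension
#'
#' Slope of the least-squares fit of `log(occupied box count)` against
#' `log(1 / box size)`, with the counting grid anchored at the origin
#' (a single fixed grid origin; optional offset averaging behind a flag).
#'
#' @param mask a [binary_mask] (or logical matrix), non-empty.
#' @param box_sizes at least two box sizes in pixels; default: dyadic sizes
#'   from 2 to half the smaller mask dimension.
#' @param offsets number of grid origins averaged per size (1 = fixed grid).
#' @return The fitted dimension (scalar). Attributes `box_sizes` and
#'   `counts` expose the regression inputs.
#' @export
box_count_dimension <- function(mask, box_sizes = NULL, offsets = 1) {
  mask <- as_binary_mask(mask)
  co <- mask_coords(mask)
  if (nrow(co) == 0) stop("empty mask: fractal dimension undefined")
  if (is.null(box_sizes))
    box_sizes <- dyadic_box_sizes(min(dim(mask$foreground)) / 2)
  if (length(box_sizes) < 2) stop("need at least two box sizes")
  counts <- vapply(box_sizes, function(s) {
    n <- 0
    for (k in seq_len(offsets)) {
      ox <- if (offsets > 1) floor((k - 1) * s / offsets) else 0
      bx <- (co[, 1] + ox) %/% s
      by <- (co[, 2] + ox) %/% s
      n <- n + length(unique(bx * (2^26) + by))
    }
    n / offsets
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / box_sizes))
  structure(unname(coef(fit)[2]), box_sizes = box_sizes, counts = counts)
}

#' Local fractal dimension map
#'
#' [box_count_dimension()] evaluated in sliding windows across the mask.
#' Windows with fewer than `min_foreground` pixels are skipped. Defaults
#' (window 128, stride 64, min 50 foreground pixels, dyadic box sizes from 2
#' to half the window) target vessel images at the scale where the LFD of
#' vascular patterns falls in roughly 1.0-1.5.
#'
#' @param mask a [binary_mask].
#' @param window_size window side in pixels (<= mask dimensions).
#' @param stride window step in pixels.
#' @param min_foreground minimum foreground pixels for a window to qualify.
#' @param box_sizes box sizes used inside each window (default dyadic
#'   2..window_size/2).
#' @return An `lfd_map`: data.frame `(x, y, lfd)` of window origins and
#'   values, with the parameters as attributes. Empty (no qualifying
#'   window) maps are returned with a warning.
#' @export
local_fractal_map <- function(mask, window_size = 128, stride = 64,
                              min_foreground = 50, box_sizes = NULL) {
  mask <- as_binary_mask(mask)
  fg <- mask$foreground
  if (window_size > min(dim(fg))) stop("window_size exceeds mask dimensions")
  if (is.null(box_sizes)) box_sizes <- dyadic_box_sizes(window_size / 2)
  xs <- seq(0, ncol(fg) - window_size, by = stride)
  ys <- seq(0, nrow(fg) - window_size, by = stride)
  rows <- list()
  for (y0 in ys) {
    for (x0 in xs) {
      win <- fg[(y0 + 1):(y0 + window_size), (x0 + 1):(x0 + window_size)]
      if (sum(win) < min_foreground) next
      d <- box_count_dimension(binary_mask(win), box_sizes)
      rows[[length(rows) + 1]] <- data.frame(x = x0, y = y0, lfd = as.numeric(d))
    }
  }
  if (length(rows) == 0) {
    warning("no window passed the min_foreground filter: empty LFD map")
    out <- data.frame(x = numeric(0), y = numeric(0), lfd = numeric(0))
  } else out <- do.call(rbind, rows)
  structure(out, window_size = window_size, stride = stride,
            min_foreground = min_foreground, box_sizes = box_sizes,
            class = c("lfd_map", "data.frame"))
}

#' LFD histogram
#'
#' Counts of local fractal dimension values over fixed bins. Values outside
#' `range` are clamped into the edge bins with a warning. Normalized
#' histograms hold frequencies summing to 1; group averaging of histograms
#' (per-bin mean across samples) follows the normalized form.
#'
#' @param map an `lfd_map` (or numeric vector of LFD values).
#' @param bin_width bin width in LFD units (> 0).
#' @param range `c(lo, hi)` histogram support.
#' @param normalize return frequencies instead of counts.
#' @return An `lfd_histogram`: list with `bin_edges`, `counts`, `normalized`;
#'   the underlying values are kept in `attr(, "values")` for the moment
#'   features.
#' @export
build_lfd_histogram <- function(map, bin_width = 0.01, range = c(1, 2),
                                normalize = FALSE) {
  stopifnot(bin_width > 0, length(range) == 2, range[2] > range[1])
  values <- if (is.data.frame(map)) map$lfd else as.numeric(map)
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  if (any(values < range[1] | values > range[2])) {
    warning("LFD values outside histogram range: counted in the edge bins")
    values_b <- pmin(pmax(values, range[1]), range[2])
  } else values_b <- values
  idx <- findInterval(values_b, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(bin_edges = edges, counts = counts, normalized = normalize),
            values = values, class = "lfd_histogram")
}

#' @export
print.lfd_histogram <- function(x, ...) {
  cat(sprintf("<lfd_histogram> %d bins over [%g, %g], %s total %g\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              if (x$normalized) "frequency" else "count", sum(x$counts)))
  invisible(x)
}

#' Average histograms across samples
#'
#' Per-bin mean of normalized frequencies across a group of samples; all
#' histograms must share their bins.
#'
#' @param hists list of `lfd_histogram` objects.
#' @return An `lfd_histogram` of per-bin mean frequencies.
#' @export
average_lfd_histograms <- function(hists) {
  stopifnot(length(hists) >= 1)
  edges <- hists[[1]]$bin_edges
  for (h in hists) if (!isTRUE(all.equal(h$bin_edges, edges)))
    stop("histograms must share identical bins")
  freq <- vapply(hists, function(h) {
    s <- sum(h$counts)
    if (h$normalized || s == 0) h$counts else h$counts / s
  }, numeric(length(edges) - 1))
  structure(list(bin_edges = edges, counts = rowMeans(freq), normalized = TRUE),
            class = "lfd_histogram")
}

# adjusted Fisher-Pearson standardized third moment and excess kurtosis
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x); s <- sqrt(sum((x - m)^2) / n)
  g1 <- sum((x - m)^3) / n / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
sample_excess_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x); m2 <- sum((x - m)^2) / n
  g2 <- sum((x - m)^4) / n / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Complexity features of an LFD histogram
#'
#' The four distribution features compared across groups: skewness (adjusted
#' Fisher-Pearson third standardized moment of the underlying LFD values),
#' excess (Fisher) kurtosis, peak frequency (the modal bin height), and the
#' maximum LFD (upper edge of the highest nonzero bin). The LFD value at
#' the modal bin is exposed as the secondary `lfd_at_peak`. Moments come
#' from the raw values when the histogram kept them, otherwise from bin
#' midpoints weighted by counts; single-bin histograms get `NA` moments
#' (flagged undefined).
#'
#' @param hist an `lfd_histogram`.
#' @return A one-row data.frame: `skewness, kurtosis, peak_frequency,
#'   max_lfd, lfd_at_peak, moments_defined`.
#' @export
extract_features <- function(hist) {
  stopifnot(inherits(hist, "lfd_histogram"))
  counts <- hist$counts
  edges <- hist$bin_edges
  nz <- which(counts > 0)
  if (length(nz) == 0) stop("empty histogram")
  values <- attr(hist, "values")
  if (is.null(values)) {
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    reps <- if (hist$normalized) round(counts * 1e6) else counts
    values <- rep(mids, reps)
  }
  defined <- length(nz) >= 2 && length(values) >= 4
  peak_bin <- which.max(counts)
  data.frame(
    skewness = if (defined) sample_skewness(values) else NA_real_,
    kurtosis = if (defined) sample_excess_kurtosis(values) else NA_real_,
    peak_frequency = max(counts),
    max_lfd = edges[max(nz) + 1],
    lfd_at_peak = (edges[peak_bin] + edges[peak_bin + 1]) / 2,
    moments_defined = defined
  )
}
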