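# Image preparation: the steps that turn an acquired z-stack into the 8-bit,
# contrast-optimized, ROI-scoped image the tracing/segmentation stages consume.

#' Maximum-intensity projection of a z-stack
#'
#' @param stack a [zstack].
#' @return A [raster_image]: per-pixel maximum across slices, calibration
#'   inherited from the first slice.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "zstack")) stop("max_project expects a zstack")
  if (length(stack$slices) == 0) stop("empty stack")
  out <- stack$slices[[1]]$values
  for (s in stack$slices[-1]) out <- pmax(out, s$values)
  raster_image(out, stack$slices[[1]]$pixel_size_um, stack$slices[[1]]$bit_depth)
}

#' Linear auto-contrast with quantile saturation
#'
#' Emulates Fiji's brightness/contrast "Auto": the `saturation_fraction`
#' quantile maps to 0 and the `1 - saturation_fraction` quantile to the bit
#' depth maximum, with clipping. The default saturation is Fiji's documented
#' 0.35\%. Constant (degenerate) images pass through unchanged.
#'
#' @param img a [raster_image].
#' @param saturation_fraction proportion in `[0, 0.5)` saturated at each tail.
#' @return A rescaled [raster_image].
#' @export
auto_contrast <- function(img, saturation_fraction = 0.0035) {
  stopifnot(is_raster_image(img))
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    stop("saturation_fraction must be in [0, 0.5)")
  v <- img$values
  lo <- as.numeric(quantile(v, saturation_fraction, names = FALSE))
  hi <- as.numeric(quantile(v, 1 - saturation_fraction, names = FALSE))
  if (hi <= lo) return(img)  # constant image
  maxv <- 2^img$bit_depth - 1
  out <- (v - lo) / (hi - lo) * maxv
  out <- pmin(pmax(out, 0), maxv)
  raster_image(out, img$pixel_size_um, img$bit_depth)
}

# replicate-pad a matrix by k pixels on every side
pad_replicate <- function(m, k) {
  m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
  m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
}

# 3x3 (or larger, odd) convolution with replicate border padding
convolve2d <- function(m, kernel) {
  k <- (nrow(kernel) - 1) / 2
  p <- pad_replicate(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc)]
    }
  }
  out
}

#' Unsharp-style 3x3 sharpening
#'
#' Fiji's built-in "Sharpen": convolution with the kernel (center 12,
#' neighbours -1) / 4, replicate border padding, clipped to the bit depth.
#' The kernel sums to 1 so constant regions are unchanged.
#'
#' @param img a [raster_image].
#' @return A sharpened [raster_image].
#' @export
sharpen <- function(img) {
  stopifnot(is_raster_image(img))
  kernel <- matrix(-1, 3, 3) / 4
  kernel[2, 2] <- 12 / 4
  maxv <- 2^img$bit_depth - 1
  out <- pmin(pmax(convolve2d(img$values, kernel), 0), maxv)
  raster_image(out, img$pixel_size_um, img$bit_depth)
}

# grayscale erosion/dilation with an arbitrary offset set; pixels whose
# offset falls outside the image are ignored (+-Inf identity)
morph_extremum <- function(m, offsets, op = c("min", "max")) {
  op <- match.arg(op)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(if (op == "min") Inf else -Inf, nr, nc)
  f <- if (op == "min") pmin else pmax
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1]; dx <- offsets[k, 2]
    r_dst <- max(1, 1 - dy):min(nr, nr - dy)
    c_dst <- max(1, 1 - dx):min(nc, nc - dx)
    out[r_dst, c_dst] <- f(out[r_dst, c_dst], m[r_dst + dy, c_dst + dx])
  }
  out
}

disk_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  as.matrix(d[d$dy^2 + d$dx^2 <= radius^2 + 1e-9, ])
}

#' Morphological background (haze) subtraction
#'
#' Out-of-focus glow is estimated as the grayscale opening of the image with a
#' disk structuring element of the given radius, and subtracted (clipped at 0).
#' This is the standard rolling-ball-equivalent stand-in for proprietary
#' haze-reduction filters: structures narrower than the disk survive, smooth
#' background does not.
#'
#' @param img a [raster_image].
#' @param radius disk radius in pixels (>= 1); must fit inside the image.
#' @return A background-subtracted [raster_image].
#' @export
reduce_haze <- function(img, radius) {
  stopifnot(is_raster_image(img))
  if (radius < 1) stop("radius must be >= 1")
  if (2 * radius + 1 > min(dim(img$values)))
    stop("structuring element larger than the image")
  off <- disk_offsets(radius)
  background <- morph_extremum(morph_extremum(img$values, off, "min"), off, "max")
  raster_image(pmax(img$values - background, 0), img$pixel_size_um, img$bit_depth)
}

#' Extract a polygonal region of interest
#'
#' Crops the image to the polygon's (clipped) bounding box and zeroes every
#' pixel whose center lies outside the polygon. The point-in-polygon test is
#' boundary-inclusive (see [points_in_polygon()]).
#'
#' @param img a [raster_image].
#' @param roi a [polygon_roi] in the image's 0-based coordinates.
#' @return The cropped, masked [raster_image].
#' @export
extract_polygon_roi <- function(img, roi) {
  stopifnot(is_raster_image(img), inherits(roi, "polygon_roi"))
  v <- roi$vertices
  x0 <- max(0, floor(min(v[, 1]))); x1 <- min(img_width(img) - 1, ceiling(max(v[, 1])))
  y0 <- max(0, floor(min(v[, 2]))); y1 <- min(img_height(img) - 1, ceiling(max(v[, 2])))
  if (x0 > x1 || y0 > y1) stop("polygon lies fully outside the image")
  sub <- img$values[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  xs <- rep(x0:x1, each = nrow(sub))
  ys <- rep(y0:y1, times = ncol(sub))
  keep <- matrix(points_in_polygon(xs, ys, roi), nrow = nrow(sub))
  if (!any(keep)) stop("polygon contains no pixel centers inside the image")
  sub[!keep] <- 0
  raster_image(sub, img$pixel_size_um, img$bit_depth)
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustive search over the 256 intensity levels for the threshold t
#' (foreground = values >= t) maximizing the between-class variance.
#' Ties take the lowest maximizing t.
#'
#' @param values numeric matrix or vector of 8-bit intensities.
#' @return The threshold t in `1:255`.
#' @export
otsu_threshold <- function(values) {
  h <- tabulate(as.integer(round(values)) + 1L, nbins = 256L)
  n <- sum(h)
  levels <- 0:255
  cum_n <- cumsum(h)
  cum_s <- cumsum(h * levels)
  total <- cum_s[256]
  best_t <- 1L; best_v <- -1
  for (t in 1:255) {
    n0 <- cum_n[t]          # class < t, i.e. levels 0..t-1
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cum_s[t] / n0
    mu1 <- (total - cum_s[t]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

#' Binarize an 8-bit image
#'
#' @param img a [raster_image] (8-bit).
#' @param method `"otsu"` for automatic thresholding or `"fixed"` with
#'   `threshold` given explicitly. Foreground = values >= threshold.
#' @param threshold fixed threshold (used when `method = "fixed"`).
#' @return A [binary_mask]. A constant image under Otsu yields an
#'   empty-foreground mask with a warning.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = 128) {
  stopifnot(is_raster_image(img))
  method <- match.arg(method)
  if (img$bit_depth != 8) stop("binarize expects an 8-bit image; see to_8bit()")
  if (method == "otsu") {
    if (min(img$values) == max(img$values)) {
      warning("constant image: Otsu threshold undefined, returning empty mask")
      return(binary_mask(matrix(FALSE, nrow(img$values), ncol(img$values)),
                         img$pixel_size_um))
    }
    threshold <- otsu_threshold(img$values)
  }
  binary_mask(img$values >= threshold, img$pixel_size_um)
}

#' Gaussian blur
#'
#' Separable Gaussian with the kernel truncated at 4 sigma, replicate border
#' padding; sigma is given in pixels.
#'
#' @param img a [raster_image] or plain matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return Same type as the input.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(sigma > 0)
  m <- if (is_raster_image(img)) img$values else img
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, ncol(p))
  for (i in seq_along(k))                    # vertical pass
    tmp <- tmp + k[i] * p[(i - 1) + seq_len(nr), ]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k))                    # horizontal pass
    out <- out + k[j] * tmp[, (j - 1) + seq_len(nc)]
  if (is_raster_image(img)) {
    maxv <- 2^img$bit_depth - 1
    raster_image(pmin(pmax(out, 0), maxv), img$pixel_size_um, img$bit_depth)
  } else out
}

#' Rescale a 16-bit image to 8-bit
#'
#' Linear map of the full 16-bit range onto 0..255 (8-bit images pass
#' through), matching the convention of saving prepared images as 8-bit
#' grayscale before tracing.
#'
#' @param img a [raster_image].
#' @return An 8-bit [raster_image].
#' @export
to_8bit <- function(img) {
  stopifnot(is_raster_image(img))
  if (img$bit_depth == 8) return(img)
  raster_image(round(img$values / 65535 * 255), img$pixel_size_um, 8)
}
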