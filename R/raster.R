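# Core containers. All images are numeric matrices indexed [row = y, col = x]
# with 0-based (x, y) pixel coordinates in every user-facing interface and
# pixel centers at integer coordinates (x right, y down).

#' Calibrated 2D grayscale image
#'
#' The universal input of the pipeline: an intensity grid with a pixel-size
#' calibration. Values live on an 8- or 16-bit scale; most preparation steps
#' require (or convert to) 8-bit.
#'
#' @param values numeric matrix, `[row = y, col = x]`, all values within the
#'   declared bit depth.
#' @param pixel_size_um microns per pixel (> 0).
#' @param bit_depth 8 or 16.
#' @return A `raster_image` object.
#' @export
raster_image <- function(values, pixel_size_um = 1, bit_depth = 8) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  stopifnot(nrow(values) >= 1, ncol(values) >= 1)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxv <- 2^bit_depth - 1
  if (anyNA(values)) stop("image values must not contain NA")
  if (min(values) < 0 || max(values) > maxv)
    stop(sprintf("image values outside [0, %d] for bit depth %d", maxv, bit_depth))
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d-bit, %.4g um/px, range [%g, %g]\n",
              img_width(x), img_height(x), x$bit_depth, x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname raster_image
#' @param x object to test / query.
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

#' @rdname raster_image
#' @export
img_width <- function(x) ncol(x$values)

#' @rdname raster_image
#' @export
img_height <- function(x) nrow(x$values)

#' Ordered stack of image slices
#'
#' @param slices list of [raster_image] objects with identical dimensions.
#' @param step_um spacing between consecutive slices in microns.
#' @return A `zstack` object.
#' @export
zstack <- function(slices, step_um = 1) {
  if (length(slices) < 1) stop("a zstack needs at least one slice")
  if (!all(vapply(slices, is_raster_image, logical(1))))
    stop("all slices must be raster_image objects")
  dims <- vapply(slices, function(s) c(img_height(s), img_width(s)), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share the same dimensions")
  structure(list(slices = slices, step_um = step_um), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack> %d slice(s) of %d x %d px, step %.4g um\n",
              length(x$slices), img_width(x$slices[[1]]),
              img_height(x$slices[[1]]), x$step_um))
  invisible(x)
}

#' Polygon region of interest
#'
#' A simple (non-self-intersecting) polygon in 0-based pixel coordinates,
#' used to delimit e.g. an arterial territory or an anastomosis zone.
#'
#' @param vertices n x 2 matrix (or list of `[x, y]` pairs) of ordered
#'   vertices, n >= 3.
#' @return A `polygon_roi` object.
#' @export
polygon_roi <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("a polygon needs >= 3 (x, y) vertices")
  if (anyNA(vertices)) stop("polygon vertices must not contain NA")
  if (polygon_self_intersects(vertices)) stop("polygon must be simple (non-self-intersecting)")
  structure(list(vertices = vertices), class = "polygon_roi")
}

# segment-intersection scan over non-adjacent edge pairs (n is small)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      denom <- cross2(r[1], r[2], s[1], s[2])
      if (abs(denom) < 1e-12) next
      t <- cross2(q[1] - p[1], q[2] - p[2], s[1], s[2]) / denom
      u <- cross2(q[1] - p[1], q[2] - p[2], r[1], r[2]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> %d vertices, bbox x [%g, %g], y [%g, %g]\n",
              nrow(x$vertices), min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param foreground logical matrix, `[row = y, col = x]`.
#' @param pixel_size_um microns per pixel.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(foreground, pixel_size_um = 1) {
  foreground <- as.matrix(foreground)
  storage.mode(foreground) <- "logical"
  if (anyNA(foreground)) stop("mask must not contain NA")
  stopifnot(pixel_size_um > 0)
  structure(list(foreground = foreground, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %d foreground px (%.2f%%)\n",
              ncol(x$foreground), nrow(x$foreground), x$pixel_size_um,
              sum(x$foreground), 100 * mean(x$foreground)))
  invisible(x)
}

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

# coerce anything image-like to a binary_mask
as_binary_mask <- function(x) {
  if (is_binary_mask(x)) return(x)
  if (is_raster_image(x)) return(binary_mask(x$values > 0, x$pixel_size_um))
  if (is.matrix(x)) return(binary_mask(x != 0))
  stop("cannot interpret input as a binary mask")
}

#' Pixel coordinates of mask foreground
#'
#' @param mask a [binary_mask] (or skeleton).
#' @return n x 2 matrix of 0-based (x, y) coordinates.
#' @export
mask_coords <- function(mask) {
  idx <- which(mask$foreground, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray-casting with an explicit on-boundary check, so pixel centers
#' lying exactly on a polygon edge count as inside. This is the single test
#' used by ROI extraction, ROI metrics and collateral scoping.
#'
#' @param px,py point coordinates (vectors).
#' @param roi a [polygon_roi].
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, roi) {
  v <- roi$vertices
  n <- nrow(v)
  vx <- v[, 1]; vy <- v[, 2]
  jx <- vx[c(n, seq_len(n - 1))]; jy <- vy[c(n, seq_len(n - 1))]
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- vx[k]; y2 <- vy[k]
    crosses <- ((y2 > py) != (y1 > py))
    xi <- x2 + (py - y2) * (x1 - x2) / (y1 - y2)
    inside <- xor(inside, crosses & !is.na(xi) & (px < xi))
    # on-segment: collinear and within the edge's bounding box
    dx <- x1 - x2; dy <- y1 - y2
    cr <- abs((px - x2) * dy - (py - y2) * dx)
    len <- sqrt(dx^2 + dy^2)
    onedge <- onedge | (cr <= eps * max(1, len) &
                          px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
                          py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps)
  }
  inside | onedge
}

# rasterize a polygon over image dims -> logical matrix of pixel centers inside
rasterize_polygon <- function(roi, width, height) {
  xs <- rep(0:(width - 1), each = height)
  ys <- rep(0:(height - 1), times = width)
  matrix(points_in_polygon(xs, ys, roi), nrow = height, ncol = width)
}
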