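# Whole-field vascular network metrics: tubular-structure segmentation by
# multiscale Hessian ridge enhancement and the classical density / junction /
# length measures over an ROI.

# Hessian of a Gaussian-smoothed matrix via central differences,
# scale-normalized by sigma^2. Returns list(xx, yy, xy).
hessian_at_scale <- function(m, sigma) {
  g <- gaussian_blur(m, sigma)
  shift <- function(mat, dy, dx) {
    p <- pad_replicate(mat, 1)
    p[(2 + dy):(nrow(mat) + 1 + dy), (2 + dx):(ncol(mat) + 1 + dx)]
  }
  xx <- shift(g, 0, 1) - 2 * g + shift(g, 0, -1)
  yy <- shift(g, 1, 0) - 2 * g + shift(g, -1, 0)
  xy <- (shift(g, 1, 1) - shift(g, 1, -1) - shift(g, -1, 1) + shift(g, -1, -1)) / 4
  s2 <- sigma^2
  list(xx = xx * s2, yy = yy * s2, xy = xy * s2)
}

# eigenvalues of the 2x2 symmetric Hessian per pixel, ordered |l1| <= |l2|
hessian_eigen <- function(h) {
  tr2 <- (h$xx + h$yy) / 2
  disc <- sqrt(((h$xx - h$yy) / 2)^2 + h$xy^2)
  a <- tr2 + disc
  b <- tr2 - disc
  swap <- abs(a) > abs(b)
  l1 <- ifelse(swap, b, a)   # smaller magnitude
  l2 <- ifelse(swap, a, b)   # larger magnitude (negative on bright ridges)
  list(l1 = l1, l2 = l2)
}

#' Multiscale Hessian vesselness (Frangi-type)
#'
#' The classic two-dimensional vesselness for bright curvilinear structures:
#' at each scale sigma the Hessian eigenvalues (|l1| <= |l2|) yield a
#' blobness ratio `Rb = l1 / l2` and structureness `S = sqrt(l1^2 + l2^2)`;
#' the response `exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))` is kept
#' where `l2 < 0` and maximized over scales. `c` defaults to half the
#' maximum structureness at each scale.
#'
#' @param img a [raster_image] or matrix.
#' @param scales vector of Gaussian scales in pixels.
#' @param beta blobness sensitivity (default 0.5).
#' @param c_frac structureness parameter as a fraction of max S (default 0.5).
#' @return Matrix of vesselness values scaled to `[0, 1]`.
#' @export
frangi_vesselness <- function(img, scales = c(1, 2, 4), beta = 0.5,
                              c_frac = 0.5) {
  if (length(scales) == 0) stop("empty scale list")
  m <- if (is_raster_image(img)) img$values else img
  out <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    ev <- hessian_eigen(hessian_at_scale(m, s))
    S <- sqrt(ev$l1^2 + ev$l2^2)
    smax <- max(S)
    if (smax == 0) next
    cc <- c_frac * smax
    rb <- ifelse(ev$l2 != 0, ev$l1 / ev$l2, 0)
    v <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
    v[ev$l2 >= 0] <- 0
    out <- pmax(out, v)
  }
  if (max(out) > 0) out <- out / max(out)
  out
}

#' Remove small connected components from a mask
#'
#' @param mask a [binary_mask].
#' @param min_px minimum component area in pixels.
#' @return The filtered [binary_mask].
#' @export
remove_small_objects <- function(mask, min_px) {
  mask <- as_binary_mask(mask)
  if (min_px <= 1 || !any(mask$foreground)) return(mask)
  lab <- cpp_label_components(mask$foreground, 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  binary_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)), mask$pixel_size_um)
}

#' Segment tubular (vessel-like) structures
#'
#' Multiscale Hessian ridge enhancement ([frangi_vesselness()]) followed by
#' thresholding of the response and removal of small objects. This is the
#' standard equivalent of the enhancement + threshold stage of whole-field
#' angiogenesis quantifiers.
#'
#' @param img a prepared grayscale [raster_image].
#' @param scales vessel radii to enhance, in pixels.
#' @param threshold `"otsu"` or a fixed value in `[0, 1]` applied to the
#'   normalized vesselness.
#' @param min_object_px minimum connected-component area kept (default 30).
#' @return A [binary_mask] of the segmented vessels.
#' @export
segment_vessels <- function(img, scales = c(1, 2, 4), threshold = "otsu",
                            min_object_px = 30) {
  stopifnot(is_raster_image(img))
  if (length(scales) == 0) stop("empty scale list")
  v <- frangi_vesselness(img, scales)
  if (max(v) == min(v)) {  # blank/constant response -> nothing to segment
    return(binary_mask(matrix(FALSE, nrow(v), ncol(v)), img$pixel_size_um))
  }
  if (identical(threshold, "otsu")) {
    v8 <- round(v * 255)
    t <- otsu_threshold(v8)
    fg <- v8 >= t
  } else {
    fg <- v >= threshold
  }
  remove_small_objects(binary_mask(fg, img$pixel_size_um), min_object_px)
}

#' Whole-field network metrics over an ROI
#'
#' Vessel density (foreground percentage of the ROI area), junction count and
#' density, total / average vessel (branch) length, and endpoint count. The
#' skeleton is computed internally by [thin_mask()]; branches follow the
#' skeleton-graph convention, so "average vessel length" is the mean
#' skeleton-branch length between graph nodes. Junction density is
#' normalized by the ROI polygon area (not the foreground area).
#'
#' @param mask a calibrated [binary_mask] of segmented vessels.
#' @param roi optional [polygon_roi]; default is the whole image.
#' @return A one-row data.frame of class `network_metrics` with columns
#'   `vessel_density_percent, junction_count, junction_density_per_mm2,
#'   total_vessel_length_um, average_vessel_length_um, endpoint_count,
#'   roi_area_mm2`.
#' @export
compute_network_metrics <- function(mask, roi = NULL) {
  mask <- as_binary_mask(mask)
  fg <- mask$foreground
  if (is.null(roi)) {
    roi_px <- matrix(TRUE, nrow(fg), ncol(fg))
  } else {
    roi_px <- rasterize_polygon(roi, ncol(fg), nrow(fg))
  }
  n_roi <- sum(roi_px)
  if (n_roi == 0) stop("ROI has zero area on this image")
  px <- mask$pixel_size_um
  roi_area_mm2 <- n_roi * px^2 / 1e6
  scoped <- binary_mask(fg & roi_px, px)
  sk <- thin_mask(scoped)
  g <- build_skeleton_graph(sk)
  meas <- if (length(g$edges) > 0) measure_branches(g) else NULL
  total_len <- if (is.null(meas)) 0 else sum(meas$length_um)
  n_branch <- if (is.null(meas)) 0L else nrow(meas)
  n_jun <- sum(g$vertices$kind == "junction")
  out <- data.frame(
    vessel_density_percent = 100 * sum(scoped$foreground) / n_roi,
    junction_count = n_jun,
    junction_density_per_mm2 = n_jun / roi_area_mm2,
    total_vessel_length_um = total_len,
    average_vessel_length_um = if (n_branch > 0) total_len / n_branch else 0,
    endpoint_count = sum(g$vertices$kind == "endpoint"),
    roi_area_mm2 = roi_area_mm2
  )
  class(out) <- c("network_metrics", "data.frame")
  out
}
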