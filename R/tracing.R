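# Semi-automated centerline tracing: a ridge-feature cost image, shortest
# path tracing between seed points (live-wire style), path smoothing /
# subsampling and rasterized export of the traced skeleton.

#' Tracing parameters
#'
#' Parameter block of the semi-automated tracer. Defaults follow the values
#' that detect artery branches well on vessel-painted images: bright
#' appearance, Hessian smoothing scale 2 px, cost weight 0.7, snap window
#' 9 x 9, path-search window 2500 x 2500, smoothing range 5, subsampling
#' factor 5, line width 3.
#'
#' @param appearance `"bright"` (vessels brighter than background) or
#'   `"dark"`.
#' @param hessian_scale Gaussian scale of the ridge filter, px.
#' @param cost_weight gamma in `[0, 1]` blending ridge feature (gamma)
#'   against raw intensity (1 - gamma) in the cost.
#' @param snap_window odd `c(width, height)` of the snap neighbourhood.
#' @param search_window `c(width, height)` of the path-search window.
#' @param smoothing_range half-width (vertices) of the moving-average
#'   smoother.
#' @param subsampling_factor keep every k-th vertex (>= 1).
#' @param line_width stroke width for rasterized output, px (odd, >= 1).
#' @return A `tracing_params` list.
#' @export
tracing_params <- function(appearance = c("bright", "dark"), hessian_scale = 2,
                           cost_weight = 0.7, snap_window = c(9, 9),
                           search_window = c(2500, 2500), smoothing_range = 5,
                           subsampling_factor = 5, line_width = 3) {
  appearance <- match.arg(appearance)
  if (cost_weight < 0 || cost_weight > 1) stop("cost_weight must be in [0, 1]")
  if (any(snap_window %% 2 != 1)) stop("snap_window must be odd")
  if (subsampling_factor < 1) stop("subsampling_factor must be >= 1")
  if (line_width < 1 || line_width %% 2 != 1) stop("line_width must be odd and >= 1")
  structure(list(appearance = appearance, hessian_scale = hessian_scale,
                 cost_weight = cost_weight, snap_window = as.integer(snap_window),
                 search_window = as.integer(search_window),
                 smoothing_range = as.integer(smoothing_range),
                 subsampling_factor = as.integer(subsampling_factor),
                 line_width = as.integer(line_width)),
            class = "tracing_params")
}

#' Per-pixel traversal cost for live-wire tracing
#'
#' `cost = gamma * (1 - ridge) + (1 - gamma) * (1 - intensity)`, where
#' `ridge` is the rescaled magnitude of the dominant negative Hessian
#' eigenvalue at `hessian_scale` (bright appearance; sign flipped for dark)
#' and `intensity` is the image normalized by its bit-depth maximum. Costs
#' are floored at a small positive value so every step has positive weight.
#'
#' @param img a prepared 8-bit [raster_image].
#' @param params a [tracing_params].
#' @return A `cost_image`: numeric matrix of costs in (0, 1] with the
#'   pixel size as attribute.
#' @export
compute_cost_image <- function(img, params = tracing_params()) {
  stopifnot(is_raster_image(img))
  gamma <- params$cost_weight
  if (gamma < 0 || gamma > 1) stop("cost_weight must be in [0, 1]")
  maxv <- 2^img$bit_depth - 1
  intensity <- img$values / maxv
  if (params$appearance == "dark") intensity <- 1 - intensity
  ev <- hessian_eigen(hessian_at_scale(img$values, params$hessian_scale))
  ridge <- pmax(0, -ev$l2)   # l2 most negative along bright ridges
  if (max(ridge) > 0) ridge <- ridge / max(ridge)
  cost <- gamma * (1 - ridge) + (1 - gamma) * (1 - intensity)
  cost <- pmax(cost, 1e-3)
  structure(cost, pixel_size_um = img$pixel_size_um, class = "cost_image")
}

as_cost_matrix <- function(cost) {
  if (inherits(cost, "cost_image")) unclass(cost) else as.matrix(cost)
}

#' Trace a minimum-cost path between two points
#'
#' Dijkstra shortest path on the 8-connected pixel grid, diagonal steps
#' weighted by sqrt(2), with the edge weight the mean cost of its two pixels
#' (so tracing is symmetric in direction). The search is restricted to a
#' `search_window` centered between the endpoints. Priority ties are broken
#' by pixel index, and neighbours expand in the fixed order
#' E, NE, N, NW, W, SW, S, SE, making outputs bit-reproducible.
#'
#' @param cost a cost image ([compute_cost_image()]) or numeric matrix.
#' @param seed,target `c(x, y)` 0-based pixel coordinates.
#' @param params a [tracing_params] (supplies the search window).
#' @return k x 2 matrix of (x, y) path pixels from seed to target, with the
#'   total path cost in `attr(, "cost")`.
#' @export
trace_segment <- function(cost, seed, target, params = tracing_params()) {
  m <- as_cost_matrix(cost)
  nr <- nrow(m); nc <- ncol(m)
  chk <- function(p, what) {
    if (p[1] < 0 || p[1] >= nc || p[2] < 0 || p[2] >= nr)
      stop(what, " outside the image")
  }
  chk(seed, "seed"); chk(target, "target")
  cx <- (seed[1] + target[1]) / 2; cy <- (seed[2] + target[2]) / 2
  hw <- params$search_window[1] / 2; hh <- params$search_window[2] / 2
  cmin <- max(0, ceiling(cx - hw)); cmax <- min(nc - 1, floor(cx + hw))
  rmin <- max(0, ceiling(cy - hh)); rmax <- min(nr - 1, floor(cy + hh))
  inside <- function(p) p[1] >= cmin && p[1] <= cmax && p[2] >= rmin && p[2] <= rmax
  if (!inside(seed) || !inside(target))
    stop("endpoints outside the mutual search window")
  res <- cpp_dijkstra(m, seed[2], seed[1], target[2], target[1],
                      rmin, rmax, cmin, cmax)
  if (is.null(res$path)) stop("no path found inside the search window")
  path <- cbind(x = res$path[, 2], y = res$path[, 1])
  attr(path, "cost") <- res$cost
  path
}

#' Snap a click to the lowest-cost nearby pixel
#'
#' Returns the minimum-cost pixel within the snap window centered on the
#' click (window clipped at image borders). Candidates are ordered by
#' squared distance from the click (then y, then x), and the first minimum
#' wins, so a uniform-cost window returns the click unchanged.
#'
#' @param cost a cost image or matrix (a [raster_image] is converted with
#'   default parameters).
#' @param click `c(x, y)` 0-based coordinates.
#' @param params a [tracing_params] (supplies the snap window).
#' @return Snapped `c(x, y)`.
#' @export
snap_point <- function(cost, click, params = tracing_params()) {
  if (is_raster_image(cost)) cost <- compute_cost_image(cost, params)
  m <- as_cost_matrix(cost)
  hw <- (params$snap_window[1] - 1) %/% 2
  hh <- (params$snap_window[2] - 1) %/% 2
  xs <- max(0, click[1] - hw):min(ncol(m) - 1, click[1] + hw)
  ys <- max(0, click[2] - hh):min(nrow(m) - 1, click[2] + hh)
  cand <- expand.grid(x = xs, y = ys)
  d2 <- (cand$x - click[1])^2 + (cand$y - click[2])^2
  cand <- cand[order(d2, cand$y, cand$x), ]
  costs <- m[cbind(cand$y + 1, cand$x + 1)]
  best <- cand[which.min(costs), ]  # first minimum in distance order
  c(best$x, best$y)
}

# 8-connected Bresenham line between 0-based (x0,y0) and (x1,y1), inclusive
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  err <- dx - dy
  n <- dx + dy + 1
  out <- matrix(0L, n, 2)
  x <- x0; y <- y0; k <- 0
  repeat {
    k <- k + 1
    out[k, ] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Smooth and subsample a traced path
#'
#' Moving-average smoothing over +-`smoothing_range` vertices with the
#' window shrunk symmetrically near the ends (endpoints fixed), then
#' decimation keeping every `subsampling_factor`-th vertex with both
#' endpoints always kept, and re-rasterization to an 8-connected pixel path.
#'
#' @param path k x 2 (x, y) matrix from [trace_segment()].
#' @param params a [tracing_params].
#' @return The refined k' x 2 (x, y) pixel path.
#' @export
refine_tracing <- function(path, params = tracing_params()) {
  stopifnot(nrow(path) >= 2)
  n <- nrow(path)
  r <- params$smoothing_range
  sm <- path
  if (r > 0 && n > 2) {
    for (i in 2:(n - 1)) {
      w <- min(r, i - 1, n - i)   # symmetric window keeps collinear paths fixed
      sm[i, ] <- colMeans(path[(i - w):(i + w), , drop = FALSE])
    }
  }
  keep <- unique(c(seq(1, n, by = params$subsampling_factor), n))
  ctrl <- round(sm[keep, , drop = FALSE])
  out <- ctrl[1, , drop = FALSE]
  for (i in seq_len(nrow(ctrl) - 1)) {
    seg <- bresenham(ctrl[i, 1], ctrl[i, 2], ctrl[i + 1, 1], ctrl[i + 1, 2])
    out <- rbind(out, seg[-1, , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Assemble a tracing from traced paths
#'
#' @param segments list of (x, y) path matrices (one per traced branch).
#' @param dims image dimensions `c(height, width)` in px.
#' @param pixel_size_um calibration.
#' @param params the [tracing_params] used.
#' @return A `tracing` object.
#' @export
tracing <- function(segments, dims, pixel_size_um = 1,
                    params = tracing_params()) {
  stopifnot(length(segments) >= 1)
  structure(list(segments = segments, dims = dims,
                 pixel_size_um = pixel_size_um, params = params),
            class = "tracing")
}

#' @export
print.tracing <- function(x, ...) {
  cat(sprintf("<tracing> %d segment(s), %d px total, image %d x %d\n",
              length(x$segments), sum(vapply(x$segments, nrow, integer(1))),
              x$dims[2], x$dims[1]))
  invisible(x)
}

#' Rasterize a tracing to a stroke mask
#'
#' Paints every traced path with a stroke of `line_width` px (Chebyshev
#' dilation, so a width-3 horizontal stroke is exactly 3 px tall). The
#' result is the "isolated skeleton" image handed to Gaussian blur /
#' binarization / thinning.
#'
#' @param tr a [tracing].
#' @param line_width override of the params' line width (odd).
#' @return A [binary_mask].
#' @export
rasterize_tracing <- function(tr, line_width = NULL) {
  stopifnot(inherits(tr, "tracing"))
  w <- if (is.null(line_width)) tr$params$line_width else line_width
  if (w %% 2 != 1) stop("line_width must be odd")
  nr <- tr$dims[1]; nc <- tr$dims[2]
  fg <- matrix(FALSE, nr, nc)
  for (seg in tr$segments) {
    ok <- seg[, 1] >= 0 & seg[, 1] < nc & seg[, 2] >= 0 & seg[, 2] < nr
    fg[cbind(seg[ok, 2] + 1, seg[ok, 1] + 1)] <- TRUE
  }
  r <- (w - 1) %/% 2
  if (r > 0) {
    off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
    dil <- morph_extremum(fg * 1, off, "max")
    fg <- dil > 0
  }
  binary_mask(fg, tr$pixel_size_um)
}

#' Trace a set of seed-point branches on an image
#'
#' Batch replacement for interactive clicking: each branch is an ordered
#' list of anchor points; consecutive anchors are snapped ([snap_point()])
#' and connected by [trace_segment()], then refined ([refine_tracing()]).
#'
#' @param img a prepared 8-bit [raster_image].
#' @param seeds named list: `branch_id -> n x 2 matrix (or list) of (x, y)`
#'   anchors.
#' @param params a [tracing_params].
#' @param snap snap anchors to the local cost minimum first (default TRUE).
#' @return A [tracing].
#' @export
trace_branches <- function(img, seeds, params = tracing_params(), snap = TRUE) {
  stopifnot(is_raster_image(img), length(seeds) >= 1)
  cost <- compute_cost_image(img, params)
  segments <- lapply(seeds, function(anchors) {
    if (is.list(anchors)) anchors <- do.call(rbind, lapply(anchors, as.numeric))
    anchors <- as.matrix(anchors)
    if (nrow(anchors) < 2) stop("each branch needs >= 2 anchor points")
    if (snap) anchors <- t(apply(anchors, 1, function(p) snap_point(cost, p, params)))
    path <- NULL
    for (i in seq_len(nrow(anchors) - 1)) {
      seg <- trace_segment(cost, anchors[i, ], anchors[i + 1, ], params)
      path <- if (is.null(path)) seg else rbind(path, seg[-1, , drop = FALSE])
    }
    refine_tracing(path, params)
  })
  tracing(segments, dims = dim(as_cost_matrix(cost)),
          pixel_size_um = img$pixel_size_um, params = params)
}
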