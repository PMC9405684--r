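# Synthetic vascular images with analytic ground truth: bifurcating trees,
# grid-like anastomotic networks, fractal fixtures and imaging noise. Every
# generator output carries the ground truth needed to score the downstream
# stages without re-derivation.

#' Specification of a synthetic bifurcating vascular tree
#'
#' Defaults describe a clean artery-like tree at 1 um/px: branch lengths
#' decay from 160 px by 0.9 per level, which keeps branches in the
#' 105-160 um range typical of traced artery branches; children diverge by
#' 90 degrees at the first bifurcation, narrowing by 0.8 per level; strokes are 3 px wide; jitter, curvature and noise
#' default to zero so the default tree is the exact analytic object.
#'
#' @param depth bifurcation levels (>= 0; depth 0 = a single branch).
#' @param root_length_px trunk length in px.
#' @param length_decay per-level length ratio.
#' @param bifurcation_angle_deg total angle between the two children at the
#'   first bifurcation.
#' @param bifurcation_angle_decay per-level multiplier on the bifurcation
#'   angle; distal generations of arterial trees branch at narrower angles,
#'   and the default 0.8 also guarantees a planar (non-self-intersecting)
#'   embedding up to depth 4, which the ground-truth counts assume.
#' @param angle_jitter_deg uniform jitter added to each child angle.
#' @param stroke_width_px rendered vessel width (odd, >= 1).
#' @param curvature_amplitude_px amplitude of the sinusoidal centerline
#'   perturbation (0 = straight branches).
#' @param curvature_cycles sine periods per branch (multiples of 0.5 keep
#'   branch endpoints exact).
#' @param noise_sigma additive Gaussian noise s.d. (8-bit units).
#' @param background_level additive background (8-bit units).
#' @param n_collaterals extra straight branches labelled "collateral",
#'   rendered in a band beyond the leaf tips (stand-in for inter-territory
#'   anastomoses).
#' @param pixel_size_um calibration of the rendered image.
#' @param seed RNG seed (jitter + noise); `NULL` uses the current stream.
#' @return A `tree_spec` list.
#' @export
tree_spec <- function(depth = 3, root_length_px = 160, length_decay = 0.9,
                      bifurcation_angle_deg = 90,
                      bifurcation_angle_decay = 0.8, angle_jitter_deg = 0,
                      stroke_width_px = 3, curvature_amplitude_px = 0,
                      curvature_cycles = 1, noise_sigma = 0,
                      background_level = 10, n_collaterals = 0,
                      pixel_size_um = 1, seed = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (root_length_px <= 0 || length_decay <= 0) stop("lengths must be > 0")
  if (stroke_width_px < 1 || stroke_width_px %% 2 != 1)
    stop("stroke_width_px must be odd and >= 1")
  structure(list(depth = as.integer(depth), root_length_px = root_length_px,
                 length_decay = length_decay,
                 bifurcation_angle_deg = bifurcation_angle_deg,
                 bifurcation_angle_decay = bifurcation_angle_decay,
                 angle_jitter_deg = angle_jitter_deg,
                 stroke_width_px = as.integer(stroke_width_px),
                 curvature_amplitude_px = curvature_amplitude_px,
                 curvature_cycles = curvature_cycles,
                 noise_sigma = noise_sigma, background_level = background_level,
                 n_collaterals = as.integer(n_collaterals),
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "tree_spec")
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# minimum chord-to-chord distance between non-adjacent branches (branches
# sharing an endpoint - parent/child/sibling - are skipped)
tree_min_separation <- function(branches) {
  chords <- lapply(branches, function(b)
    rbind(b$polyline[1, ], b$polyline[nrow(b$polyline), ]))
  seg_dist <- function(p1, p2, q1, q2) {
    pt <- function(a, b, p) {
      ab <- b - a; t2 <- sum(ab^2)
      t <- if (t2 == 0) 0 else min(1, max(0, sum((p - a) * ab) / t2))
      sqrt(sum((a + t * ab - p)^2))
    }
    cr <- function(u, v) u[1] * v[2] - u[2] * v[1]
    r <- p2 - p1; s <- q2 - q1; den <- cr(r, s)
    if (abs(den) > 1e-12) {
      t <- cr(q1 - p1, s) / den; u <- cr(q1 - p1, r) / den
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) return(0)
    }
    min(pt(p1, p2, q1), pt(p1, p2, q2), pt(q1, q2, p1), pt(q1, q2, p2))
  }
  n <- length(chords)
  if (n < 2) return(Inf)
  worst <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chords[[i]]; b <- chords[[j]]
      shares <- FALSE
      for (u in 1:2) for (v in 1:2)
        if (sqrt(sum((a[u, ] - b[v, ])^2)) < 1e-6) shares <- TRUE
      if (shares) next
      worst <- min(worst, seg_dist(a[1, ], a[2, ], b[1, ], b[2, ]))
    }
  }
  worst
}

# smallest divergence angle (radians) between branches meeting at a common
# point, each direction taken pointing away from the shared point; small
# angles mean the strokes run fused for ~width / (2 sin(angle/2)) px
tree_min_divergence <- function(branches) {
  chords <- lapply(branches, function(b)
    rbind(b$polyline[1, ], b$polyline[nrow(b$polyline), ]))
  n <- length(chords)
  worst <- pi
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      a <- chords[[i]]; b <- chords[[j]]
      for (u in 1:2) for (v in 1:2) {
        if (sqrt(sum((a[u, ] - b[v, ])^2)) >= 1e-6) next
        da <- a[3 - u, ] - a[u, ]; db <- b[3 - v, ] - b[v, ]
        ang <- acos(max(-1, min(1, sum(da * db) /
                                  sqrt(sum(da^2) * sum(db^2)))))
        worst <- min(worst, ang)
      }
    }
  }
  worst
}

# one branch centerline: straight run start -> start + L*dir with an optional
# sinusoidal lateral perturbation vanishing at both ends
branch_polyline <- function(start, dir, len, amp, cycles) {
  n <- max(3, ceiling(len / 1.5) + 1)
  t <- seq(0, 1, length.out = n)
  perp <- c(-dir[2], dir[1])
  lat <- amp * sin(2 * pi * cycles * t)
  cbind(start[1] + t * len * dir[1] + lat * perp[1],
        start[2] + t * len * dir[2] + lat * perp[2])
}

# anti-aliased union of polyline strokes; returns an intensity matrix in
# [0, 255]: 255 inside the stroke, linear 1-px falloff at the rim
rasterize_polylines_aa <- function(polys, width, nr, nc) {
  img <- matrix(0, nr, nc)
  half <- width / 2
  reach <- half + 1
  for (p in polys) {
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      x0 <- max(0, floor(min(a[1], b[1]) - reach))
      x1 <- min(nc - 1, ceiling(max(a[1], b[1]) + reach))
      y0 <- max(0, floor(min(a[2], b[2]) - reach))
      y1 <- min(nr - 1, ceiling(max(a[2], b[2]) + reach))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
      gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
      ab <- b - a
      len2 <- sum(ab^2)
      tt <- if (len2 == 0) 0 else
        pmin(pmax(((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2, 0), 1)
      d <- sqrt((gx - (a[1] + tt * ab[1]))^2 + (gy - (a[2] + tt * ab[2]))^2)
      inten <- 255 * pmin(pmax(half + 0.5 - d, 0), 1)
      sub <- img[ys + 1, xs + 1, drop = FALSE]
      img[ys + 1, xs + 1] <- pmax(sub, inten)
    }
  }
  img
}

#' Generate a synthetic bifurcating vascular tree
#'
#' Renders a recursive tree of bright anti-aliased strokes on a dark noisy
#' background and returns it together with its exact ground truth: branch
#' polylines with labels, true branch / junction / endpoint counts, true
#' per-branch polyline and chord lengths (hence true tortuosity), and the
#' stroke mask (anti-aliased intensity thresholded at 50%). Deterministic
#' given `spec$seed`.
#'
#' @param spec a [tree_spec].
#' @return list with `image` ([raster_image]) and `truth` (a `ground_truth`
#'   list: `branches` data.frame-like records, `polylines`,
#'   `branch_count`, `junction_count`, `endpoint_count`, `stroke_mask`,
#'   optional `collateral_roi`).
#' @export
generate_tree <- function(spec = tree_spec()) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(spec$seed, {
    branches <- list()
    recurse <- function(start, dir, level) {
      len <- spec$root_length_px * spec$length_decay^level
      poly <- branch_polyline(start, dir, len, spec$curvature_amplitude_px,
                              spec$curvature_cycles)
      id <- length(branches) + 1
      branches[[id]] <<- list(
        id = id, level = level,
        label = if (level == 0) "trunk" else "branch",
        polyline = poly,
        length_px = polyline_length(poly),
        chord_px = sqrt(sum((poly[nrow(poly), ] - poly[1, ])^2)))
      if (level < spec$depth) {
        endp <- poly[nrow(poly), ]
        ang0 <- atan2(dir[2], dir[1])
        half <- spec$bifurcation_angle_deg * spec$bifurcation_angle_decay^level /
          2 * pi / 180
        for (s in c(-1, 1)) {
          jit <- if (spec$angle_jitter_deg > 0)
            runif(1, -spec$angle_jitter_deg, spec$angle_jitter_deg) * pi / 180
          else 0
          a <- ang0 + s * half + jit
          recurse(endp, c(cos(a), sin(a)), level + 1)
        }
      }
    }
    recurse(c(0, 0), c(0, -1), 0)  # trunk grows upward (y down convention)

    # the ground-truth counts assume a planar embedding: warn if any two
    # non-adjacent branches come within touching distance of the strokes
    min_sep <- tree_min_separation(branches)
    if (is.finite(min_sep) &&
        min_sep <= spec$stroke_width_px + 2 * spec$curvature_amplitude_px + 2)
      warning(sprintf(paste0(
        "tree branches approach within %.1f px: strokes may touch and the ",
        "ground-truth counts may not hold for this geometry"), min_sep))
    # branches meeting at too shallow an angle stay fused for a long run
    min_div <- tree_min_divergence(branches)
    fused <- (spec$stroke_width_px + 2) / (2 * max(sin(min_div / 2), 1e-9))
    shortest <- min(vapply(branches, `[[`, numeric(1), "chord_px"))
    if (fused > 0.25 * shortest)
      warning(sprintf(paste0(
        "branches diverge at only %.1f deg: strokes stay fused for ~%.0f px ",
        "and the ground-truth counts may not hold for this geometry"),
        min_div * 180 / pi, fused))

    # optional collateral band beyond the crown
    all_pts <- do.call(rbind, lapply(branches, `[[`, "polyline"))
    collateral_roi <- NULL
    if (spec$n_collaterals > 0) {
      ytop <- min(all_pts[, 2])
      clen <- spec$root_length_px / 2
      gap <- 4 * spec$stroke_width_px
      for (k in seq_len(spec$n_collaterals)) {
        y <- ytop - gap * k - 10
        x0 <- -clen / 2 + (k - 1) * 3
        poly <- cbind(seq(x0, x0 + clen, length.out = 20), rep(y, 20))
        id <- length(branches) + 1
        branches[[id]] <- list(id = id, level = NA_integer_,
                               label = "collateral", polyline = poly,
                               length_px = clen, chord_px = clen)
      }
      all_pts <- do.call(rbind, lapply(branches, `[[`, "polyline"))
      collateral_roi_raw <- c(ytop - gap * spec$n_collaterals - 10 - gap,
                              ytop - 10 + gap / 2)
    }

    # translate everything onto a canvas with a safety margin
    margin <- spec$stroke_width_px + 6
    ox <- margin - min(all_pts[, 1])
    oy <- margin - min(all_pts[, 2])
    for (i in seq_along(branches)) {
      p <- branches[[i]]$polyline
      branches[[i]]$polyline <- cbind(p[, 1] + ox, p[, 2] + oy)
    }
    nc <- ceiling(max(all_pts[, 1]) + ox + margin) + 1
    nr <- ceiling(max(all_pts[, 2]) + oy + margin) + 1
    if (nr < 8 || nc < 8) stop("image too small for the requested tree")
    if (!is.null(spec$n_collaterals) && spec$n_collaterals > 0) {
      ys <- collateral_roi_raw + oy
      collateral_roi <- polygon_roi(rbind(c(0, ys[1]), c(nc - 1, ys[1]),
                                          c(nc - 1, ys[2]), c(0, ys[2])))
    }

    aa <- rasterize_polylines_aa(lapply(branches, `[[`, "polyline"),
                                 spec$stroke_width_px, nr, nc)
    stroke_mask <- binary_mask(aa >= 127.5, spec$pixel_size_um)
    vals <- pmin(aa + spec$background_level, 255)
    if (spec$noise_sigma > 0) {
      vals <- vals + rnorm(length(vals), 0, spec$noise_sigma)
      vals <- matrix(pmin(pmax(round(vals), 0), 255), nr, nc)
    }
    img <- raster_image(vals, spec$pixel_size_um, 8)

    d <- spec$depth
    n_tree <- 2^(d + 1) - 1
    truth <- structure(list(
      branches = branches,
      branch_count = n_tree + spec$n_collaterals,
      junction_count = 2^d - 1,
      endpoint_count = 2^d + 1 + 2 * spec$n_collaterals,
      tortuosity = vapply(branches, function(b) b$length_px / b$chord_px,
                          numeric(1)),
      stroke_mask = stroke_mask,
      collateral_roi = collateral_roi,
      spec = spec
    ), class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d branches, %d junctions, %d endpoints\n",
              x$branch_count, x$junction_count, x$endpoint_count))
  invisible(x)
}

#' Generate a grid-like anastomotic network
#'
#' An orthogonal lattice of `n_horizontal` horizontal and `n_vertical`
#' vertical lines spanning the canvas, rendered at `width_px`. Ground truth:
#' crossings = `n_h * n_v` junctions; each horizontal line is cut into
#' `n_v + 1` branches and vice versa; endpoints sit on the canvas border.
#'
#' @param n_horizontal,n_vertical line counts (>= 0, at least one line total).
#' @param spacing_px distance between parallel lines (> width).
#' @param width_px stroke width (odd).
#' @param pixel_size_um calibration.
#' @return list with `mask` ([binary_mask]) and `truth` (counts as above).
#' @export
generate_grid <- function(n_horizontal, n_vertical, spacing_px = 40,
                          width_px = 3, pixel_size_um = 1) {
  if (n_horizontal < 0 || n_vertical < 0 || n_horizontal + n_vertical < 1)
    stop("need at least one line")
  if (spacing_px <= width_px) stop("spacing must exceed the line width")
  if (width_px %% 2 != 1) stop("width_px must be odd")
  margin <- spacing_px
  wd <- max(n_vertical - 1, 0) * spacing_px + 2 * margin
  ht <- max(n_horizontal - 1, 0) * spacing_px + 2 * margin
  fg <- matrix(FALSE, ht, wd)
  r <- (width_px - 1) %/% 2
  ys <- if (n_horizontal > 0) margin + (0:(n_horizontal - 1)) * spacing_px else integer(0)
  xs <- if (n_vertical > 0) margin + (0:(n_vertical - 1)) * spacing_px else integer(0)
  for (y in ys) fg[(y - r):(y + r) + 1, ] <- TRUE
  for (x in xs) fg[, (x - r):(x + r) + 1] <- TRUE
  nh <- n_horizontal; nv <- n_vertical
  truth <- structure(list(
    branch_count = nh * (nv + 1) + nv * (nh + 1),
    junction_count = nh * nv,
    endpoint_count = 2 * (nh + nv),
    line_y = ys, line_x = xs
  ), class = "ground_truth")
  list(mask = binary_mask(fg, pixel_size_um), truth = truth)
}

#' Exact fractal point-set fixtures
#'
#' Calibration targets for box counting: a 1-px straight line (D = 1), a
#' filled square (D = 2), and the Sierpinski triangle of a given depth
#' (similarity dimension log 3 / log 2; the depth-d point set has exactly
#' 3^d cells and its dyadic, origin-anchored box counts follow
#' `N(2^k) = 3^(d-k)` exactly).
#'
#' @param kind `"line"`, `"filled_square"` or `"sierpinski_triangle"`.
#' @param size side length for line / square fixtures.
#' @param depth recursion depth of the Sierpinski triangle.
#' @return A [binary_mask].
#' @export
generate_fractal_fixture <- function(kind = c("line", "filled_square",
                                              "sierpinski_triangle"),
                                     size = NULL, depth = 7) {
  kind <- match.arg(kind)
  if (kind == "line") {
    if (is.null(size)) size <- 1024
    fg <- matrix(FALSE, size, size)
    fg[size %/% 2, ] <- TRUE
  } else if (kind == "filled_square") {
    if (is.null(size)) size <- 512
    fg <- matrix(TRUE, size, size)
  } else {
    n <- 2^depth
    i <- matrix(rep(0:(n - 1), times = n), n)   # row index (y)
    j <- matrix(rep(0:(n - 1), each = n), n)    # col index (x)
    fg <- matrix(bitwAnd(i, j) == 0, n, n)  # bitwAnd drops dim
  }
  binary_mask(fg)
}

#' Add imaging background and noise
#'
#' Additive constant background plus Gaussian noise, rounded and clipped to
#' the image bit depth; deterministic given `seed`.
#'
#' @param img a [raster_image].
#' @param noise_sigma Gaussian s.d. (>= 0, intensity units).
#' @param background_level additive offset.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A noisy [raster_image].
#' @export
add_imaging_noise <- function(img, noise_sigma = 0, background_level = 0,
                              seed = NULL) {
  stopifnot(is_raster_image(img), noise_sigma >= 0)
  if (noise_sigma == 0 && background_level == 0) return(img)
  with_seed(seed, {
    maxv <- 2^img$bit_depth - 1
    v <- img$values + background_level
    if (noise_sigma > 0) {
      v <- v + rnorm(length(v), 0, noise_sigma)
      v <- round(v)
    }
    raster_image(matrix(pmin(pmax(v, 0), maxv), nrow(img$values)),
                 img$pixel_size_um, img$bit_depth)
  })
}
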