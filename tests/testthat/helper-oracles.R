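# Independent oracles and fixture builders shared across the suite. These
# deliberately re-derive quantities with different algorithms than the
# package (value iteration instead of Dijkstra, winding numbers instead of
# ray casting, plain BFS instead of the compiled labeller).

# --- connected components by plain R BFS ------------------------------------
oracle_label_components <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4)
    cbind(c(0, 0, -1, 1), c(-1, 1, 0, 0))
  else as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  nxt <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!fg[rr, cc] || lab[rr, cc]) next
        lab[rr, cc] <- nxt
        queue <- c(queue, (cc - 1L) * nr + rr)
      }
    }
  }
  lab
}

# --- winding-number point-in-polygon (boundary treated as inside) -----------
oracle_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    wn <- 0
    on_edge <- FALSE
    for (k in seq_len(n)) {
      a <- vertices[k, ]; b <- vertices[if (k == n) 1 else k + 1, ]
      cross <- (b[1] - a[1]) * (y - a[2]) - (x - a[1]) * (b[2] - a[2])
      if (abs(cross) < 1e-9 &&
          x >= min(a[1], b[1]) - 1e-9 && x <= max(a[1], b[1]) + 1e-9 &&
          y >= min(a[2], b[2]) - 1e-9 && y <= max(a[2], b[2]) + 1e-9)
        on_edge <- TRUE
      if (a[2] <= y) {
        if (b[2] > y && cross > 0) wn <- wn + 1
      } else {
        if (b[2] <= y && cross < 0) wn <- wn - 1
      }
    }
    on_edge || wn != 0
  }, logical(1))
}

# --- Bellman-Ford-style value iteration for the grid shortest path ----------
# same edge weights as the tracer: 0.5*(c_u + c_v) * steplen
oracle_shortest_cost <- function(cost, seed, target) {
  nr <- nrow(cost); nc <- ncol(cost)
  dist <- matrix(Inf, nr, nc)
  dist[seed[2] + 1, seed[1] + 1] <- 0
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  steplen <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  repeat {
    new <- dist
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      r_dst <- max(1, 1 + dr):min(nr, nr + dr)
      c_dst <- max(1, 1 + dc):min(nc, nc + dc)
      r_src <- r_dst - dr; c_src <- c_dst - dc
      w <- 0.5 * (cost[r_dst, c_dst, drop = FALSE] +
                    cost[r_src, c_src, drop = FALSE]) * steplen[k]
      new[r_dst, c_dst] <- pmin(new[r_dst, c_dst, drop = FALSE],
                                dist[r_src, c_src, drop = FALSE] + w)
    }
    if (isTRUE(all.equal(new, dist, tolerance = 0))) break
    dist <- new
  }
  dist[target[2] + 1, target[1] + 1]
}

# --- random blob masks (thresholded smoothed noise) -------------------------
random_blob_mask <- function(n = 48, seed = 1, p = 0.5) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  s <- vasculomorph::gaussian_blur(m, 2)
  s >= quantile(s, p)
}

# --- draw an 8-connected path into a mask -----------------------------------
path_to_mask <- function(path, nr, nc) {
  fg <- matrix(FALSE, nr, nc)
  fg[cbind(path[, 2] + 1, path[, 1] + 1)] <- TRUE
  fg
}

# random self-avoiding-ish 8-connected walk from a point (may self-touch;
# used where arbitrary skeleton shapes are wanted)
random_walk_path <- function(n_steps, x0, y0, seed) {
  set.seed(seed)
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))[-5, ]
  p <- matrix(c(x0, y0), 1)
  d <- dirs[sample(8, 1), ]
  for (i in seq_len(n_steps)) {
    # mostly keep heading, occasionally turn: gives vessel-like wiggles
    if (runif(1) < 0.25) {
      turn <- sample(c(-1, 1), 1)
      ang <- atan2(d[2], d[1]) + turn * pi / 4
      d <- c(round(cos(ang)), round(sin(ang)))
      if (all(d == 0)) d <- c(1, 0)
    }
    p <- rbind(p, p[nrow(p), ] + d)
  }
  colnames(p) <- c("x", "y")
  p
}

hausdorff <- function(a, b) {
  one <- function(p, q) max(vapply(seq_len(nrow(p)), function(i)
    min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), numeric(1)))
  max(one(a, b), one(b, a))
}
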