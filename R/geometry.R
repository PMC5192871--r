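# Planar geometry primitives shared across the pipeline. All coordinates are
# planar metres (a British-National-Grid-like projected system); no lat/lon.

#' Polyline length
#' @param coords Two-column matrix of vertices (m).
#' @return Length in metres.
#' @export
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

#' Points along a polyline at fixed arc-length spacing
#'
#' Places points at arc lengths `0, step, 2*step, ...` from the start, and
#' always includes the final vertex.
#'
#' @param coords Two-column vertex matrix.
#' @param step Spacing in metres (> 0).
#' @return Matrix of sample points with attribute `"arc"` giving arc lengths.
#' @export
polyline_sample <- function(coords, step) {
  stopifnot(step > 0)
  L <- polyline_length(coords)
  arcs <- seq(0, L, by = step)
  if (abs(arcs[length(arcs)] - L) > 1e-9) arcs <- c(arcs, L)
  pts <- polyline_interpolate(coords, arcs)
  attr(pts, "arc") <- arcs
  pts
}

# interpolate points at given arc lengths along a polyline
polyline_interpolate <- function(coords, arcs) {
  seg <- diff(coords)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  L <- cum[length(cum)]
  arcs <- pmin(pmax(arcs, 0), L)
  i <- findInterval(arcs, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(coords) - 1)
  t <- ifelse(seg_len[i] > 0, (arcs - cum[i]) / seg_len[i], 0)
  cbind(coords[i, 1] + t * seg[i, 1], coords[i, 2] + t * seg[i, 2])
}

#' Recursive perpendicular-distance line simplification
#'
#' The classic split-point (Douglas-Peucker) algorithm: keeps the vertex
#' farthest from the chord if it exceeds `tolerance`, recursing on both halves;
#' endpoints are always preserved.
#'
#' @param coords Two-column vertex matrix.
#' @param tolerance Maximum allowed perpendicular deviation (m, >= 0).
#' @return Simplified vertex matrix.
#' @export
simplify_polyline <- function(coords, tolerance) {
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  n <- nrow(coords)
  if (n <= 2 || tolerance == 0) return(coords)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- point_segment_distance(coords[mid, 1], coords[mid, 2],
                                coords[i, ], coords[j, ])
    k <- mid[which.max(d)]
    if (max(d) > tolerance) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  coords[keep, , drop = FALSE]
}

#' Distance from points to one line segment
#' @param px,py Point coordinates.
#' @param a,b Segment endpoints (length-2 vectors).
#' @return Vector of Euclidean distances.
#' @export
point_segment_distance <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / len2, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

# Intersection of two closed segments a1-a2 and b1-b2.
# Returns a matrix of 0, 1 or 2 intersection points (2 for collinear overlap:
# the overlap's endpoints).
segment_intersection <- function(a1, a2, b1, b2, eps = 1e-9) {
  r <- a2 - a1
  s <- b2 - b1
  rxs <- r[1] * s[2] - r[2] * s[1]
  qp <- b1 - a1
  qpxr <- qp[1] * r[2] - qp[2] * r[1]
  if (abs(rxs) < eps) {
    if (abs(qpxr) >= eps) return(matrix(numeric(0), 0, 2))  # parallel, apart
    # collinear: project onto r
    rr <- sum(r^2)
    if (rr < eps) return(matrix(numeric(0), 0, 2))
    t0 <- sum((b1 - a1) * r) / rr
    t1 <- sum((b2 - a1) * r) / rr
    lo <- max(min(t0, t1), 0); hi <- min(max(t0, t1), 1)
    if (lo > hi + eps) return(matrix(numeric(0), 0, 2))
    p0 <- a1 + lo * r
    p1 <- a1 + hi * r
    if (sum((p1 - p0)^2) < eps^2) return(matrix(p0, 1, 2))
    return(rbind(p0, p1))
  }
  t <- (qp[1] * s[2] - qp[2] * s[1]) / rxs
  u <- qpxr / rxs
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) {
    return(matrix(numeric(0), 0, 2))
  }
  matrix(a1 + pmin(pmax(t, 0), 1) * r, 1, 2)
}

# Clip a polyline to an axis-aligned rectangle [xmin,xmax] x [ymin,ymax].
# Returns a list of clipped pieces (two-column matrices), parametric
# (Liang-Barsky per edge) so total length is conserved across adjacent boxes.
clip_polyline_rect <- function(coords, xmin, xmax, ymin, ymax) {
  pieces <- list()
  cur <- NULL
  push <- function(p) {
    if (is.null(cur)) cur <<- p else cur <<- rbind(cur, p)
  }
  flush <- function() {
    if (!is.null(cur) && nrow(cur) >= 2 && polyline_length(cur) > 0) {
      pieces[[length(pieces) + 1]] <<- cur
    }
    cur <<- NULL
  }
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    d <- b - a
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (e in list(c(-d[1], a[1] - xmin), c(d[1], xmax - a[1]),
                   c(-d[2], a[2] - ymin), c(d[2], ymax - a[2]))) {
      p <- e[1]; q <- e[2]
      if (p == 0) {
        if (q < 0) { ok <- FALSE; break }
      } else {
        t <- q / p
        if (p < 0) { if (t > t1) { ok <- FALSE; break }; t0 <- max(t0, t) }
        else       { if (t < t0) { ok <- FALSE; break }; t1 <- min(t1, t) }
      }
    }
    if (!ok || t0 > t1) { flush(); next }
    pa <- a + t0 * d
    pb <- a + t1 * d
    if (t0 > 0) flush()
    if (is.null(cur)) push(matrix(pa, 1, 2))
    push(matrix(pb, 1, 2))
    if (t1 < 1) flush()
  }
  flush()
  pieces
}

# Uniform-grid spatial index over straight edges (given as parallel vectors
# of endpoint coordinates); keeps point queries near-linear.
edge_index <- function(x1, y1, x2, y2, cell) {
  xmin <- pmin(x1, x2); xmax <- pmax(x1, x2)
  ymin <- pmin(y1, y2); ymax <- pmax(y1, y2)
  x0 <- min(xmin); y0 <- min(ymin)
  key <- function(ix, iy) paste(ix, iy)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(x1)) {
    for (ix in floor((xmin[i] - x0) / cell):floor((xmax[i] - x0) / cell)) {
      for (iy in floor((ymin[i] - y0) / cell):floor((ymax[i] - y0) / cell)) {
        k <- key(ix, iy)
        buckets[[k]] <- c(buckets[[k]], i)
      }
    }
  }
  list(buckets = buckets, x0 = x0, y0 = y0, cell = cell,
       x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# distance from points to nearest edge in the index, capped: returns Inf where
# no edge lies within `max_dist` (search radius).
points_to_edges_distance <- function(idx, px, py, max_dist) {
  n <- length(px)
  out <- rep(Inf, n)
  rad <- ceiling(max_dist / idx$cell)
  ix0 <- floor((px - idx$x0) / idx$cell)
  iy0 <- floor((py - idx$y0) / idx$cell)
  dx <- idx$x2 - idx$x1
  dy <- idx$y2 - idx$y1
  len2 <- dx^2 + dy^2
  for (i in seq_len(n)) {
    ids <- NULL
    for (ix in (ix0[i] - rad):(ix0[i] + rad)) {
      for (iy in (iy0[i] - rad):(iy0[i] + rad)) {
        ids <- c(ids, idx$buckets[[paste(ix, iy)]])
      }
    }
    if (is.null(ids)) next
    ids <- unique(ids)
    t <- ((px[i] - idx$x1[ids]) * dx[ids] + (py[i] - idx$y1[ids]) * dy[ids]) /
      pmax(len2[ids], .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    out[i] <- sqrt(min((px[i] - (idx$x1[ids] + t * dx[ids]))^2 +
                         (py[i] - (idx$y1[ids] + t * dy[ids]))^2))
  }
  out
}
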