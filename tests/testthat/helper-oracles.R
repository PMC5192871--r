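# Fixtures and independent brute-force oracles used across the suite.

unit_square <- function(x0, y0) {
  rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
}

grid_of <- function(vals, cell = 5, nr = NULL, nc = NULL) {
  if (!is.matrix(vals)) vals <- matrix(vals, nr, nc)
  height_grid(vals, origin_x = 0, origin_y = nrow(vals) * cell, cell_size = cell)
}

# enumerate the undirected unit edges of a dissolved mosaic arrangement by
# brute force: every polygon edge, deduplicated on unordered endpoint pairs
oracle_arrangement_edges <- function(polygons) {
  keys <- character(0)
  for (m in polygons) {
    n <- nrow(m)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      a <- sprintf("%.6f,%.6f", m[i, 1], m[i, 2])
      b <- sprintf("%.6f,%.6f", m[j, 1], m[j, 2])
      keys <- c(keys, paste(min(a, b), max(a, b)))
    }
  }
  unique(keys)
}

# brute-force along-line height statistics: enumerate the sample arcs by hand
# and look each point up cell-by-cell with explicit floor arithmetic
oracle_segment_stats <- function(coords, g, step) {
  L <- sum(sqrt(rowSums(diff(coords)^2)))
  arcs <- seq(0, L, by = step)
  if (max(arcs) < L - 1e-9) arcs <- c(arcs, L)
  hs <- numeric(0)
  for (a in arcs) {
    # locate point at arc a by walking vertices
    cum <- c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
    k <- max(which(cum <= a + 1e-12))
    k <- min(k, nrow(coords) - 1)
    seg_len <- cum[k + 1] - cum[k]
    t <- if (seg_len > 0) (a - cum[k]) / seg_len else 0
    p <- coords[k, ] + t * (coords[k + 1, ] - coords[k, ])
    col <- floor((p[1] - g$origin_x) / g$cell_size) + 1
    row <- floor((g$origin_y - p[2]) / g$cell_size) + 1
    if (col == g$n_cols + 1 && p[1] == g$origin_x + g$n_cols * g$cell_size) col <- g$n_cols
    if (row == g$n_rows + 1 && p[2] == g$origin_y - g$n_rows * g$cell_size) row <- g$n_rows
    if (col >= 1 && col <= g$n_cols && row >= 1 && row <= g$n_rows) {
      hs <- c(hs, g$values[row, col])
    }
  }
  hs <- hs[!is.na(hs)]
  list(min = min(hs), max = max(hs), mean = mean(hs))
}

# O(n^2) nearest-neighbour confusion matrix oracle (truth -> model)
oracle_match_points <- function(model_pts, truth_pts, max_dist) {
  n <- c(ww = 0, wo = 0, ow = 0, oo = 0)
  for (i in seq_len(nrow(truth_pts))) {
    d <- sqrt((model_pts$x - truth_pts$x[i])^2 + (model_pts$y - truth_pts$y[i])^2)
    if (length(d) == 0 || min(d) > max_dist) next
    j <- min(which(d == min(d)))
    key <- paste0(substr(model_pts$label[j], 1, 1), substr(truth_pts$label[i], 1, 1))
    n[key] <- n[key] + 1
  }
  confusion_matrix(n[["ww"]], n[["wo"]], n[["ow"]], n[["oo"]])
}

# direct hand computation of kappa from four counts
oracle_kappa <- function(ww, wo, ow, oo) {
  N <- ww + wo + ow + oo
  p_o <- (ww + oo) / N
  p_e <- ((ww + wo) / N) * ((ww + ow) / N) + ((ow + oo) / N) * ((wo + oo) / N)
  (p_o - p_e) / (1 - p_e)
}

# area of the buffered-intersection region by independent dense-grid counting
# over an explicit bounding box, using raw point-to-segment distances
oracle_buffer_intersection_area <- function(net_a, net_b, radius, res = 0.1) {
  pts <- rbind(do.call(rbind, net_a$geometry), do.call(rbind, net_b$geometry))
  # cell-centre counting over an independent bounding box
  xs <- seq(min(pts[, 1]) - radius + res / 2, max(pts[, 1]) + radius, by = res)
  ys <- seq(min(pts[, 2]) - radius + res / 2, max(pts[, 2]) + radius, by = res)
  dist_to <- function(net, px, py) {
    best <- rep(Inf, length(px))
    for (m in net$geometry) {
      for (e in seq_len(nrow(m) - 1)) {
        best <- pmin(best, point_segment_distance(px, py, m[e, ], m[e + 1, ]))
      }
    }
    best
  }
  inside <- 0
  for (y in ys) {
    da <- dist_to(net_a, xs, rep(y, length(xs)))
    db <- dist_to(net_b, xs, rep(y, length(xs)))
    inside <- inside + sum(da <= radius & db <= radius)
  }
  inside * res^2
}

# small attributed network for threshold tests (one row per statistic triple)
attributed_net <- function(stats_df) {
  geoms <- lapply(seq_len(nrow(stats_df)), function(i) {
    rbind(c(0, i * 10), c(100, i * 10))
  })
  wlf_network(geoms, min_h = stats_df$min, max_h = stats_df$max,
              mean_h = stats_df$mean)
}

clean_params <- function(extent_km = 2, seed = 11, ...) {
  landscape_params(extent_km = extent_km, seed = seed, gap_fraction = 0,
                   tree_prob = 0, ditch_prob = 0, woodland_frac = 0,
                   urban_frac = 0, noise_sd = 0, ...)
}
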