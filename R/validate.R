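#' Collapse co-located boundary features to a single class
#'
#' Survey records list every feature present on a boundary (hedge, fence,
#' wall, ...). For comparison against a single-label model the list collapses
#' to one class, with woody features taking dominance: any woody member makes
#' the boundary woody.
#'
#' @param features Character vector of feature classes on one boundary.
#' @param woody_classes Classes counted as woody.
#' @return `"woody"` or `"other"`.
#' @export
dominant_label <- function(features,
                           woody_classes = c("hedge", "line_of_trees",
                                             "shrub", "woody")) {
  if (length(features) == 0) stop("empty feature list", call. = FALSE)
  if (any(features %in% woody_classes)) "woody" else "other"
}

#' Buffer-intersection comparison region
#'
#' Both line networks are buffered by `radius` (round caps and joins) and the
#' comparison is restricted to the intersection of the two buffers, absorbing
#' small line-work disagreements between frameworks. The region is held
#' implicitly: a point lies inside iff its distance to *each* network is at
#' most `radius`, which is exactly the buffered-intersection membership test.
#'
#' @param model_net,truth_net `wlf_network`s.
#' @param radius Buffer radius in metres (default 5).
#' @return An `agreement_region` object; see [region_contains()] and
#'   [region_area()].
#' @export
agreement_region <- function(model_net, truth_net, radius = 5) {
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  make_idx <- function(net) {
    if (nrow(net) == 0) return(NULL)
    ed <- network_edges(net)
    idx <- edge_index(ed$x1, ed$y1, ed$x2, ed$y2, cell = max(radius * 2, 1))
    idx$n_edges <- nrow(ed)
    idx
  }
  structure(
    list(model_idx = make_idx(model_net), truth_idx = make_idx(truth_net),
         radius = radius,
         bbox = region_bbox(model_net, truth_net, radius)),
    class = "agreement_region"
  )
}

region_bbox <- function(a, b, radius) {
  pts <- do.call(rbind, c(a$geometry, b$geometry))
  if (is.null(pts) || nrow(pts) == 0) return(NULL)
  c(xmin = min(pts[, 1]) - radius, xmax = max(pts[, 1]) + radius,
    ymin = min(pts[, 2]) - radius, ymax = max(pts[, 2]) + radius)
}

#' Point-in-region test for an agreement region
#'
#' @param region An [agreement_region()].
#' @param x,y Point coordinates (m).
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y) {
  if (is.null(region$model_idx) || is.null(region$truth_idx)) {
    return(rep(FALSE, length(x)))
  }
  r <- region$radius
  within_r <- function(idx) {
    if (idx$n_edges <= 200) {
      # few edges: one vectorised pass over all points beats the index
      best <- rep(Inf, length(x))
      for (j in seq_len(idx$n_edges)) {
        best <- pmin(best, point_segment_distance(x, y, c(idx$x1[j], idx$y1[j]),
                                                  c(idx$x2[j], idx$y2[j])))
      }
      best <= r
    } else {
      points_to_edges_distance(idx, x, y, r) <= r
    }
  }
  within_r(region$model_idx) & within_r(region$truth_idx)
}

#' Area of an agreement region by fine rasterisation
#'
#' @param region An [agreement_region()].
#' @param resolution Rasterisation cell edge (m); cells whose centre is inside
#'   count fully.
#' @return Area in square metres.
#' @export
region_area <- function(region, resolution = 0.1) {
  bb <- region$bbox
  if (is.null(bb)) return(0)
  cx <- seq(bb["xmin"] + resolution / 2, bb["xmax"], by = resolution)
  cy <- seq(bb["ymin"] + resolution / 2, bb["ymax"], by = resolution)
  total <- 0
  for (yy in cy) {
    inside <- region_contains(region, cx, rep(yy, length(cx)))
    total <- total + sum(inside) * resolution^2
  }
  total
}

#' Sample labelled points along a network inside a region
#'
#' Points are placed along each segment at arc-length multiples of `interval`
#' starting at 0 (the segment end is not forced in), each carrying its
#' segment's label; only points inside the region are kept.
#'
#' @param net A labelled `wlf_network`.
#' @param region An [agreement_region()], or `NULL` to keep all points.
#' @param interval Spacing in metres (default 5).
#' @return Tibble of `x`, `y`, `label`, `segment_id`.
#' @export
sample_labeled_points <- function(net, region = NULL, interval = 5) {
  if (interval <= 0) stop("`interval` must be > 0", call. = FALSE)
  pts <- purrr::map_dfr(seq_len(nrow(net)), function(i) {
    m <- net$geometry[[i]]
    arcs <- seq(0, polyline_length(m), by = interval)
    p <- polyline_interpolate(m, arcs)
    tibble::tibble(x = p[, 1], y = p[, 2],
                   label = net$label[i], segment_id = net$segment_id[i])
  })
  if (nrow(pts) == 0 || is.null(region)) return(pts)
  pts[region_contains(region, pts$x, pts$y), ]
}

#' Two-by-two point-match confusion matrix
#'
#' Counts are model class x truth class with `w` woody and `o` other.
#'
#' @param n_ww,n_wo,n_ow,n_oo Nonnegative counts: model woody/truth woody,
#'   model woody/truth other, model other/truth woody, model other/truth other.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(n_ww, n_wo, n_ow, n_oo) {
  counts <- c(n_ww = n_ww, n_wo = n_wo, n_ow = n_ow, n_oo = n_oo)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$n_ww, x$n_wo, x$n_ow, x$n_oo), 2, 2, byrow = TRUE,
              dimnames = list(model = c("woody", "other"),
                              truth = c("woody", "other")))
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    model = c("woody", "woody", "other", "other"),
    truth = c("woody", "other", "woody", "other"),
    n = c(x$n_ww, x$n_wo, x$n_ow, x$n_oo)
  )
}

#' Nearest-neighbour point matching
#'
#' Each truth point is paired with its nearest model point within `max_dist`
#' (ties broken by the smaller model point index); unpaired truth points are
#' dropped. Each pair increments the confusion cell indexed by (model label,
#' truth label). With `direction = "model_to_truth"` the roles are reversed.
#'
#' @param model_pts,truth_pts Tibbles of `x`, `y`, `label` (see
#'   [sample_labeled_points()]).
#' @param max_dist Maximum pairing distance in metres; defaults to twice the
#'   5-m buffer radius, beyond which two points cannot belong to the same
#'   boundary's buffer pair.
#' @param direction Matching direction.
#' @return A [confusion_matrix()].
#' @export
match_points <- function(model_pts, truth_pts, max_dist = 10,
                         direction = c("truth_to_model", "model_to_truth")) {
  direction <- match.arg(direction)
  if (max_dist <= 0) stop("`max_dist` must be > 0", call. = FALSE)
  if (direction == "model_to_truth") {
    from <- model_pts; to <- truth_pts
  } else {
    from <- truth_pts; to <- model_pts
  }
  n <- c(n_ww = 0, n_wo = 0, n_ow = 0, n_oo = 0)
  if (nrow(from) > 0 && nrow(to) > 0) {
    nn <- nearest_within(from$x, from$y, to$x, to$y, max_dist)
    ok <- !is.na(nn)
    if (any(ok)) {
      from_lab <- from$label[ok]
      to_lab <- to$label[nn[ok]]
      if (direction == "truth_to_model") {
        model_lab <- to_lab; truth_lab <- from_lab
      } else {
        model_lab <- from_lab; truth_lab <- to_lab
      }
      key <- paste0("n_", substr(model_lab, 1, 1), substr(truth_lab, 1, 1))
      tab <- table(factor(key, levels = names(n)))
      n[names(tab)] <- as.numeric(tab)
    }
  }
  confusion_matrix(n[["n_ww"]], n[["n_wo"]], n[["n_ow"]], n[["n_oo"]])
}

# index of nearest (qx,qy) neighbour in (px,py) within max_dist; ties to the
# smallest index. Grid-bucketed for near-linear cost.
nearest_within <- function(qx, qy, px, py, max_dist) {
  out <- rep(NA_integer_, length(qx))
  if (length(px) == 0) return(out)
  cell <- max_dist
  x0 <- min(px); y0 <- min(py)
  bx <- floor((px - x0) / cell); by <- floor((py - y0) / cell)
  buckets <- split(seq_along(px), paste(bx, by))
  qix <- floor((qx - x0) / cell); qiy <- floor((qy - y0) / cell)
  for (i in seq_along(qx)) {
    ids <- integer(0)
    for (ix in (qix[i] - 1):(qix[i] + 1)) {
      for (iy in (qiy[i] - 1):(qiy[i] + 1)) {
        ids <- c(ids, buckets[[paste(ix, iy)]])
      }
    }
    if (length(ids) == 0) next
    d2 <- (px[ids] - qx[i])^2 + (py[ids] - qy[i])^2
    dmin <- min(d2)
    if (dmin <= max_dist^2) out[i] <- min(ids[d2 == dmin])
  }
  out
}

#' Row-wise percent agreement of a confusion matrix
#'
#' The share of a model row's points whose matched truth label agrees,
#' as a percentage. `rounded = TRUE` rounds half-up to the integer shown in
#' summary tables; the unrounded value is what the statistic returns by
#' default.
#'
#' @param cm A [confusion_matrix()].
#' @param row `"woody"` or `"other"` (the model row).
#' @param rounded Round half-up to integer.
#' @return Percent agreement.
#' @export
percent_agreement <- function(cm, row = c("woody", "other"), rounded = FALSE) {
  row <- match.arg(row)
  if (row == "woody") {
    diag <- cm$n_ww; total <- cm$n_ww + cm$n_wo
  } else {
    diag <- cm$n_oo; total <- cm$n_ow + cm$n_oo
  }
  if (total == 0) stop(sprintf("%s row total is zero", row), call. = FALSE)
  pct <- 100 * diag / total
  if (rounded) floor(pct + 0.5) else pct
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e) with observed
#' agreement p_o the diagonal share and expected agreement p_e from the
#' row/column marginal products. If p_e = 1 the statistic is defined as 1 when
#' agreement is perfect and 0 otherwise.
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  N <- cm$n_ww + cm$n_wo + cm$n_ow + cm$n_oo
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- (cm$n_ww + cm$n_oo) / N
  p_e <- ((cm$n_ww + cm$n_wo) * (cm$n_ww + cm$n_ow) +
            (cm$n_ow + cm$n_oo) * (cm$n_wo + cm$n_oo)) / N^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (abs(p_o - 1) < .Machine$double.eps^0.5) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Verbal agreement band for a kappa value
#'
#' Conventional Landis-Koch descriptors; report annotation only.
#'
#' @param kappa Kappa value.
#' @return Band name.
#' @export
kappa_band <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("poor", "slight", "fair", "moderate",
                 "substantial", "almost perfect"),
      right = TRUE) |> as.character()
}

#' One-shot validation of a model network against a truth network
#'
#' Buffers both networks, samples labelled points at `interval` inside the
#' buffer intersection, matches nearest neighbours, and summarises agreement.
#'
#' @inheritParams agreement_region
#' @inheritParams match_points
#' @param interval Point spacing in metres (default 5).
#' @return A `wlf_validation` object with the confusion matrix and statistics;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
validate_networks <- function(model_net, truth_net, radius = 5, interval = 5,
                              max_dist = 2 * radius,
                              direction = "truth_to_model") {
  region <- agreement_region(model_net, truth_net, radius)
  model_pts <- sample_labeled_points(model_net, region, interval)
  truth_pts <- sample_labeled_points(truth_net, region, interval)
  cm <- match_points(model_pts, truth_pts, max_dist, direction)
  N <- cm$n_ww + cm$n_wo + cm$n_ow + cm$n_oo
  kap <- if (N > 0) cohen_kappa(cm) else NA_real_
  structure(
    list(cm = cm, kappa = kap,
         n_model_pts = nrow(model_pts), n_truth_pts = nrow(truth_pts),
         n_matched = N, radius = radius, interval = interval,
         max_dist = max_dist, direction = direction),
    class = "wlf_validation"
  )
}

#' @export
print.wlf_validation <- function(x, ...) {
  cat(sprintf("<wlf_validation> %d matched point pairs (buffer %g m, interval %g m)\n",
              x$n_matched, x$radius, x$interval))
  print(x$cm)
  if (!is.na(x$kappa)) {
    cat(sprintf("kappa = %.3f (%s)\n", x$kappa, kappa_band(x$kappa)))
  }
  invisible(x)
}

#' @export
tidy.wlf_validation <- function(x, ...) tidy.confusion_matrix(x$cm)

#' @export
glance.wlf_validation <- function(x, ...) {
  has_w <- (x$cm$n_ww + x$cm$n_wo) > 0
  has_o <- (x$cm$n_ow + x$cm$n_oo) > 0
  tibble::tibble(
    n_matched = x$n_matched,
    pct_agreement_woody = if (has_w) percent_agreement(x$cm, "woody") else NA_real_,
    pct_agreement_other = if (has_o) percent_agreement(x$cm, "other") else NA_real_,
    kappa = x$kappa,
    kappa_band = if (is.na(x$kappa)) NA_character_ else kappa_band(x$kappa)
  )
}

#' Woody-feature density raster
#'
#' Clips woody segments to a lattice of square cells and reports per-cell
#' woody length divided by cell area, in m per square km for 1-km cells.
#'
#' @param net A classified `wlf_network`.
#' @param cell_size Cell edge in metres (default 1000).
#' @param origin_x,origin_y Lattice origin (south-west corner).
#' @param n_cols,n_rows Lattice shape; defaults cover the network extent.
#' @return A `height_grid` whose values are densities in m/km^2.
#' @export
density_map <- function(net, cell_size = 1000, origin_x = 0, origin_y = 0,
                        n_cols = NULL, n_rows = NULL) {
  if (is.null(n_cols) || is.null(n_rows)) {
    pts <- do.call(rbind, net$geometry)
    if (is.null(pts)) {
      n_cols <- n_cols %||% 1; n_rows <- n_rows %||% 1
    } else {
      n_cols <- n_cols %||% max(1, ceiling((max(pts[, 1]) - origin_x) / cell_size))
      n_rows <- n_rows %||% max(1, ceiling((max(pts[, 2]) - origin_y) / cell_size))
    }
  }
  vals <- matrix(0, n_rows, n_cols)
  clipped <- if (nrow(net) > 0) {
    clip_to_squares(net, square_size = cell_size,
                    origin_x = origin_x, origin_y = origin_y)
  } else net
  if (nrow(clipped) > 0) {
    woody <- clipped[clipped$label == "woody", ]
    for (i in seq_len(nrow(woody))) {
      id <- woody$square_id[i]
      ij <- as.integer(strsplit(sub("^sq_", "", id), "_")[[1]])
      col <- ij[1] + 1
      row <- n_rows - ij[2]  # lattice rows count from the south; grid rows from the north
      if (col >= 1 && col <= n_cols && row >= 1 && row <= n_rows) {
        vals[row, col] <- vals[row, col] + woody$length[i]
      }
    }
  }
  area_km2 <- (cell_size / 1000)^2
  height_grid(vals / area_km2,
              origin_x = origin_x, origin_y = origin_y + n_rows * cell_size,
              cell_size = cell_size)
}

#' Mean cell density per stratum
#'
#' @param density A density `height_grid` from [density_map()].
#' @param cell_strata Tibble of `square_id`, `stratum_id` mapping lattice
#'   cells to strata (square ids as from [square_id_at()]).
#' @return Tibble of `stratum_id`, `mean_density` (same units as the raster).
#' @export
stratum_density_means <- function(density, cell_strata) {
  n_rows <- density$n_rows
  vals <- purrr::map_dbl(cell_strata$square_id, function(id) {
    ij <- as.integer(strsplit(sub("^sq_", "", id), "_")[[1]])
    col <- ij[1] + 1
    row <- n_rows - ij[2]
    if (col >= 1 && col <= density$n_cols && row >= 1 && row <= n_rows) {
      density$values[row, col]
    } else NA_real_
  })
  tibble::tibble(stratum_id = cell_strata$stratum_id, density = vals) |>
    dplyr::group_by(.data$stratum_id) |>
    dplyr::summarise(mean_density = mean(.data$density, na.rm = TRUE),
                     .groups = "drop")
}
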