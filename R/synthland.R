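# Seeded synthetic landscapes with known ground truth: a perturbed-grid field
# mosaic, hedges on a stratum-dependent subset of boundaries, a smooth
# terrain surface, a canopy layer with gaps / emergent trees / ditch
# depressions, land-cover patches, and a census stratum table.

#' Parameters of a synthetic landscape
#'
#' Defaults emulate a lowland GB field landscape at the 5-m grid resolution
#' of an airborne-radar surface model: fields a couple of hundred metres
#' across, hedges 1-4 m tall on roughly half the boundaries in hedged country,
#' modest gappiness, occasional emergent trees, shallow ditch depressions
#' beside some hedges, and small woodland/built-up patches.
#'
#' @param extent_km Landscape edge in whole kilometres (>= 1).
#' @param field_scale Mean field edge length (m).
#' @param hedge_prob_by_stratum Named vector: probability that a boundary in
#'   each stratum (west-to-east bands of 1-km squares) carries a hedge.
#' @param hedge_height_range `c(lo, hi)` hedge canopy height (m).
#' @param gap_fraction Proportion of hedge length with zero canopy.
#' @param tree_prob Per-cell probability of an emergent tree within a hedge.
#' @param tree_height_max Tallest emergent tree (m).
#' @param ditch_prob Probability that a hedge has an adjacent ditch.
#' @param ditch_depth Ditch depression depth (m); appears as negative canopy
#'   beside the hedge. The default sits within the shallow-ditch tolerance
#'   the classification's minimum-height floor (-0.13 m) is designed for.
#' @param woodland_frac,urban_frac Area fractions of woodland / built-up
#'   patches.
#' @param terrain_relief Total terrain height range (m).
#' @param noise_sd Gaussian surface-model noise, standard deviation (m).
#' @param cell_size Raster resolution (m).
#' @param hedge_width Painted hedge width (m): canopy lands on cells whose
#'   centres lie within half this width of the boundary line.
#' @param seed Integer seed; identical seeds give bit-identical landscapes.
#' @return A `landscape_params` list.
#' @export
landscape_params <- function(extent_km = 3, field_scale = 200,
                             hedge_prob_by_stratum = c(lowland = 0.55,
                                                       upland = 0.25),
                             hedge_height_range = c(1, 4),
                             gap_fraction = 0.15,
                             tree_prob = 0.02, tree_height_max = 25,
                             ditch_prob = 0.1, ditch_depth = 0.1,
                             woodland_frac = 0.04, urban_frac = 0.03,
                             terrain_relief = 120, noise_sd = 0,
                             cell_size = 5, hedge_width = 5, seed = 1) {
  p <- list(extent_km = extent_km, field_scale = field_scale,
            hedge_prob_by_stratum = hedge_prob_by_stratum,
            hedge_height_range = hedge_height_range,
            gap_fraction = gap_fraction, tree_prob = tree_prob,
            tree_height_max = tree_height_max,
            ditch_prob = ditch_prob, ditch_depth = ditch_depth,
            woodland_frac = woodland_frac, urban_frac = urban_frac,
            terrain_relief = terrain_relief, noise_sd = noise_sd,
            cell_size = cell_size, hedge_width = hedge_width,
            seed = as.integer(seed))
  probs <- c(p$hedge_prob_by_stratum, p$gap_fraction, p$tree_prob,
             p$ditch_prob, p$woodland_frac, p$urban_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and area fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!(p$hedge_height_range[2] > p$hedge_height_range[1] &&
          p$hedge_height_range[1] >= 0)) {
    stop("hedge_height_range must satisfy hi > lo >= 0", call. = FALSE)
  }
  if (extent_km < 1) stop("extent_km must be >= 1", call. = FALSE)
  if (is.null(names(p$hedge_prob_by_stratum))) {
    stop("hedge_prob_by_stratum must be named by stratum", call. = FALSE)
  }
  structure(p, class = "landscape_params")
}

# evaluate an expression under a private RNG stream
with_stream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Default land-cover legend
#'
#' The class-name-to-code mapping used by the synthetic generator and by the
#' pipeline when reading land-cover grids without an explicit legend; it
#' carries all classes the masking rules require.
#'
#' @return Named integer vector.
#' @export
landcover_legend <- function() {
  c(built_up = 1L, woodland = 2L, littoral = 3L, sublittoral = 4L, other = 5L)
}

# stratum of a 1-km square: west-to-east bands, one per named stratum
square_stratum <- function(ix, n_sq_x, stratum_names) {
  n <- length(stratum_names)
  band <- pmin(floor(ix * n / n_sq_x) + 1, n)
  stratum_names[band]
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds a perturbed-grid field mosaic, dissolves it into a boundary
#' network, designates a stratum-dependent random subset of boundaries as
#' true hedges, renders terrain and surface grids at `cell_size`, paints
#' land-cover patches, and tabulates a census stratum table (every square
#' sampled). All randomness comes from one stream seeded by `params$seed`;
#' draws occur in a fixed, documented order (mosaic jitter, hedge assignment,
#' canopy, patches, noise), so identical parameters give identical output.
#'
#' @param params A [landscape_params()].
#' @return List with `polygons` (ring list), `truth` (labelled
#'   `wlf_network`), `dtm`, `dsm`, `chm_true` (the noise-free canopy layer),
#'   `landcover`, `strata` (census [stratum_table()]), and `params`.
#' @export
generate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  with_stream(params$seed, {
    ext <- params$extent_km * 1000
    # --- field mosaic: jittered grid nodes, quad fields ---
    nfx <- max(2, round(ext / params$field_scale))
    xs <- seq(0, ext, length.out = nfx + 1)
    nodes_x <- outer(rep(1, nfx + 1), xs)
    nodes_y <- outer(xs, rep(1, nfx + 1))
    interior <- matrix(FALSE, nfx + 1, nfx + 1)
    interior[2:nfx, 2:nfx] <- TRUE
    jit <- 0.3 * (ext / nfx)
    nodes_x[interior] <- nodes_x[interior] +
      stats::runif(sum(interior), -jit, jit)
    nodes_y[interior] <- nodes_y[interior] +
      stats::runif(sum(interior), -jit, jit)
    polygons <- list()
    for (i in seq_len(nfx)) {        # row (south-north index)
      for (j in seq_len(nfx)) {      # col (west-east index)
        polygons[[length(polygons) + 1]] <- rbind(
          c(nodes_x[i, j], nodes_y[i, j]),
          c(nodes_x[i, j + 1], nodes_y[i, j + 1]),
          c(nodes_x[i + 1, j + 1], nodes_y[i + 1, j + 1]),
          c(nodes_x[i + 1, j], nodes_y[i + 1, j])
        )
      }
    }
    truth <- polygons_to_network(polygons, crs_note = "synthetic planar metres")
    # --- hedge assignment by stratum of the segment midpoint ---
    strat_names <- names(params$hedge_prob_by_stratum)
    n_sq_x <- params$extent_km
    mid <- t(vapply(truth$geometry,
                    function(m) polyline_interpolate(m, polyline_length(m) / 2)[1, ],
                    numeric(2)))
    seg_strat <- square_stratum(pmin(floor(mid[, 1] / 1000), n_sq_x - 1),
                                n_sq_x, strat_names)
    p_hedge <- unname(params$hedge_prob_by_stratum[seg_strat])
    is_hedge <- stats::runif(nrow(truth)) < p_hedge
    truth$label <- ifelse(is_hedge, "woody", "other")
    # --- terrain ---
    s <- params$cell_size
    n_cells <- ext / s
    cx <- (seq_len(n_cells) - 0.5) * s
    cy_north_first <- ext - (seq_len(n_cells) - 0.5) * s
    dtm_vals <- params$terrain_relief *
      outer(0.5 * (1 + sin(2 * pi * cy_north_first / ext)),
            0.5 * (1 + cos(2 * pi * cx / ext))) / 1
    dtm <- height_grid(dtm_vals, origin_x = 0, origin_y = ext, cell_size = s)
    # --- canopy painting along hedges ---
    canopy <- matrix(0, n_cells, n_cells)
    half_w <- params$hedge_width / 2
    hedge_rows <- which(truth$label == "woody")
    for (i in hedge_rows) {
      m <- truth$geometry[[i]]
      has_ditch <- stats::runif(1) < params$ditch_prob
      reach <- if (has_ditch) params$hedge_width else half_w
      cmin <- pmax(floor((apply(m, 2, min) - reach) / s), 0)
      cmax <- pmin(ceiling((apply(m, 2, max) + reach) / s), n_cells - 1)
      if (any(cmax < cmin)) next
      jj <- (cmin[1]:cmax[1]) + 1          # columns
      rr <- n_cells - (cmin[2]:cmax[2])    # rows, north-first
      gx <- cx[jj]; gy <- ext - (rr - 0.5) * s
      d <- matrix(Inf, length(rr), length(jj))
      for (e in seq_len(nrow(m) - 1)) {
        for (q in seq_along(rr)) {
          d[q, ] <- pmin(d[q, ], point_segment_distance(gx, rep(gy[q], length(gx)),
                                                        m[e, ], m[e + 1, ]))
        }
      }
      core <- which(d <= half_w, arr.ind = TRUE)
      if (nrow(core) > 0) {
        n_core <- nrow(core)
        h <- stats::runif(n_core, params$hedge_height_range[1],
                          params$hedge_height_range[2])
        gap <- stats::runif(n_core) < params$gap_fraction
        tree <- stats::runif(n_core) < params$tree_prob
        h[tree] <- stats::runif(sum(tree), params$hedge_height_range[2],
                                params$tree_height_max)
        h[gap] <- 0
        canopy[cbind(rr[core[, 1]], jj[core[, 2]])] <- h
      }
      if (has_ditch) {
        ring <- which(d > half_w & d <= params$hedge_width, arr.ind = TRUE)
        if (nrow(ring) > 0) {
          idx <- cbind(rr[ring[, 1]], jj[ring[, 2]])
          untouched <- canopy[idx] == 0
          canopy[idx[untouched, , drop = FALSE]] <- -params$ditch_depth
        }
      }
    }
    # --- land-cover patches (woodland, built-up) with their own canopy ---
    lc <- matrix(landcover_legend()[["other"]], n_cells, n_cells)
    paint_patch <- function(frac, code, h_range) {
      if (frac <= 0) return(invisible())
      side <- sqrt(frac) * ext
      x0 <- stats::runif(1, 0, ext - side)
      y0 <- stats::runif(1, 0, ext - side)
      jj <- which(cx >= x0 & cx <= x0 + side)
      rr <- which(cy_north_first >= y0 & cy_north_first <= y0 + side)
      lc[rr, jj] <<- code
      canopy[rr, jj] <<- stats::runif(length(rr) * length(jj),
                                      h_range[1], h_range[2])
    }
    paint_patch(params$woodland_frac, landcover_legend()[["woodland"]], c(8, 20))
    paint_patch(params$urban_frac, landcover_legend()[["built_up"]], c(0, 8))
    landcover <- landcover_grid(lc, landcover_legend(),
                                origin_x = 0, origin_y = ext, cell_size = s)
    # --- surface model ---
    dsm_vals <- dtm_vals + canopy
    if (params$noise_sd > 0) {
      dsm_vals <- dsm_vals + stats::rnorm(length(dsm_vals), 0, params$noise_sd)
    }
    dsm <- height_grid(dsm_vals, origin_x = 0, origin_y = ext, cell_size = s)
    chm_true <- height_grid(canopy, origin_x = 0, origin_y = ext, cell_size = s)
    # --- census stratum table ---
    sq <- expand.grid(ix = 0:(n_sq_x - 1), iy = 0:(n_sq_x - 1))
    sq$stratum <- square_stratum(sq$ix, n_sq_x, strat_names)
    sq$square_id <- square_id_at(sq$ix, sq$iy)
    # small extents may leave the eastern band(s) without any square
    occupied <- strat_names[strat_names %in% sq$stratum]
    strata <- stratum_table(
      stratum_id = occupied,
      population_squares = vapply(occupied,
                                  function(sn) sum(sq$stratum == sn), numeric(1)),
      sampled_square_ids = lapply(occupied,
                                  function(sn) sort(sq$square_id[sq$stratum == sn]))
    )
    list(polygons = polygons, truth = truth, dtm = dtm, dsm = dsm,
         chm_true = chm_true, landcover = landcover, strata = strata,
         params = params)
  })
}

#' Degrade a truth network to mimic framework mismatch
#'
#' Randomly drops segments and jitters vertices, emulating the imperfect
#' agreement between independently derived line frameworks, for exercising
#' the buffered point-sampling validation path.
#'
#' @param truth A `wlf_network`.
#' @param drop_prob Probability a segment is dropped.
#' @param jitter_sd Gaussian vertex jitter, standard deviation (m).
#' @param seed Integer seed.
#' @return A `wlf_network`.
#' @export
degrade_truth <- function(truth, drop_prob = 0, jitter_sd = 0, seed = 1) {
  if (drop_prob < 0 || drop_prob > 1) {
    stop("`drop_prob` must lie in [0, 1]", call. = FALSE)
  }
  with_stream(seed, {
    keep <- stats::runif(nrow(truth)) >= drop_prob
    kept <- truth[keep, ]
    if (nrow(kept) == 0) {
      return(wlf_network(list(), crs_note = attr(truth, "crs_note") %||%
                           "planar metres"))
    }
    geoms <- lapply(kept$geometry, function(m) {
      if (jitter_sd > 0) {
        m + matrix(stats::rnorm(length(m), 0, jitter_sd), nrow(m), 2)
      } else m
    })
    wlf_network(geoms, label = kept$label,
                min_h = kept$min_h, max_h = kept$max_h, mean_h = kept$mean_h,
                square_id = kept$square_id,
                crs_note = attr(truth, "crs_note") %||% "planar metres")
  })
}
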