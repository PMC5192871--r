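#' Stratum table for survey expansion
#'
#' Each stratum (land class) holds the count of 1-km squares in its national
#' population and the ids of the squares sampled from it.
#'
#' @param stratum_id Unique stratum identifiers.
#' @param population_squares Number of 1-km squares in each stratum.
#' @param sampled_square_ids List-column (or list) of sampled square ids per
#'   stratum.
#' @return A tibble with class `stratum_table`.
#' @export
stratum_table <- function(stratum_id, population_squares, sampled_square_ids) {
  if (anyDuplicated(stratum_id)) stop("stratum ids must be unique", call. = FALSE)
  if (!is.list(sampled_square_ids)) sampled_square_ids <- list(sampled_square_ids)
  n_sampled <- lengths(sampled_square_ids)
  if (any(n_sampled < 1)) {
    stop("every stratum must have at least one sampled square", call. = FALSE)
  }
  if (any(population_squares < n_sampled)) {
    stop("population_squares must be >= number of sampled squares", call. = FALSE)
  }
  out <- tibble::tibble(
    stratum_id = as.character(stratum_id),
    population_squares = as.numeric(population_squares),
    sampled_square_ids = sampled_square_ids
  )
  class(out) <- c("stratum_table", class(out))
  out
}

#' Read / write a stratum table as CSV
#'
#' Columns: `stratum_id`, `population_squares`, `sampled_square_ids` (the ids
#' joined with `;`).
#'
#' @param path File path.
#' @export
read_strata_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stratum_table(df$stratum_id, df$population_squares,
                strsplit(as.character(df$sampled_square_ids), ";"))
}

#' @rdname read_strata_csv
#' @param strata A `stratum_table`.
#' @export
write_strata_csv <- function(strata, path) {
  df <- tibble::tibble(
    stratum_id = strata$stratum_id,
    population_squares = strata$population_squares,
    sampled_square_ids = vapply(strata$sampled_square_ids,
                                paste, character(1), collapse = ";")
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Square id for a 1-km square by its south-west corner
#' @param ix,iy Square column/row indices (0-based, west-to-east /
#'   south-to-north).
#' @export
square_id_at <- function(ix, iy) sprintf("sq_%03d_%03d", ix, iy)

#' Clip a network to 1-km squares
#'
#' Splits segments at square borders and tags each piece with the id of the
#' square containing it, so per-square totals conserve overall length.
#'
#' @param net A `wlf_network`.
#' @param square_size Square edge in metres (default 1000).
#' @param origin_x,origin_y Planar coordinates of the square lattice origin
#'   (south-west corner of square `sq_000_000`).
#' @return A `wlf_network` with `square_id` set on every segment.
#' @export
clip_to_squares <- function(net, square_size = 1000, origin_x = 0, origin_y = 0) {
  if (nrow(net) == 0) return(net)
  # outer closing edges of the lattice covering the network clamp inwards, so
  # every piece is assigned exactly once (half-open squares by piece midpoint)
  all_pts <- do.call(rbind, net$geometry)
  ix_max <- max(0, ceiling((max(all_pts[, 1]) - origin_x) / square_size) - 1)
  iy_max <- max(0, ceiling((max(all_pts[, 2]) - origin_y) / square_size) - 1)
  pieces <- list(); parent <- integer(0); sq <- character(0)
  for (i in seq_len(nrow(net))) {
    m <- net$geometry[[i]]
    ix_rng <- floor((range(m[, 1]) - origin_x) / square_size)
    iy_rng <- floor((range(m[, 2]) - origin_y) / square_size)
    for (ix in ix_rng[1]:min(ix_rng[2], ix_max)) {
      for (iy in iy_rng[1]:min(iy_rng[2], iy_max)) {
        got <- clip_polyline_rect(
          m,
          origin_x + ix * square_size, origin_x + (ix + 1) * square_size,
          origin_y + iy * square_size, origin_y + (iy + 1) * square_size
        )
        for (p in got) {
          mid <- polyline_interpolate(p, polyline_length(p) / 2)
          mix <- min(floor((mid[1] - origin_x) / square_size), ix_max)
          miy <- min(floor((mid[2] - origin_y) / square_size), iy_max)
          if (mix != ix || miy != iy) next  # border piece owned by a neighbour
          pieces[[length(pieces) + 1]] <- p
          parent <- c(parent, i)
          sq <- c(sq, square_id_at(ix, iy))
        }
      }
    }
  }
  wlf_network(pieces, label = net$label[parent],
              min_h = net$min_h[parent], max_h = net$max_h[parent],
              mean_h = net$mean_h[parent], square_id = sq,
              crs_note = attr(net, "crs_note") %||% "planar metres")
}

#' Woody length within one square (m)
#'
#' @param net A classified `wlf_network` whose segments carry `square_id`
#'   (see [clip_to_squares()]).
#' @param square_id Square to total.
#' @return Woody length in metres (0 if the square holds no woody segments).
#' @export
square_woody_length <- function(net, square_id) {
  known <- unique(net$square_id)
  if (!square_id %in% known) {
    stop(sprintf("unknown square_id: %s", square_id), call. = FALSE)
  }
  sum(net$length[net$label == "woody" & net$square_id == square_id])
}

#' Per-square woody lengths as a tibble
#'
#' @inheritParams square_woody_length
#' @param square_ids Squares to report; defaults to all squares present.
#' @return Tibble of `square_id`, `woody_m`.
#' @export
square_lengths <- function(net, square_ids = NULL) {
  present <- net |>
    tibble::as_tibble() |>
    dplyr::filter(.data$label == "woody") |>
    dplyr::group_by(square_id = .data$square_id) |>
    dplyr::summarise(woody_m = sum(.data$length), .groups = "drop")
  ids <- square_ids %||% sort(unique(net$square_id))
  tibble::tibble(square_id = ids) |>
    dplyr::left_join(present, by = "square_id") |>
    dplyr::mutate(woody_m = dplyr::coalesce(.data$woody_m, 0))
}

#' Stratified expansion of per-square lengths to a national total
#'
#' The classical stratified estimator: for each stratum, the mean woody length
#' over its sampled squares is scaled by the stratum's square population; the
#' stratum totals are then summed. With `weighted = FALSE` the per-stratum
#' sample sums are added without population scaling.
#'
#' @param square_lengths Tibble of `square_id`, `woody_m` (see
#'   [square_lengths()]), or a named numeric vector of metres by square id.
#' @param strata A [stratum_table()]; every sampled id must be present in
#'   `square_lengths`.
#' @param weighted Use population weighting (default `TRUE`).
#' @return Total length in kilometres, with a `"by_stratum"` tibble attribute.
#' @export
stratified_total <- function(square_lengths, strata, weighted = TRUE) {
  if (is.numeric(square_lengths)) {
    square_lengths <- tibble::tibble(square_id = names(square_lengths),
                                     woody_m = unname(square_lengths))
  }
  lookup <- stats::setNames(square_lengths$woody_m, square_lengths$square_id)
  missing <- setdiff(unique(unlist(strata$sampled_square_ids)),
                     names(lookup))
  if (length(missing) > 0) {
    stop("sampled squares absent from square_lengths: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  by_stratum <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    ids <- strata$sampled_square_ids[[i]]
    mean_m <- mean(lookup[ids])
    tibble::tibble(
      stratum_id = strata$stratum_id[i],
      n_sampled = length(ids),
      population_squares = strata$population_squares[i],
      mean_m = mean_m,
      total_km = if (weighted) strata$population_squares[i] * mean_m / 1000
                 else sum(lookup[ids]) / 1000
    )
  })
  structure(sum(by_stratum$total_km), by_stratum = by_stratum)
}

#' Calibrate classification thresholds against a survey length estimate
#'
#' Sequential coordinate search: the three thresholds are varied in fixed
#' order (`min_h_floor`, `mean_h_floor`, `max_h_ceiling`). Each in turn is
#' scanned across its range in `step` (default 0.01 m) increments and set to
#' the value minimising the absolute deviation of the stratified total from
#' `target_km`; the piecewise-constant objective has flat stretches between
#' segment statistics, so the scan is exhaustive along each coordinate rather
#' than stopping at the first non-improving step. Sweeps repeat until one
#' changes nothing or `max_sweeps` is reached. Ties keep the incumbent value,
#' so the result never has a worse objective than the start.
#'
#' Since segment height statistics do not depend on the thresholds, the
#' network is attributed once and each candidate evaluation is a vectorised
#' relabelling.
#'
#' @param net An attributed `wlf_network` with `square_id` set.
#' @param strata A [stratum_table()].
#' @param target_km Survey-derived target total (km).
#' @param start Starting [threshold_set()]; must lie within `ranges`.
#' @param ranges Named list of `c(low, high)` bounds per parameter.
#' @param step Increment in metres (default 0.01).
#' @param max_sweeps Maximum full sweeps (default 50).
#' @param weighted Passed to [stratified_total()].
#' @return A `wlf_calibration` object: best thresholds, objective (km), the
#'   evaluation trace, and sweep count. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
calibrate_thresholds <- function(net, strata, target_km,
                                 start = threshold_set(),
                                 ranges = list(min_h_floor = c(-2, 2),
                                               mean_h_floor = c(0, 5),
                                               max_h_ceiling = c(5, 100)),
                                 step = 0.01, max_sweeps = 50,
                                 weighted = TRUE) {
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  params <- c("min_h_floor", "mean_h_floor", "max_h_ceiling")
  for (p in params) {
    rng <- ranges[[p]]
    if (is.null(rng) || rng[1] >= rng[2]) {
      stop(sprintf("`ranges$%s` must be c(low, high) with low < high", p),
           call. = FALSE)
    }
    if (start[[p]] < rng[1] || start[[p]] > rng[2]) {
      stop(sprintf("start value of %s (%g) outside its range [%g, %g]",
                   p, start[[p]], rng[1], rng[2]), call. = FALSE)
    }
  }
  square_ids <- sort(unique(net$square_id))
  evaluate <- function(thr) {
    labels <- classify_labels(net$min_h, net$max_h, net$mean_h, thr)
    lens <- net$length * (labels == "woody")
    per_sq <- tapply(lens, factor(net$square_id, levels = square_ids), sum)
    sl <- tibble::tibble(square_id = square_ids,
                         woody_m = as.numeric(per_sq))
    est <- stratified_total(sl, strata, weighted = weighted)
    as.numeric(est)
  }
  trace <- list()
  note <- function(thr, est, obj) {
    trace[[length(trace) + 1]] <<- c(thr$min_h_floor, thr$mean_h_floor,
                                     thr$max_h_ceiling, est, obj)
  }
  cur <- start
  est <- evaluate(cur)
  best_obj <- abs(est - target_km)
  note(cur, est, best_obj)
  sweeps <- 0
  repeat {
    sweeps <- sweeps + 1
    improved_any <- FALSE
    for (p in params) {
      grid <- seq(ranges[[p]][1], ranges[[p]][2], by = step)
      for (v in grid) {
        if (abs(v - cur[[p]]) < step / 2) next
        cand <- cur
        cand[[p]] <- v
        if (!(cand$min_h_floor <= cand$mean_h_floor &&
                cand$mean_h_floor <= cand$max_h_ceiling)) next
        cand_est <- evaluate(cand)
        cand_obj <- abs(cand_est - target_km)
        note(cand, cand_est, cand_obj)
        if (cand_obj < best_obj) {
          cur <- cand
          best_obj <- cand_obj
          improved_any <- TRUE
        }
      }
    }
    if (!improved_any || sweeps >= max_sweeps) break
  }
  tr <- do.call(rbind, trace)
  colnames(tr) <- c("min_h_floor", "mean_h_floor", "max_h_ceiling",
                    "estimate_km", "objective_km")
  structure(
    list(thresholds = cur, objective_km = best_obj,
         estimate_km = evaluate(cur), target_km = target_km,
         sweeps = sweeps, trace = tibble::as_tibble(tr)),
    class = "wlf_calibration"
  )
}

#' @export
print.wlf_calibration <- function(x, ...) {
  cat(sprintf(
    "<wlf_calibration> %d candidates over %d sweep(s)\n  best: min >= %g, mean >= %g, max <= %g m\n  estimate %.3f km vs target %.3f km (|dev| = %.3f km)\n",
    nrow(x$trace), x$sweeps, x$thresholds$min_h_floor,
    x$thresholds$mean_h_floor, x$thresholds$max_h_ceiling,
    x$estimate_km, x$target_km, x$objective_km
  ))
  invisible(x)
}

#' @export
tidy.wlf_calibration <- function(x, ...) x$trace

#' @export
glance.wlf_calibration <- function(x, ...) {
  tibble::tibble(
    min_h_floor = x$thresholds$min_h_floor,
    mean_h_floor = x$thresholds$mean_h_floor,
    max_h_ceiling = x$thresholds$max_h_ceiling,
    estimate_km = x$estimate_km, target_km = x$target_km,
    objective_km = x$objective_km, sweeps = x$sweeps,
    n_evaluated = nrow(x$trace)
  )
}
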