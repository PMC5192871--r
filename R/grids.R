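#' Construct a height grid
#'
#' A `height_grid` is a single-band georeferenced raster of altitudes or
#' canopy heights in metres. The origin is the *top-left* corner of the grid;
#' rows increase southwards. Cell `(r, c)` (1-based) covers the half-open
#' square `[x0 + (c-1)s, x0 + c*s) x (y0 - r*s, y0 - (r-1)s]`, so a point on a
#' shared edge belongs to the cell to its east/south.
#'
#' @param values Numeric matrix of cell values (row 1 is the northernmost row).
#' @param origin_x,origin_y Planar coordinates (m) of the top-left corner.
#' @param cell_size Cell edge length in metres; must be positive.
#' @param nodata Sentinel value marking missing cells. Cells equal to `nodata`
#'   (or `NA`) are excluded from all statistics.
#' @return An object of class `height_grid`.
#' @examples
#' g <- height_grid(matrix(1:6, 2, 3), origin_x = 0, origin_y = 10, cell_size = 5)
#' g
#' @export
height_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                        cell_size = 1, nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  vals <- values
  vals[vals == nodata] <- NA_real_
  if (any(!is.finite(vals) & !is.na(vals))) {
    stop("non-nodata grid values must be finite", call. = FALSE)
  }
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      n_rows = nrow(values), n_cols = ncol(values),
      values = vals, nodata = as.numeric(nodata)
    ),
    class = "height_grid"
  )
}

#' @export
print.height_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "<height_grid> %d x %d cells of %g m; origin (%g, %g); values %s\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
    if (all(is.na(x$values))) "all nodata" else sprintf("[%.3g, %.3g] m", rng[1], rng[2])
  ))
  invisible(x)
}

#' @describeIn height_grid Pivot a grid to a tibble of cell centres and values.
#' @param x A `height_grid`.
#' @param ... Unused.
#' @export
as_tibble.height_grid <- function(x, ...) {
  rc <- expand.grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols))
  cx <- x$origin_x + (rc$col - 0.5) * x$cell_size
  cy <- x$origin_y - (rc$row - 0.5) * x$cell_size
  v <- x$values[cbind(rc$row, rc$col)]
  tibble::tibble(row = rc$row, col = rc$col, x = cx, y = cy, value = v)
}

grid_extent <- function(g) {
  c(
    xmin = g$origin_x, xmax = g$origin_x + g$n_cols * g$cell_size,
    ymin = g$origin_y - g$n_rows * g$cell_size, ymax = g$origin_y
  )
}

#' Check that two grids share georeferencing
#'
#' Two grids are aligned iff origin, cell size and shape are identical.
#' @param a,b Grids to compare.
#' @return `TRUE` invisibly, or an error naming the first mismatching field.
#' @export
check_aligned <- function(a, b) {
  for (f in c("origin_x", "origin_y", "cell_size", "n_rows", "n_cols")) {
    if (!isTRUE(all.equal(a[[f]], b[[f]]))) {
      stop(sprintf("grids are not aligned: `%s` differs (%g vs %g)",
                   f, a[[f]], b[[f]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Map planar points to grid cells
#'
#' Uses the half-open cell convention: a point on a vertical cell edge falls in
#' the cell to the east, on a horizontal edge in the cell to the south.
#'
#' @param g A grid.
#' @param x,y Point coordinates (m).
#' @return A tibble with 1-based `row` and `col`; `NA` for points outside the
#'   grid extent.
#' @export
cell_index <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1
  row <- floor((g$origin_y - y) / g$cell_size) + 1
  # the extent's own closing (east/south) edges belong to the last col/row:
  # no neighbour exists to take them under the half-open interior rule
  col[x == g$origin_x + g$n_cols * g$cell_size] <- g$n_cols
  row[y == g$origin_y - g$n_rows * g$cell_size] <- g$n_rows
  bad <- col < 1 | col > g$n_cols | row < 1 | row > g$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Look up grid values at planar points
#'
#' @inheritParams cell_index
#' @return Numeric vector of cell values; `NA` for nodata cells or points
#'   outside the extent.
#' @export
grid_lookup <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Canopy height model by grid differencing
#'
#' Subtracts a terrain model (ground altitude) from a surface model (altitude
#' at the top of canopies) to give vegetation height above ground. Cells where
#' either input is nodata are nodata in the result.
#'
#' @param dsm Surface model (`height_grid`).
#' @param dtm Terrain model (`height_grid`), aligned with `dsm`.
#' @return A `height_grid` of canopy heights (m).
#' @export
canopy_height <- function(dsm, dtm) {
  check_aligned(dsm, dtm)
  out <- dsm
  out$values <- dsm$values - dtm$values
  out
}

#' Construct a categorical land-cover grid
#'
#' @param values Integer matrix of class codes.
#' @param legend Named integer vector mapping class name to code. Must cover
#'   every code present in `values`.
#' @inheritParams height_grid
#' @return A `landcover_grid`.
#' @export
landcover_grid <- function(values, legend,
                           origin_x = 0, origin_y = nrow(values) * cell_size,
                           cell_size = 1) {
  stopifnot(is.matrix(values))
  if (is.null(names(legend)) || any(names(legend) == "")) {
    stop("`legend` must be a fully named vector (name -> code)", call. = FALSE)
  }
  codes <- unique(as.vector(values))
  missing <- setdiff(codes[!is.na(codes)], legend)
  if (length(missing) > 0) {
    stop(sprintf("cell codes not in legend: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  g <- height_grid(values + 0, origin_x, origin_y, cell_size, nodata = -9999)
  g$legend <- vapply(legend, as.integer, integer(1))
  class(g) <- c("landcover_grid", "height_grid")
  g
}

#' Masking configuration
#'
#' Screening rules for areas where woody linear features do not occur or
#' cannot be detected: built-up, woodland, littoral and sublittoral land
#' cover, and high-altitude ground (default cutoff 300 m).
#'
#' @param excluded_classes Land-cover class names set to zero canopy height.
#' @param altitude_cutoff Altitude (m) above which canopy heights are zeroed.
#' @return A `mask_config` list.
#' @export
mask_config <- function(excluded_classes = c("built_up", "woodland",
                                             "littoral", "sublittoral"),
                        altitude_cutoff = 300) {
  if (!is.numeric(altitude_cutoff) || altitude_cutoff <= 0) {
    stop("`altitude_cutoff` must be positive", call. = FALSE)
  }
  structure(list(excluded_classes = as.character(excluded_classes),
                 altitude_cutoff = as.numeric(altitude_cutoff)),
            class = "mask_config")
}

#' Nearest-neighbour resampling onto a reference grid
#'
#' Used to bring a coarser altitude screen onto the canopy grid: each target
#' cell takes the value of the source cell containing its centre.
#'
#' @param src Source grid.
#' @param ref Reference grid defining the target georeferencing.
#' @return A `height_grid` aligned with `ref`.
#' @export
resample_to_grid <- function(src, ref) {
  cx <- ref$origin_x + (seq_len(ref$n_cols) - 0.5) * ref$cell_size
  cy <- ref$origin_y - (seq_len(ref$n_rows) - 0.5) * ref$cell_size
  vals <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  for (r in seq_len(ref$n_rows)) {
    vals[r, ] <- grid_lookup(src, cx, rep(cy[r], length(cx)))
  }
  out <- ref
  out$values <- vals
  out$legend <- src$legend
  class(out) <- class(src)
  out
}

#' Mask a canopy height grid by land cover and altitude
#'
#' Cells falling in an excluded land-cover class, or whose ground altitude
#' exceeds the cutoff, have their canopy height set to zero (not nodata:
#' masked means "no woody feature possible here", not "unknown"). All other
#' cells pass through unchanged. The operation is idempotent.
#'
#' @param chm Canopy height grid.
#' @param landcover A `landcover_grid`; legend must include every name in
#'   `cfg$excluded_classes`. May be coarser than `chm` (resampled nearest).
#' @param terrain Ground-altitude grid for the altitude screen; may be coarser
#'   than `chm` (resampled nearest).
#' @param cfg A [mask_config()].
#' @return A `height_grid` aligned with `chm`.
#' @export
apply_mask <- function(chm, landcover, terrain, cfg = mask_config()) {
  missing <- setdiff(cfg$excluded_classes, names(landcover$legend))
  if (length(missing) > 0) {
    stop(sprintf("land-cover legend lacks required class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!isTRUE(try(check_aligned(chm, landcover), silent = TRUE))) {
    landcover <- resample_to_grid(landcover, chm)
  }
  if (!isTRUE(try(check_aligned(chm, terrain), silent = TRUE))) {
    terrain <- resample_to_grid(terrain, chm)
  }
  excluded_codes <- unname(landcover$legend[cfg$excluded_classes])
  out <- chm
  mask <- (landcover$values %in% excluded_codes & !is.na(landcover$values)) |
    (!is.na(terrain$values) & terrain$values > cfg$altitude_cutoff)
  dim(mask) <- dim(chm$values)
  out$values[mask & !is.na(out$values)] <- 0
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange. The header's `NODATA_value` is honoured on
#' read and written as -9999 by default. `xllcorner`/`yllcorner` reference the
#' lower-left corner as the format requires; the in-memory origin is top-left.
#'
#' @param path File path.
#' @return `read_esri_ascii()` returns a `height_grid`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such grid file: %s", path), call. = FALSE)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  height_grid(
    m,
    origin_x = hdr$xllcorner,
    origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
    cell_size = hdr$cellsize, nodata = nodata
  )
}

#' @rdname read_esri_ascii
#' @param g Grid to write.
#' @export
write_esri_ascii <- function(g, path) {
  vals <- g$values
  vals[is.na(vals)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
autoplot.height_grid <- function(object, ...) {
  df <- as_tibble.height_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", fill = "m")
}
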