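# GeoJSON plumbing (built on jsonlite). Networks travel as LineString
# features with segment attributes in `properties`; mosaics as Polygon
# features. Coordinates are planar metres; the CRS note rides in a
# `crs_note` foreign member.

#' Write / read a boundary network as GeoJSON
#'
#' Segment attributes (`id`, `label`, `min_h`, `max_h`, `mean_h`,
#' `square_id`) are carried as feature properties.
#'
#' @param net A `wlf_network`.
#' @param path File path.
#' @export
write_network_geojson <- function(net, path) {
  features <- lapply(seq_len(nrow(net)), function(i) {
    m <- net$geometry[[i]]
    props <- list(id = net$segment_id[i], label = net$label[i])
    for (f in c("min_h", "max_h", "mean_h", "square_id")) {
      v <- net[[f]][i]
      if (!is.na(v)) props[[f]] <- v
    }
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(m)),
                                           function(r) c(m[r, 1], m[r, 2]))),
      properties = props
    )
  })
  obj <- list(type = "FeatureCollection",
              crs_note = attr(net, "crs_note") %||% "planar metres",
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_geojson
#' @export
read_network_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- obj$features
  geoms <- lapply(feats, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, unlist))
  })
  prop <- function(name, default) {
    vapply(feats, function(f) {
      v <- f$properties[[name]]
      if (is.null(v)) default else v
    }, default)
  }
  wlf_network(
    geoms,
    label = prop("label", "unclassified"),
    min_h = prop("min_h", NA_real_), max_h = prop("max_h", NA_real_),
    mean_h = prop("mean_h", NA_real_),
    square_id = prop("square_id", NA_character_),
    crs_note = obj$crs_note %||% "planar metres"
  )
}

#' Write / read a polygon mosaic as GeoJSON
#'
#' @param polygons List of polygon rings (two-column matrices).
#' @param path File path.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(m) {
    m <- as.matrix(m)
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(m)),
                                                function(r) c(m[r, 1], m[r, 2])))),
      properties = stats::setNames(list(), character(0))
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, unlist))
  })
}
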