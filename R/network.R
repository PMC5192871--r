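# Boundary line networks are tibbles: one row per segment, coordinates in a
# list-column of two-column matrices, so dplyr verbs apply directly.

COORD_FMT <- "%.6f,%.6f"  # vertex key precision: 1e-6 m

vertex_key <- function(x, y) sprintf(COORD_FMT, x, y)

#' Build a boundary network tibble from segment coordinates
#'
#' @param geometry List of two-column coordinate matrices (planar metres),
#'   each with at least two vertices.
#' @param label Segment class labels (`"woody"`, `"other"`, `"unclassified"`).
#' @param min_h,max_h,mean_h Optional canopy height attributes (m).
#' @param square_id Optional 1-km square membership.
#' @param crs_note Free text naming the planar reference system.
#' @return A `wlf_network` tibble with deterministic segment ids (sorted by
#'   the lexicographic (min-endpoint, max-endpoint) key, so runs are
#'   reproducible).
#' @export
wlf_network <- function(geometry, label = "unclassified",
                        min_h = NA_real_, max_h = NA_real_, mean_h = NA_real_,
                        square_id = NA_character_,
                        crs_note = "planar metres") {
  geometry <- lapply(geometry, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  })
  len <- vapply(geometry, polyline_length, numeric(1))
  if (any(len <= 0) && length(len) > 0) {
    stop("zero-length segment(s) at position(s): ",
         paste(which(len <= 0), collapse = ", "), call. = FALSE)
  }
  n <- length(geometry)
  net <- tibble::tibble(
    segment_id = character(n),
    geometry = geometry,
    length = len,
    min_h = rep_len(min_h, n), max_h = rep_len(max_h, n),
    mean_h = rep_len(mean_h, n),
    label = rep_len(label, n),
    square_id = rep_len(square_id, n)
  )
  if (n > 0) {
    key <- vapply(geometry, function(m) {
      e1 <- vertex_key(m[1, 1], m[1, 2])
      e2 <- vertex_key(m[nrow(m), 1], m[nrow(m), 2])
      mid <- vertex_key(mean(m[, 1]), mean(m[, 2]))
      paste(min(e1, e2), max(e1, e2), mid)
    }, character(1))
    ord <- order(key)
    net <- net[ord, ]
    net$segment_id <- sprintf("s%05d", seq_len(n))
  }
  attr(net, "crs_note") <- crs_note
  class(net) <- c("wlf_network", class(tibble::tibble()))
  net
}

# rebuild class/ids after dplyr manipulation dropped them
as_wlf_network <- function(tbl, crs_note = attr(tbl, "crs_note") %||% "planar metres") {
  wlf_network(tbl$geometry, label = tbl$label,
              min_h = tbl$min_h, max_h = tbl$max_h, mean_h = tbl$mean_h,
              square_id = tbl$square_id, crs_note = crs_note)
}

#' Total network length in metres
#' @param net A `wlf_network`.
#' @export
network_length <- function(net) sum(net$length)

#' Constituent straight edges of a network
#'
#' Decomposes every segment into its straight edges; useful for comparing a
#' dissolved network against a brute-force arrangement enumeration.
#'
#' @param net A `wlf_network`.
#' @return Tibble of edges with endpoint coordinates and the parent
#'   `segment_id`; `edge_key` is an undirected identity key.
#' @export
network_edges <- function(net) {
  purrr::map_dfr(seq_len(nrow(net)), function(i) {
    m <- net$geometry[[i]]
    k <- nrow(m) - 1
    tibble::tibble(
      segment_id = net$segment_id[i],
      x1 = m[-nrow(m), 1], y1 = m[-nrow(m), 2],
      x2 = m[-1, 1], y2 = m[-1, 2]
    )
  }) |>
    dplyr::mutate(edge_key = paste(
      pmin(vertex_key(.data$x1, .data$y1), vertex_key(.data$x2, .data$y2)),
      pmax(vertex_key(.data$x1, .data$y1), vertex_key(.data$x2, .data$y2))
    ))
}

validate_ring <- function(ring, index) {
  m <- as.matrix(ring)
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop(sprintf("polygon %d has fewer than 3 distinct vertices", index),
                  call. = FALSE)
  # brute-force self-intersection test over non-adjacent edge pairs
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      p <- segment_intersection(m[i, ], m[i %% n + 1, ],
                                m[j, ], m[j %% n + 1, ])
      if (nrow(p) > 0) {
        stop(sprintf("polygon %d is self-intersecting", index), call. = FALSE)
      }
    }
  }
  m
}

#' Dissolve a polygon mosaic into a noded boundary network
#'
#' Every polygon edge shared between adjacent polygons appears exactly once in
#' the result. Edges are chained through degree-2 vertices into segments whose
#' endpoints are the junction points of the boundary graph (vertices of degree
#' other than 2). An isolated ring with no junctions stays one closed segment.
#'
#' @param polygons List of polygon rings (two-column coordinate matrices,
#'   closed or open; must not self-intersect).
#' @param crs_note Planar reference note carried on the output.
#' @return A `wlf_network`.
#' @export
polygons_to_network <- function(polygons, crs_note = "planar metres") {
  edges <- list()       # undirected edge key -> c(v1_key, v2_key)
  verts <- new.env(hash = TRUE, parent = emptyenv())  # key -> c(x, y)
  for (pi in seq_along(polygons)) {
    m <- validate_ring(polygons[[pi]], pi)
    n <- nrow(m)
    keys <- vertex_key(m[, 1], m[, 2])
    for (i in seq_len(n)) {
      j <- i %% n + 1
      if (keys[i] == keys[j]) next
      assign(keys[i], m[i, ], envir = verts)
      assign(keys[j], m[j, ], envir = verts)
      ek <- paste(min(keys[i], keys[j]), max(keys[i], keys[j]))
      edges[[ek]] <- c(min(keys[i], keys[j]), max(keys[i], keys[j]))
    }
  }
  chain_edges(edges, verts, crs_note)
}

# chain an undirected edge set into junction-to-junction segments
chain_edges <- function(edges, verts, crs_note) {
  if (length(edges) == 0) {
    return(wlf_network(list(), crs_note = crs_note))
  }
  ekeys <- sort(names(edges))
  adj <- new.env(hash = TRUE, parent = emptyenv())   # vertex key -> edge ids
  for (i in seq_along(ekeys)) {
    vv <- edges[[ekeys[i]]]
    for (v in vv) assign(v, c(get0(v, envir = adj), i), envir = adj)
  }
  degree <- function(v) length(get0(v, envir = adj))
  used <- rep(FALSE, length(ekeys))
  other_end <- function(eid, v) {
    vv <- edges[[ekeys[eid]]]
    if (vv[1] == v) vv[2] else vv[1]
  }
  walk <- function(start_v, eid) {
    # follow unused edges from start_v through degree-2 vertices
    path <- start_v
    v <- start_v
    repeat {
      used[eid] <<- TRUE
      v <- other_end(eid, v)
      path <- c(path, v)
      if (degree(v) != 2 || v == start_v) break
      nxt <- setdiff(get0(v, envir = adj), which(used))
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      eid <- min(nxt)
    }
    path
  }
  geoms <- list()
  all_verts <- ls(envir = adj)
  junctions <- all_verts[vapply(all_verts, degree, integer(1)) != 2]
  for (v in sort(junctions)) {
    repeat {
      cand <- get0(v, envir = adj)
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      path <- walk(v, min(cand))
      geoms[[length(geoms) + 1]] <- path
    }
  }
  # remaining edges form pure rings: start each at its smallest vertex key
  while (any(!used)) {
    remaining <- ekeys[!used]
    start_v <- min(vapply(remaining, function(k) edges[[k]][1], character(1)))
    cand <- get0(start_v, envir = adj)
    cand <- cand[!used[cand]]
    path <- walk(start_v, min(cand))
    geoms[[length(geoms) + 1]] <- path
  }
  coords <- lapply(geoms, function(path) {
    do.call(rbind, lapply(path, function(k) get(k, envir = verts)))
  })
  wlf_network(coords, crs_note = crs_note)
}

#' Cartographically generalize a network
#'
#' Simplifies each segment with recursive perpendicular-distance (split-point)
#' simplification. Endpoints — and therefore junctions and noding — are
#' preserved; a segment's length can only shrink.
#'
#' @param net A `wlf_network`.
#' @param tolerance Maximum perpendicular deviation in metres (>= 0); 0 leaves
#'   the network unchanged.
#' @return A `wlf_network`.
#' @export
generalize_network <- function(net, tolerance = 0) {
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  if (tolerance == 0 || nrow(net) == 0) return(net)
  out <- net
  out$geometry <- lapply(net$geometry, simplify_polyline, tolerance = tolerance)
  out$length <- vapply(out$geometry, polyline_length, numeric(1))
  out
}

#' Split segments at mutual intersections
#'
#' Any two segments crossing at an interior point are cut there (including
#' T-junctions where one segment ends on another's interior), yielding a noded
#' network. Total length is conserved. Already-noded networks pass through
#' unchanged up to segment ids.
#'
#' @param net A `wlf_network`.
#' @return A noded `wlf_network`; attribute columns are inherited from parent
#'   segments.
#' @export
split_segments <- function(net) {
  if (nrow(net) == 0) return(net)
  ed <- network_edges(net)
  seg_of <- match(ed$segment_id, net$segment_id)
  # arc position of each edge start within its segment
  arc0 <- numeric(nrow(ed))
  for (i in seq_len(nrow(net))) {
    m <- net$geometry[[i]]
    rows <- which(seg_of == i)
    arc0[rows] <- c(0, cumsum(sqrt(rowSums(diff(m)^2))))[seq_along(rows)]
  }
  cell <- max(stats::median(sqrt((ed$x2 - ed$x1)^2 + (ed$y2 - ed$y1)^2)), 1e-6)
  idx <- edge_index(ed$x1, ed$y1, ed$x2, ed$y2, cell)
  # candidate pairs: edges sharing a bucket
  pairs <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ls(envir = idx$buckets)) {
    ids <- idx$buckets[[k]]
    if (length(ids) < 2) next
    cmb <- utils::combn(sort(ids), 2)
    for (q in seq_len(ncol(cmb))) {
      assign(paste(cmb[1, q], cmb[2, q]), TRUE, envir = pairs)
    }
  }
  cuts <- vector("list", nrow(net))  # arc positions to cut, per segment
  add_cut <- function(si, arc, L) {
    if (arc > 1e-9 && arc < L - 1e-9) cuts[[si]] <<- c(cuts[[si]], arc)
  }
  for (k in ls(envir = pairs)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    i <- ij[1]; j <- ij[2]
    if (seg_of[i] == seg_of[j] && abs(i - j) <= 1) next  # consecutive edges
    pts <- segment_intersection(c(ed$x1[i], ed$y1[i]), c(ed$x2[i], ed$y2[i]),
                                c(ed$x1[j], ed$y1[j]), c(ed$x2[j], ed$y2[j]))
    if (nrow(pts) == 0) next
    for (p in seq_len(nrow(pts))) {
      for (e in c(i, j)) {
        si <- seg_of[e]
        d <- sqrt((pts[p, 1] - ed$x1[e])^2 + (pts[p, 2] - ed$y1[e])^2)
        add_cut(si, arc0[e] + d, net$length[si])
      }
    }
  }
  pieces <- list()
  parent <- integer(0)
  for (i in seq_len(nrow(net))) {
    m <- net$geometry[[i]]
    cc <- sort(unique(round(cuts[[i]] %||% numeric(0), 9)))
    if (length(cc) == 0) {
      pieces[[length(pieces) + 1]] <- m
      parent <- c(parent, i)
      next
    }
    bounds <- c(0, cc, net$length[i])
    vert_arc <- c(0, cumsum(sqrt(rowSums(diff(m)^2))))
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b]; hi <- bounds[b + 1]
      inner <- which(vert_arc > lo + 1e-9 & vert_arc < hi - 1e-9)
      piece <- rbind(polyline_interpolate(m, lo),
                     m[inner, , drop = FALSE],
                     polyline_interpolate(m, hi))
      pieces[[length(pieces) + 1]] <- piece
      parent <- c(parent, i)
    }
  }
  wlf_network(pieces,
              label = net$label[parent],
              min_h = net$min_h[parent], max_h = net$max_h[parent],
              mean_h = net$mean_h[parent], square_id = net$square_id[parent],
              crs_note = attr(net, "crs_note") %||% "planar metres")
}

#' Brute-force noding check
#'
#' All-pairs test that no two segments intersect except at shared endpoints.
#' Intended for tests and small networks (quadratic cost).
#'
#' @param net A `wlf_network`.
#' @return `TRUE` if noded.
#' @export
is_noded <- function(net) {
  n <- nrow(net)
  if (n < 2) return(TRUE)
  endpoint_keys <- lapply(net$geometry, function(m) {
    vertex_key(m[c(1, nrow(m)), 1], m[c(1, nrow(m)), 2])
  })
  for (i in seq_len(n - 1)) {
    mi <- net$geometry[[i]]
    for (j in (i + 1):n) {
      mj <- net$geometry[[j]]
      for (a in seq_len(nrow(mi) - 1)) {
        for (b in seq_len(nrow(mj) - 1)) {
          pts <- segment_intersection(mi[a, ], mi[a + 1, ], mj[b, ], mj[b + 1, ])
          if (nrow(pts) == 0) next
          for (p in seq_len(nrow(pts))) {
            k <- vertex_key(pts[p, 1], pts[p, 2])
            if (!(k %in% endpoint_keys[[i]]) || !(k %in% endpoint_keys[[j]])) {
              return(FALSE)
            }
          }
        }
      }
    }
  }
  TRUE
}

#' @export
print.wlf_network <- function(x, ...) {
  cat(sprintf("<wlf_network> %d segments, %.1f m total (%s)\n",
              nrow(x), network_length(x),
              attr(x, "crs_note") %||% "planar metres"))
  NextMethod()
}

#' @export
autoplot.wlf_network <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    m <- object$geometry[[i]]
    tibble::tibble(segment_id = object$segment_id[i],
                   label = object$label[i], x = m[, 1], y = m[, 2])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$segment_id,
                                   colour = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", colour = "class")
}
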