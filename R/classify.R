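#' Height thresholds separating woody from other linear features
#'
#' A boundary segment is classified woody when its minimum sampled canopy
#' height is at least `min_h_floor` (negative by default: a ditch running
#' beside a hedge pulls the minimum below ground level), its mean height is at
#' least `mean_h_floor` (well below typical hedge height, tolerating gappy
#' features), and its maximum height is at most `max_h_ceiling` (the tallest
#' tree expected; taller returns are artefacts or buildings). All comparisons
#' are inclusive, so the threshold values themselves classify as woody.
#'
#' @param min_h_floor Minimum-height floor in metres (default -0.13).
#' @param mean_h_floor Mean-height floor in metres (default 0.58).
#' @param max_h_ceiling Maximum-height ceiling in metres (default 58).
#' @return A `threshold_set`.
#' @export
threshold_set <- function(min_h_floor = -0.13, mean_h_floor = 0.58,
                          max_h_ceiling = 58) {
  if (!(min_h_floor <= mean_h_floor && mean_h_floor <= max_h_ceiling)) {
    stop("thresholds must satisfy min_h_floor <= mean_h_floor <= max_h_ceiling",
         call. = FALSE)
  }
  structure(list(min_h_floor = min_h_floor, mean_h_floor = mean_h_floor,
                 max_h_ceiling = max_h_ceiling),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> min >= %g m, mean >= %g m, max <= %g m\n",
              x$min_h_floor, x$mean_h_floor, x$max_h_ceiling))
  invisible(x)
}

#' Attribute segments with canopy-height statistics
#'
#' Heights are sampled at points every `sample_step` metres along each
#' segment, measured from its start and always including both endpoints, and
#' summarised as min/max/mean over the non-nodata samples. Nodata samples are
#' excluded from the statistics (missing data, unlike masked cells which carry
#' an explicit zero); a segment whose samples are all nodata keeps the label
#' `"unclassified"` and `NA` statistics.
#'
#' @param net A `wlf_network`.
#' @param chm Canopy height grid.
#' @param sample_step Sampling interval in metres; defaults to the grid cell
#'   size, approximating per-cell traversal statistics.
#' @return The network with `min_h`, `max_h`, `mean_h` filled in.
#' @export
attribute_network <- function(net, chm, sample_step = chm$cell_size) {
  if (sample_step <= 0) stop("`sample_step` must be > 0", call. = FALSE)
  if (nrow(net) == 0) return(net)
  ext <- grid_extent(chm)
  out <- net
  for (i in seq_len(nrow(net))) {
    m <- net$geometry[[i]]
    if (any(m[, 1] < ext["xmin"] | m[, 1] > ext["xmax"] |
              m[, 2] < ext["ymin"] | m[, 2] > ext["ymax"])) {
      stop(sprintf("segment %s extends outside the grid extent",
                   net$segment_id[i]), call. = FALSE)
    }
    pts <- polyline_sample(m, sample_step)
    h <- grid_lookup(chm, pts[, 1], pts[, 2])
    h <- h[!is.na(h)]
    if (length(h) == 0) {
      out$min_h[i] <- out$max_h[i] <- out$mean_h[i] <- NA_real_
      out$label[i] <- "unclassified"
    } else {
      out$min_h[i] <- min(h)
      out$max_h[i] <- max(h)
      out$mean_h[i] <- mean(h)
    }
  }
  attr(out, "attributed") <- TRUE
  out
}

#' Vectorised three-threshold classification rule
#'
#' Pure function of the three height statistics and the thresholds.
#'
#' @param min_h,max_h,mean_h Height statistics (m).
#' @param thresholds A [threshold_set()].
#' @return Character vector: `"woody"`, `"other"`, or `"unclassified"` where a
#'   statistic is `NA`.
#' @export
classify_labels <- function(min_h, max_h, mean_h, thresholds = threshold_set()) {
  woody <- min_h >= thresholds$min_h_floor &
    mean_h >= thresholds$mean_h_floor &
    max_h <= thresholds$max_h_ceiling
  out <- ifelse(woody, "woody", "other")
  out[is.na(out)] <- "unclassified"
  out
}

#' Label attributed segments as woody or other
#'
#' @param net A `wlf_network` whose height statistics are set (see
#'   [attribute_network()]).
#' @inheritParams classify_labels
#' @return The network with `label` set.
#' @export
label_network <- function(net, thresholds = threshold_set()) {
  attributed <- !is.na(net$min_h) & !is.na(net$max_h) & !is.na(net$mean_h)
  if (nrow(net) > 0 && !any(attributed) && !isTRUE(attr(net, "attributed"))) {
    stop("network has no height attributes; run attribute_network() first",
         call. = FALSE)
  }
  out <- net
  out$label <- classify_labels(net$min_h, net$max_h, net$mean_h, thresholds)
  out
}

#' Attribute and classify a whole network
#'
#' Convenience composition of [attribute_network()] and [label_network()];
#' segment labels are independent of processing order.
#'
#' @inheritParams attribute_network
#' @inheritParams classify_labels
#' @return The classified `wlf_network`.
#' @export
classify_network <- function(net, chm, thresholds = threshold_set(),
                             sample_step = chm$cell_size) {
  label_network(attribute_network(net, chm, sample_step), thresholds)
}

#' Total length of woody-labelled segments (m)
#' @param net A classified `wlf_network`.
#' @export
woody_length <- function(net) sum(net$length[net$label == "woody"])
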