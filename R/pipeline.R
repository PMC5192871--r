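#' Run configuration
#'
#' Declarative configuration of a full model run, readable from a YAML file
#' (see [read_run_config()]); command-line overrides win on conflict.
#'
#' @param paths Named list of input/output paths: inputs `dsm`, `dtm`,
#'   `landcover` (ESRI ASCII grids), `polygons` or `network` (GeoJSON),
#'   `truth` (GeoJSON, optional), `strata` (CSV, optional); `out_dir` for
#'   outputs.
#' @param thresholds A [threshold_set()].
#' @param mask A [mask_config()].
#' @param buffer_radius Validation buffer radius (m, > 0).
#' @param point_interval Validation point spacing (m, > 0).
#' @param sample_step Attribution sampling step (m, > 0); `NULL` uses the
#'   grid cell size.
#' @param generalize_tolerance Network generalization tolerance (m, >= 0).
#' @param seed Integer seed recorded in the manifest.
#' @param verbosity 0 silent, 1 stage messages.
#' @return A `run_config`.
#' @export
run_config <- function(paths, thresholds = threshold_set(),
                       mask = mask_config(), buffer_radius = 5,
                       point_interval = 5, sample_step = NULL,
                       generalize_tolerance = 0, seed = 1, verbosity = 1) {
  if (buffer_radius <= 0) stop("`buffer_radius` must be > 0", call. = FALSE)
  if (point_interval <= 0) stop("`point_interval` must be > 0", call. = FALSE)
  if (!is.null(sample_step) && sample_step <= 0) {
    stop("`sample_step` must be > 0", call. = FALSE)
  }
  if (generalize_tolerance < 0) {
    stop("`generalize_tolerance` must be >= 0", call. = FALSE)
  }
  structure(list(paths = paths, thresholds = thresholds, mask = mask,
                 buffer_radius = buffer_radius,
                 point_interval = point_interval, sample_step = sample_step,
                 generalize_tolerance = generalize_tolerance,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `thresholds` and
#' `mask` are nested maps.
#'
#' @param path YAML file path.
#' @param overrides Named list applied over the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  thr <- do.call(threshold_set, y$thresholds %||% list())
  msk <- do.call(mask_config, y$mask %||% list())
  run_config(
    paths = y$paths,
    thresholds = thr, mask = msk,
    buffer_radius = y$buffer_radius %||% 5,
    point_interval = y$point_interval %||% 5,
    sample_step = y$sample_step,
    generalize_tolerance = y$generalize_tolerance %||% 0,
    seed = y$seed %||% 1,
    verbosity = y$verbosity %||% 1
  )
}

#' Execute the full modelling pipeline
#'
#' Stages, in order: canopy height differencing, masking, network
#' construction (from a polygon mosaic or a pre-built line network),
#' generalization, classification, per-square estimation (if a stratum table
#' is supplied), and validation against a reference network (if supplied).
#' Outputs — classified network GeoJSON, estimates CSV, validation summary —
#' and a machine-readable run manifest land in `paths$out_dir`. Outputs are a
#' pure function of (inputs, configuration, seed); any stage failure aborts
#' with the stage name.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the classified network, the estimate (km,
#'   or `NULL`), the validation object (or `NULL`), and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbosity > 0) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- cfg$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage chm: differencing surface and terrain grids")
  chm <- stage("chm", {
    dsm <- read_esri_ascii(cfg$paths$dsm)
    dtm <- read_esri_ascii(cfg$paths$dtm)
    canopy_height(dsm, dtm)
  })
  say("stage mask: land-cover and altitude screens")
  chm <- stage("mask", {
    lc_raw <- read_esri_ascii(cfg$paths$landcover)
    legend <- landcover_legend()
    lc <- landcover_grid(lc_raw$values, legend, lc_raw$origin_x,
                         lc_raw$origin_y, lc_raw$cell_size)
    dtm <- read_esri_ascii(cfg$paths$dtm)
    apply_mask(chm, lc, dtm, cfg$mask)
  })
  say("stage network: building the linear framework")
  net <- stage("network", {
    if (!is.null(cfg$paths$polygons)) {
      polygons_to_network(read_polygons_geojson(cfg$paths$polygons))
    } else if (!is.null(cfg$paths$network)) {
      split_segments(read_network_geojson(cfg$paths$network))
    } else {
      stop("config must name either `polygons` or `network`")
    }
  })
  if (cfg$generalize_tolerance > 0) {
    say("stage generalize: tolerance %g m", cfg$generalize_tolerance)
    net <- stage("generalize", generalize_network(net, cfg$generalize_tolerance))
  }
  say("stage classify: attributing and labelling %d segments", nrow(net))
  classified <- stage("classify", {
    classify_network(net, chm, cfg$thresholds,
                     cfg$sample_step %||% chm$cell_size)
  })
  write_network_geojson(classified, file.path(out_dir, "classified_network.geojson"))

  estimate_km <- NULL
  if (!is.null(cfg$paths$strata)) {
    say("stage estimate: stratified expansion")
    estimate_km <- stage("estimate", {
      strata <- read_strata_csv(cfg$paths$strata)
      clipped <- clip_to_squares(classified)
      sl <- square_lengths(clipped)
      est <- stratified_total(sl, strata)
      readr::write_csv(
        dplyr::bind_rows(
          attr(est, "by_stratum"),
          tibble::tibble(stratum_id = "TOTAL",
                         total_km = as.numeric(est))
        ),
        file.path(out_dir, "estimates.csv")
      )
      as.numeric(est)
    })
  }

  validation <- NULL
  if (!is.null(cfg$paths$truth)) {
    say("stage validate: buffered point comparison")
    validation <- stage("validate", {
      truth <- read_network_geojson(cfg$paths$truth)
      v <- validate_networks(classified, truth, radius = cfg$buffer_radius,
                             interval = cfg$point_interval)
      readr::write_csv(tidy.wlf_validation(v),
                       file.path(out_dir, "confusion_matrix.csv"))
      writeLines(
        utils::capture.output(print(v)),
        file.path(out_dir, "validation_summary.txt")
      )
      v
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wlfmap")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = list(
      thresholds = unclass(cfg$thresholds), mask = unclass(cfg$mask),
      buffer_radius = cfg$buffer_radius, point_interval = cfg$point_interval,
      sample_step = cfg$sample_step,
      generalize_tolerance = cfg$generalize_tolerance,
      paths = cfg$paths
    ),
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(classified = classified, estimate_km = estimate_km,
                 validation = validation, manifest = manifest))
}
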