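#' Read a pipeline configuration
#'
#' YAML (or JSON) with blocks `integration` (mirroring
#' [integration_config()]), `sv_files` (named per-frequency Sv CSV paths),
#' `roi_file`, `clustering` (`k_candidates`, `k_roi`, `seed`), `escore`
#' (`threshold`, `sweep`), `metrics` (`zone_file`), `scattering`
#' (`parameter_file`, `medium`). Defaults follow the standard operating
#' values: Ellipsoid-threshold 25, 1.5 m x 3-ping ESDU, -100 dB threshold,
#' 15 m surface exclusion.
#'
#' @param path YAML/JSON file path.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ib <- cfg$integration %||% list()
  cfg$integration <- integration_config(
    esdu_pings = ib$esdu_pings %||% 3L,
    vertical_bin_m = ib$vertical_bin_m %||% 1.5,
    sv_threshold_db = ib$sv_threshold_db %||% -100,
    surface_exclusion_m = ib$surface_exclusion_m %||% 15)
  cl <- cfg$clustering %||% list()
  cfg$clustering <- list(k_candidates = cl$k_candidates %||% 2:8,
                         k_roi = cl$k_roi %||% 3L,
                         seed = cl$seed %||% 1L)
  es <- cfg$escore %||% list()
  cfg$escore <- list(threshold = es$threshold %||% 25,
                     sweep = es$sweep %||% 1:100)
  structure(cfg, class = "pipeline_config")
}

load_aligned_set <- function(config) {
  if (is.null(config$sv_files)) stop_escore("config lacks sv_files")
  egs <- lapply(names(config$sv_files), function(f) {
    p <- config$sv_files[[f]]
    if (!file.exists(p)) stop_escore("Sv file not found: ", p)
    read_sv_csv(p, as.numeric(f))
  })
  align_frequencies(egs)
}

#' Train an Escore model from configured inputs
#'
#' Runs training end to end: load and align the per-frequency Sv grids,
#' difference against 38 kHz, extract each ROI, refine it to an echo-type by
#' K-means, build the library, select the number of echo-classes by
#' validity-index vote (unless `k` is fixed in the config), label by
#' hierarchical clustering, validate with a random forest, assign dominant
#' frequencies, and fit the per-class ellipsoids.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param set optionally, a pre-built aligned `echogram_set` (bypasses
#'   `sv_files`).
#' @param rois optionally, a list of [roi]s (bypasses `roi_file`).
#' @return list: `model` (`escore_model`), `library`, `selection`
#'   (`cluster_selection_report`), `rf` (`rf_validation_report`),
#'   `dominant`, `grid` (the `delta_sv_grid`).
#' @export
run_train <- function(config, set = NULL, rois = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(set)) set <- load_aligned_set(config)
  if (is.null(rois)) {
    if (is.null(config$roi_file) || !file.exists(config$roi_file)) {
      stop_escore("ROI file not found: ",
                  config$roi_file %||% "<unset>")
    }
    rois <- read_roi_csv(config$roi_file)
  }
  grid <- compute_delta_sv(set)
  seed <- config$clustering$seed
  ets <- lapply(seq_along(rois), function(i) {
    cells <- extract_roi_cells(grid, rois[[i]])
    kmeans_refine(cells, k_roi = config$clustering$k_roi,
                  seed = seed + i, retain = rois[[i]]$retain,
                  roi_id = rois[[i]]$id)
  })
  lib <- build_library(ets)
  selection <- select_k(lib, config$clustering$k_candidates, seed = seed)
  k <- config$clustering$k %||% selection$winning_k
  lib <- hierarchical_classify(lib, k)
  rf <- rf_validate(lib, seed = seed)
  dom <- dominant_frequency(lib, set)
  model <- fit_ellipsoids(lib, threshold = config$escore$threshold,
                          dominant_khz = dom)
  list(model = model, library = lib, selection = selection, rf = rf,
       dominant = dom, grid = grid)
}

#' Classify a whole dataset with a fitted Escore model
#'
#' Runs the classifier over every echo-integration cell, generates
#' per-class echograms over 15-250 m at the model's dominant frequencies,
#' and asserts linear-domain sA conservation across the class partition.
#'
#' @param config a `pipeline_config` (or path).
#' @param model an `escore_model` (or path to a model JSON).
#' @param set optional pre-built aligned `echogram_set`.
#' @return list: `classified` (`classified_grid`), `per_class` (echogram
#'   list at 38 kHz), `conservation` (relative sA closure error).
#' @export
run_classify <- function(config, model, set = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.character(model)) model <- read_model_json(model)
  if (is.null(set)) set <- load_aligned_set(config)
  grid <- compute_delta_sv(set)
  classified <- classify_cells(grid, model,
                               threshold = config$escore$threshold %||%
                                 model$threshold)
  pc <- per_class_echograms(classified, set, 38)
  ## conservation: per-class + unclassified sA = total sA of evaluable cells
  tops <- set$depth_edges[-length(set$depth_edges)]
  bots <- set$depth_edges[-1]
  win <- tops >= 15 - 1e-9 & bots <= 250 + 1e-9
  lin <- db_to_linear(set$sv[["38"]][, win, drop = FALSE])
  lab <- classified$labels[, win, drop = FALSE]
  lin[is.na(lab)] <- NA
  total <- sum(lin, na.rm = TRUE)
  parts <- sum(vapply(pc, function(e) sum(db_to_linear(e$sv), na.rm = TRUE),
                      1.0))
  conservation <- abs(parts - total) / max(total, .Machine$double.xmin)
  list(classified = classified, per_class = pc, conservation = conservation)
}

#' Compute the metrics report for a configured dataset
#'
#' @param config a `pipeline_config` (or path).
#' @param set optional pre-built aligned `echogram_set`.
#' @return A `metrics_report`.
#' @export
run_metrics <- function(config, set = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(set)) set <- load_aligned_set(config)
  if (is.null(set$lat) || is.null(set$lon)) {
    stop_escore("positions required for solar classification")
  }
  periods <- classify_solar(set$ping_times, set$lat, set$lon)
  zones <- NULL
  if (!is.null(config$metrics$zone_file)) {
    if (!file.exists(config$metrics$zone_file)) {
      stop_escore("zone file not found: ", config$metrics$zone_file)
    }
    zones <- assign_zones(set$ping_times,
                          read_zone_csv(config$metrics$zone_file))
    if (anyNA(zones)) warning("pings outside any zone were dropped")
  }
  egs <- lapply(names(set$sv), function(f) set_echogram(set, as.numeric(f)))
  names(egs) <- names(set$sv)
  metrics_report(egs, periods, zones)
}
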