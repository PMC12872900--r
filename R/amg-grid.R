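# Hyperparameter grid handling for automatic mask generators (AMG).
#
# An AMG configuration is a named list of the seven tunable fields of the
# mask-generator interface. The harness carries these values opaquely to the
# proposal backend: their semantics live entirely in the backend.

amg_fields <- c("points_per_side", "points_per_batch", "pred_iou_thresh",
                "stability_score_thresh", "stability_score_offset",
                "crop_n_layers", "crop_n_points_downscale_factor")

#' AMG hyperparameter grid specification
#'
#' Defines an ordered set of candidate values per AMG hyperparameter. Every
#' field must be present with a nonempty value list. The default values
#' reproduce the reference search space for mask-generator tuning: three
#' candidates for six hyperparameters with the batch size fixed, i.e.
#' `3^6 = 729` configurations.
#'
#' @param points_per_side,points_per_batch,pred_iou_thresh,stability_score_thresh,stability_score_offset,crop_n_layers,crop_n_points_downscale_factor
#'   numeric vectors of candidate values. Counts must be >= 1
#'   (`crop_n_layers` >= 0) and thresholds must lie in (0, 1).
#' @return an object of class `amg_grid_spec` (named list of value vectors in
#'   canonical field order).
#' @examples
#' nrow(expand_amg_grid(amg_grid_spec()))  # 729
#' @export
amg_grid_spec <- function(points_per_side = c(32, 64, 128),
                          points_per_batch = 128,
                          pred_iou_thresh = c(0.72, 0.8, 0.88),
                          stability_score_thresh = c(0.92, 0.95, 0.98),
                          stability_score_offset = c(0.7, 1.0, 1.3),
                          crop_n_layers = c(0, 1, 2),
                          crop_n_points_downscale_factor = c(1, 2, 4)) {
  spec <- list(points_per_side = points_per_side,
               points_per_batch = points_per_batch,
               pred_iou_thresh = pred_iou_thresh,
               stability_score_thresh = stability_score_thresh,
               stability_score_offset = stability_score_offset,
               crop_n_layers = crop_n_layers,
               crop_n_points_downscale_factor = crop_n_points_downscale_factor)
  for (f in amg_fields) {
    v <- spec[[f]]
    if (length(v) == 0 || !is.numeric(v)) {
      stop("value list for ", f, " must be a nonempty numeric vector")
    }
  }
  if (any(spec$points_per_side < 1) || any(spec$points_per_batch < 1) ||
      any(spec$crop_n_points_downscale_factor < 1) || any(spec$crop_n_layers < 0)) {
    stop("count-valued hyperparameters out of range")
  }
  if (any(spec$pred_iou_thresh <= 0 | spec$pred_iou_thresh >= 1) ||
      any(spec$stability_score_thresh <= 0 | spec$stability_score_thresh >= 1)) {
    stop("threshold hyperparameters must lie in (0, 1)")
  }
  structure(spec, class = "amg_grid_spec")
}

#' Read a grid specification from YAML or JSON
#'
#' @param path file with one entry per AMG hyperparameter.
#' @return an `amg_grid_spec`.
#' @export
read_grid_spec <- function(path) {
  if (!file.exists(path)) stop_stage("io", paste0("file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  missing <- setdiff(amg_fields, names(raw))
  if (length(missing)) {
    stop_stage("format", paste0("grid spec misses fields: ",
                                paste(missing, collapse = ", ")))
  }
  do.call(amg_grid_spec, lapply(raw[amg_fields], as.numeric))
}

#' Expand a grid specification into all configurations
#'
#' Cartesian product of the per-field candidate lists, ordered
#' lexicographically in canonical field order (the first field varies
#' slowest); the expansion order is deterministic and is used to break
#' ranking ties.
#'
#' @param spec an [amg_grid_spec()].
#' @return data frame with one row per configuration, a `config_id` column
#'   (expansion index) and one column per hyperparameter.
#' @export
expand_amg_grid <- function(spec) {
  stopifnot(inherits(spec, "amg_grid_spec"))
  grid <- expand.grid(rev(unclass(spec)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  rownames(grid) <- NULL
  cbind(config_id = seq_len(nrow(grid)), grid)
}

# one grid row -> named config list handed to backends
amg_config_from_row <- function(row) {
  cfg <- as.list(row[amg_fields])
  structure(cfg, class = "amg_config")
}
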