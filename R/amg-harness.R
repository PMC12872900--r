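# Evaluation harnesses over pluggable segmentation backends.
#
# Backend contracts (plain R closures):
#  * mask-proposal backend:  function(image, config, seed) -> list of logical
#    matrices (mask proposals); may signal an error (a backend failure).
#  * promptable segmenter:   function(image, points = NULL, box = NULL) ->
#    exactly one logical matrix.
# Both must be deterministic for fixed inputs and seed. The harness never
# interprets the AMG hyperparameters; it only carries them to the backend.

#' Point-prompt evaluation protocol
#'
#' For every ground-truth instance of every image: place a single positive
#' point prompt at the instance's geometric median
#' ([geometric_median_prompt()]), obtain one predicted mask from the
#' segmenter, and score it against the instance with
#' [generalized_dice()]. Segmenter failures are recorded and the instance is
#' skipped.
#'
#' @param segmenter promptable segmenter closure
#'   `function(image, points = NULL, box = NULL)`.
#' @param images_with_gt list of scenes, each a list with elements `image`
#'   and `gt` (a [mask_set()] whose instances are all nonempty).
#' @return list with `scores` (data frame `image_id`, `instance_id`, `gds`),
#'   `mean_gds`, `n_prompts` (prompts issued) and `failures` (data frame
#'   `image_id`, `instance_id`, `error`).
#' @export
evaluate_point_prompts <- function(segmenter, images_with_gt) {
  scores <- list(); failures <- list(); n_prompts <- 0L
  for (scene in images_with_gt) {
    gt <- scene$gt
    stopifnot(inherits(gt, "mask_set"))
    for (i in seq_along(gt$instances)) {
      prompt <- geometric_median_prompt(gt$instances[[i]])
      n_prompts <- n_prompts + 1L
      pred <- tryCatch(segmenter(scene$image, points = list(prompt)),
                       error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          image_id = gt$image_id, instance_id = gt$instance_ids[i],
          error = conditionMessage(pred))
        next
      }
      scores[[length(scores) + 1L]] <- data.frame(
        image_id = gt$image_id, instance_id = gt$instance_ids[i],
        gds = generalized_dice(gt$instances[[i]], as_binary_mask(pred))$gds)
    }
  }
  scores <- do.call(rbind, scores) %||%
    data.frame(image_id = character(0), instance_id = integer(0), gds = numeric(0))
  failures <- do.call(rbind, failures) %||%
    data.frame(image_id = character(0), instance_id = integer(0), error = character(0))
  list(scores = scores, mean_gds = mean(scores$gds),
       n_prompts = n_prompts, failures = failures)
}

#' Evaluate one AMG configuration
#'
#' Runs the proposal backend on every image, matches the proposals to the
#' ground truth with [match_masks()] and scores each image with the F-beta
#' of [precision_recall()]. The configuration's summary score is the
#' arithmetic mean of the per-image F scores. Backend errors propagate to
#' the caller (the grid search turns them into failure records).
#'
#' @param backend mask-proposal backend closure
#'   `function(image, config, seed)`.
#' @param images_with_gt list of scenes (`image` + `gt`); each image must
#'   carry at least one ground-truth instance.
#' @param config named list of AMG hyperparameters, carried opaquely.
#' @param iou_threshold matching threshold, see [match_masks()].
#' @param beta F-score weighting, see [f_beta()].
#' @param seed integer seed threaded to the backend.
#' @return list with `per_image_f` (numeric vector, one score per image) and
#'   `mean_f`.
#' @export
evaluate_config <- function(backend, images_with_gt, config,
                            iou_threshold = 0.8, beta = 2, seed = 1L) {
  stopifnot(length(images_with_gt) >= 1)
  per_image <- vapply(images_with_gt, function(scene) {
    gt <- scene$gt
    if (n_instances(gt) == 0) stop("every image must have >= 1 gt instance")
    proposals <- backend(scene$image, config, seed)
    pred <- mask_set(lapply(proposals, as_binary_mask),
                     image_shape = gt$image_shape,
                     image_id = gt$image_id)
    outcome <- match_masks(gt, pred, iou_threshold)
    precision_recall(outcome, beta)$f_score
  }, numeric(1))
  list(per_image_f = per_image, mean_f = mean(per_image))
}

#' Grid search over AMG configurations ranked by mean F-score
#'
#' Expands the grid ([expand_amg_grid()]), evaluates every configuration
#' with [evaluate_config()] and ranks the successful ones by mean F-score,
#' descending, with ties broken by expansion order. A backend failure on a
#' configuration is caught, recorded with the offending configuration, and
#' excluded from the ranking — the search always continues; if every
#' configuration fails the result has an empty ranking and a full failure
#' list rather than signalling an error.
#'
#' @inheritParams evaluate_config
#' @param spec an [amg_grid_spec()].
#' @param seed global seed; every configuration receives a deterministic
#'   sub-seed derived from it.
#' @return an object of class `grid_search_result`: list with `entries`
#'   (data frame: configuration columns, `mean_f`, list-column
#'   `per_image_f`), `failures` (data frame: configuration columns,
#'   `error`), `ranking` (`entries` sorted by `mean_f` descending) and
#'   `grid` (the full expansion).
#' @export
run_grid_search <- function(backend, images_with_gt, spec,
                            iou_threshold = 0.8, beta = 2, seed = 1L) {
  grid <- expand_amg_grid(spec)
  entry_rows <- list(); failure_rows <- list()
  for (k in seq_len(nrow(grid))) {
    config <- amg_config_from_row(grid[k, ])
    sub_seed <- derive_seed(seed, "config", k)
    res <- tryCatch(
      evaluate_config(backend, images_with_gt, config, iou_threshold, beta,
                      seed = sub_seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      row <- grid[k, ]
      row$error <- conditionMessage(res)
      failure_rows[[length(failure_rows) + 1L]] <- row
    } else {
      row <- grid[k, ]
      row$mean_f <- res$mean_f
      row$per_image_f <- list(unname(res$per_image_f))
      entry_rows[[length(entry_rows) + 1L]] <- row
    }
  }
  entries <- do.call(rbind, entry_rows) %||% cbind(grid[0, ], mean_f = numeric(0))
  failures <- do.call(rbind, failure_rows) %||% cbind(grid[0, ], error = character(0))
  rownames(entries) <- NULL; rownames(failures) <- NULL
  ranking <- if (nrow(entries)) {
    entries[order(-entries$mean_f, entries$config_id), , drop = FALSE]
  } else {
    entries
  }
  rownames(ranking) <- NULL
  structure(list(entries = entries, failures = failures, ranking = ranking,
                 grid = grid, iou_threshold = iou_threshold, beta = beta,
                 seed = seed),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d configs: %d ranked, %d failures\n",
              nrow(x$grid), nrow(x$entries), nrow(x$failures)))
  if (nrow(x$ranking)) {
    top <- x$ranking[1, ]
    cat(sprintf("  best mean F%.3g = %.4f (config_id %d)\n",
                x$beta, top$mean_f, top$config_id))
  }
  invisible(x)
}
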