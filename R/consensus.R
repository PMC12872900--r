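#' Per-pixel annotation frequency over repeated annotation rounds
#'
#' For repeated annotations of one image (e.g. several annotators, several
#' methods), computes at every pixel the fraction of rounds in which it was
#' assigned to at least one mask: `f_a_px = n_assigned / n_rounds`.
#' Membership in multiple masks within a single round counts once toward
#' `n_assigned`, which makes the frequency a proper proportion in \[0, 1\];
#' raw within-round multiplicity is available via [overlap_map()].
#'
#' @param rounds list of [mask_set()] objects, one per annotation round, all
#'   sharing `image_shape`.
#' @param image_shape optional `c(height, width)`; inferred from the first
#'   round when omitted.
#' @return an object of class `consensus_map`: list with `n_rounds`,
#'   `n_assigned` (integer matrix), `f_a_px` (numeric matrix) and
#'   `instance_counts_per_round` (masks annotated in each round).
#' @export
annotation_frequency <- function(rounds, image_shape = NULL) {
  stopifnot(length(rounds) >= 1)
  for (r in rounds) stopifnot(inherits(r, "mask_set"))
  image_shape <- as.integer(image_shape %||% rounds[[1]]$image_shape)
  for (r in rounds) {
    if (!identical(r$image_shape, image_shape)) {
      stop("all rounds must share image_shape")
    }
  }
  n_assigned <- matrix(0L, image_shape[1], image_shape[2])
  for (r in rounds) {
    covered <- matrix(FALSE, image_shape[1], image_shape[2])
    for (m in r$instances) covered <- covered | m
    n_assigned <- n_assigned + covered
  }
  structure(
    list(n_rounds = length(rounds), n_assigned = n_assigned,
         f_a_px = n_assigned / length(rounds),
         instance_counts_per_round = vapply(rounds, n_instances, integer(1))),
    class = "consensus_map"
  )
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %d rounds, %d px assigned at least once\n",
              x$n_rounds, sum(x$n_assigned > 0)))
  invisible(x)
}

#' Display filter for consensus maps
#'
#' Retains the annotation frequency only where a pixel was assigned to a
#' mask more than once (`n_assigned >= 2`); elsewhere the value is masked as
#' `NA`. Singly-assigned pixels are typically slips of a single annotator
#' and only clutter a consensus heatmap.
#'
#' @param cmap a `consensus_map` from [annotation_frequency()].
#' @return numeric matrix of `f_a_px` with `NA` at excluded pixels.
#' @export
frequency_display_filter <- function(cmap) {
  stopifnot(inherits(cmap, "consensus_map"))
  out <- cmap$f_a_px
  out[cmap$n_assigned < 2L] <- NA_real_
  out
}

#' Per-pixel overlap count within one mask set
#'
#' Counts, at every pixel, how many instances of the set cover it; pixels
#' covered by two or more masks are flagged (the headless analogue of
#' highlighting unintended overlap during annotation).
#'
#' @param mask_set a [mask_set()].
#' @return an object of class `overlap_map`: list with `counts` (integer
#'   matrix) and `flagged` (logical matrix, `counts >= 2`).
#' @export
overlap_map <- function(mask_set) {
  stopifnot(inherits(mask_set, "mask_set"))
  counts <- matrix(0L, mask_set$image_shape[1], mask_set$image_shape[2])
  for (m in mask_set$instances) counts <- counts + m
  structure(list(counts = counts, flagged = counts >= 2L),
            class = "overlap_map")
}

#' Over-/under-segmentation summary against a reference annotation
#'
#' For each reference instance and each round, the round's best-IoU
#' counterpart mask is compared pixelwise: `over_px` counts reference pixels
#' the counterpart misses (the assigned mask was too small —
#' over-segmentation in the annotation sense), `under_px` counts counterpart
#' pixels spilling beyond the reference onto neighbors (the mask was too
#' large — under-segmentation). Both are averaged over the rounds in which a
#' counterpart with positive IoU exists; rounds without one are skipped and
#' counted.
#'
#' @param rounds list of [mask_set()] annotation rounds.
#' @param reference [mask_set()] with nonempty instances.
#' @return data frame with one row per reference instance: `instance_id`,
#'   `under_px`, `over_px` (means over rounds), `n_rounds_used`,
#'   `n_rounds_skipped`.
#' @export
segmentation_bias_summary <- function(rounds, reference) {
  stopifnot(inherits(reference, "mask_set"), length(rounds) >= 1)
  rows <- lapply(seq_along(reference$instances), function(i) {
    ref <- reference$instances[[i]]
    if (!any(ref)) stop("reference instances must be nonempty")
    under <- numeric(0); over <- numeric(0); skipped <- 0L
    for (r in rounds) {
      if (!identical(r$image_shape, reference$image_shape)) {
        stop("rounds and reference must share image_shape")
      }
      ious <- vapply(r$instances, function(m) as.numeric(iou(ref, m)), numeric(1))
      if (length(ious) == 0 || max(ious) <= 0) {
        skipped <- skipped + 1L
        next
      }
      cp <- r$instances[[which.max(ious)]]
      under <- c(under, sum(cp & !ref))
      over <- c(over, sum(ref & !cp))
    }
    data.frame(instance_id = reference$instance_ids[i],
               under_px = if (length(under)) mean(under) else NA_real_,
               over_px = if (length(over)) mean(over) else NA_real_,
               n_rounds_used = length(under), n_rounds_skipped = skipped)
  })
  do.call(rbind, rows)
}
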