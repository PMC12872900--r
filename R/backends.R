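# Mock and oracle segmentation backends.
#
# These closures satisfy the backend contracts used by the harnesses
# (see amg-harness.R) with fully controllable behavior, standing in for a
# real promptable-segmentation model during tests and simulations.

#' Mock mask-proposal backend with controllable quality
#'
#' Builds a proposal backend (`function(image, config, seed)`) that, for
#' each ground-truth instance of the queried image, emits a morphologically
#' perturbed copy whose IoU with the ground truth lies within ±0.05 of
#' `quality` — pixels are eroded or dilated in order of their signed
#' distance to the mask boundary, with seeded jitter on the order so the
#' boundary is roughened, and the retained pixel count is chosen so the
#' achieved IoU is exact to within one pixel in the area. Instances too
#' small to reach the requested band are emitted unperturbed and logged
#' (see `attr(backend, "log_env")$log`). Additionally `spurious_rate`
#' random blobs disjoint from the ground truth are emitted per image, and
#' each instance is independently omitted with probability `miss_rate`.
#'
#' `quality` and `spurious_rate` may be functions of the AMG configuration
#' (e.g. to plant a known optimum in a hyperparameter for grid-search
#' tests); scalars are used as-is. All draws are deterministic given
#' (`seed`, harness seed, image id, configuration).
#'
#' @param gt_provider `function(image_id) -> mask_set`, e.g.
#'   [scene_gt_provider()].
#' @param quality target IoU in (0, 1\], or `function(config) -> quality`.
#' @param spurious_rate spurious masks per image (count), or
#'   `function(config) -> count`.
#' @param miss_rate probability of dropping each ground-truth instance.
#' @param seed backend-level seed.
#' @return a mask-proposal backend closure.
#' @export
mock_proposal_backend <- function(gt_provider, quality = 1, spurious_rate = 0,
                                  miss_rate = 0, seed = 1L) {
  log_env <- new.env(parent = emptyenv())
  log_env$log <- character(0)
  backend <- function(image, config, seed_in = NULL) {
    gt <- gt_provider(attr(image, "image_id"))
    q <- if (is.function(quality)) quality(config) else quality
    sp <- if (is.function(spurious_rate)) spurious_rate(config) else spurious_rate
    if (q <= 0 || q > 1) stop("quality must lie in (0, 1]")
    run_seed <- derive_seed(seed, seed_in %||% 0L, gt$image_id,
                            paste(unlist(config), collapse = ","))
    with_local_seed(run_seed, {
      proposals <- list()
      for (i in seq_along(gt$instances)) {
        if (stats::runif(1) < miss_rate) next
        pm <- perturb_mask_to_iou(gt$instances[[i]], q)
        if (isTRUE(attr(pm, "unreachable"))) {
          log_env$log <- c(log_env$log, sprintf(
            "%s instance %d: quality %.2f unreachable, emitted unperturbed",
            gt$image_id, gt$instance_ids[i], q))
          attr(pm, "unreachable") <- NULL
        }
        proposals <- c(proposals, list(pm))
      }
      gt_union <- matrix(FALSE, gt$image_shape[1], gt$image_shape[2])
      for (m in gt$instances) gt_union <- gt_union | m
      k <- round(sp)
      placed <- 0L; tries <- 0L
      while (placed < k && tries < 200L * max(k, 1L)) {
        tries <- tries + 1L
        r <- stats::runif(1, 3, 6)
        cx <- stats::runif(1, r + 1, gt$image_shape[2] - 2 - r)
        cy <- stats::runif(1, r + 1, gt$image_shape[1] - 2 - r)
        blob <- ellipse_mask(gt$image_shape, cx, cy, r, 0.8 * r,
                             stats::runif(1, 0, pi))
        if (any(blob & gt_union) || !any(blob)) next
        proposals <- c(proposals, list(blob))
        placed <- placed + 1L
      }
      proposals
    })
  }
  attr(backend, "log_env") <- log_env
  backend
}

# Perturb a mask to a target IoU by eroding (subset: IoU = |M|/|gt|) or
# dilating (superset: IoU = |gt|/|M|), removing/adding pixels in order of
# signed distance to the boundary with seeded jitter. Marks the result
# "unreachable" when the band q +/- 0.05 cannot be hit.
perturb_mask_to_iou <- function(mask, q) {
  if (q >= 1) return(mask)
  area <- sum(mask)
  erode <- stats::runif(1) < 0.5
  if (erode) {
    target <- round(q * area)
    if (target < 1 || abs(target / area - q) > 0.05) {
      return(structure(mask, unreachable = TRUE))
    }
    d <- EBImage::distmap(mask * 1)  # fg distance to background
    idx <- which(mask)
    ord <- order(-(d[idx] + stats::runif(length(idx), 0, 0.45)))
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    out[idx[ord[seq_len(target)]]] <- TRUE
    out
  } else {
    total <- round(area / q)
    extra <- total - area
    d <- EBImage::distmap((!mask) * 1)  # bg distance to foreground
    idx <- which(!mask)
    if (extra < 1 || extra > length(idx) || abs(area / total - q) > 0.05) {
      return(structure(mask, unreachable = TRUE))
    }
    ord <- order(d[idx] + stats::runif(length(idx), 0, 0.45))
    out <- mask
    out[idx[ord[seq_len(extra)]]] <- TRUE
    out
  }
}

#' Oracle promptable segmenter backed by ground truth
#'
#' Builds a promptable segmenter (`function(image, points = NULL,
#' box = NULL)`) that answers from the registered ground truth: for a point
#' prompt it returns the instance containing the point (or the nearest
#' instance if none does); for a box prompt, the instance with maximal
#' pixel intersection with the box, or an empty mask when no instance
#' touches the box.
#'
#' @param gt_provider `function(image_id) -> mask_set`.
#' @return a promptable segmenter closure.
#' @export
oracle_segmenter <- function(gt_provider) {
  function(image, points = NULL, box = NULL) {
    gt <- gt_provider(attr(image, "image_id"))
    empty <- matrix(FALSE, gt$image_shape[1], gt$image_shape[2])
    if (!is.null(box)) {
      bm <- bbox_mask(box, gt$image_shape)
      inter <- vapply(gt$instances, function(m) sum(m & bm), numeric(1))
      if (length(inter) == 0 || max(inter) == 0) return(empty)
      return(gt$instances[[which.max(inter)]])
    }
    if (!is.null(points)) {
      p <- points[[1]]
      r <- p$y + 1L; c <- p$x + 1L
      for (m in gt$instances) if (m[r, c]) return(m)
      if (length(gt$instances) == 0) return(empty)
      dd <- vapply(gt$instances, function(m) {
        idx <- which(m, arr.ind = TRUE)
        min((idx[, 1] - r)^2 + (idx[, 2] - c)^2)
      }, numeric(1))
      return(gt$instances[[which.min(dd)]])
    }
    stop("oracle segmenter needs a point or a box prompt")
  }
}
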