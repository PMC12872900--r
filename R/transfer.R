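#' Project a bounding box through a homography
#'
#' The four corners of the box's continuous envelope are mapped through `H`;
#' the result is the tightest integer pixel box containing the projected
#' corners, clipped to the target frame. Boxes whose projected envelope
#' falls entirely outside the frame — or keeps less than `min_inside` of its
#' area inside — yield a drop signal (`NULL`), not an error, so callers can
#' record the instance as dropped.
#'
#' @param box a [bbox_prompt()] on the source frame.
#' @param hom a `homography_estimate` or a plain 3x3 matrix mapping source
#'   to target pixel coordinates.
#' @param target_shape integer `c(height, width)` of the target frame.
#' @param min_inside minimum fraction of the projected envelope's area that
#'   must remain inside the frame (default 0.25).
#' @return a [bbox_prompt()] on the target frame, or `NULL` (drop signal).
#' @export
project_bbox <- function(box, hom, target_shape, min_inside = 0.25) {
  stopifnot(inherits(box, "bbox_prompt"))
  H <- if (inherits(hom, "homography_estimate")) hom$H else as.matrix(hom)
  h <- as.integer(target_shape[1]); w <- as.integer(target_shape[2])
  # continuous envelope of the half-open pixel box, in pixel-center coords
  corners <- rbind(c(box$x0 - 0.5, box$y0 - 0.5), c(box$x1 - 0.5, box$y0 - 0.5),
                   c(box$x1 - 0.5, box$y1 - 0.5), c(box$x0 - 0.5, box$y1 - 0.5))
  pc <- apply_homography(H, corners)
  if (!all(is.finite(pc))) return(NULL)
  # envelope in pixel-corner coordinates (+0.5), then integer pixel cover
  ex0 <- min(pc[, 1]) + 0.5; ex1 <- max(pc[, 1]) + 0.5
  ey0 <- min(pc[, 2]) + 0.5; ey1 <- max(pc[, 2]) + 0.5
  cx0 <- max(0, ex0); cx1 <- min(w, ex1)
  cy0 <- max(0, ey0); cy1 <- min(h, ey1)
  if (cx0 >= cx1 || cy0 >= cy1) return(NULL)
  frac <- ((cx1 - cx0) * (cy1 - cy0)) / ((ex1 - ex0) * (ey1 - ey0))
  if (frac < min_inside) return(NULL)
  x0 <- floor(cx0); x1 <- ceiling(cx1)
  y0 <- floor(cy0); y1 <- ceiling(cy1)
  if (x0 >= x1 || y0 >= y1) return(NULL)
  bbox_prompt(x0, y0, x1, y1)
}

#' Transfer masks to an overlapping image via box re-prompting
#'
#' Panorama-style annotation transfer: estimate (or accept) the homography
#' from image A to image B, project every source instance's bounding box
#' onto B, and prompt the segmenter with the projected box to re-segment the
#' object on B. Instances whose projection leaves the frame, whose
#' segmentation fails, or whose returned mask is empty are recorded as
#' dropped with a reason; the rest form the transferred mask set with source
#' instance ids preserved. Source instance ids map bijectively onto
#' transferred-plus-dropped.
#'
#' @param source [mask_set()] on image A's frame.
#' @param image_a,image_b the overlapping images.
#' @param segmenter promptable segmenter closure
#'   `function(image, points = NULL, box = NULL)`.
#' @param params forwarded to [estimate_homography()] /
#'   [project_bbox()] (`min_inside`); supply `params$homography` (a 3x3
#'   matrix or `homography_estimate`) to skip estimation, e.g. when the
#'   transform is known.
#' @return an object of class `transfer_report`: list with `transferred`
#'   (mask set on B), `dropped` (data frame `instance_id`, `reason`) and
#'   `homography`.
#' @seealso [score_transfer()]
#' @export
transfer_masks <- function(source, image_a, image_b, segmenter, params = list()) {
  stopifnot(inherits(source, "mask_set"))
  hom <- params$homography %||% estimate_homography(image_a, image_b, params)
  target_shape <- dim(as_gray(image_b))
  min_inside <- params$min_inside %||% 0.25
  kept <- list(); kept_ids <- integer(0); dropped <- list()
  drop_row <- function(id, reason) data.frame(instance_id = id, reason = reason)
  for (i in seq_along(source$instances)) {
    id <- source$instance_ids[i]
    m <- source$instances[[i]]
    if (!any(m)) {
      dropped[[length(dropped) + 1L]] <- drop_row(id, "empty source mask")
      next
    }
    proj <- project_bbox(mask_to_bbox(m), hom, target_shape, min_inside)
    if (is.null(proj)) {
      dropped[[length(dropped) + 1L]] <- drop_row(id, "projected outside target frame")
      next
    }
    pred <- tryCatch(segmenter(image_b, box = proj), error = function(e) e)
    if (inherits(pred, "error")) {
      dropped[[length(dropped) + 1L]] <-
        drop_row(id, paste0("segmenter failure: ", conditionMessage(pred)))
      next
    }
    pred <- as_binary_mask(pred)
    if (!any(pred)) {
      dropped[[length(dropped) + 1L]] <- drop_row(id, "segmenter returned empty mask")
      next
    }
    kept[[length(kept) + 1L]] <- pred
    kept_ids <- c(kept_ids, id)
  }
  structure(
    list(
      transferred = mask_set(kept, image_shape = target_shape,
                             image_id = attr(image_b, "image_id") %||% "",
                             instance_ids = if (length(kept_ids)) kept_ids else NULL),
      dropped = do.call(rbind, dropped) %||%
        data.frame(instance_id = integer(0), reason = character(0)),
      homography = hom),
    class = "transfer_report"
  )
}

#' Score a transfer against reference masks on the target image
#'
#' Transfer quality is judged on the target image only — instances are not
#' tracked back to the source image — by matching the transferred masks to
#' the reference annotation of image B with [match_masks()].
#'
#' @param report a `transfer_report` from [transfer_masks()].
#' @param reference [mask_set()] of reference masks on image B.
#' @param iou_threshold matching threshold, see [match_masks()].
#' @return a `match_outcome`.
#' @export
score_transfer <- function(report, reference, iou_threshold = 0.8) {
  stopifnot(inherits(report, "transfer_report"))
  match_masks(reference, report$transferred, iou_threshold)
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("<transfer_report> transferred=%d dropped=%d\n",
              n_instances(x$transferred), nrow(x$dropped)))
  invisible(x)
}
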