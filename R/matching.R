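#' Ground-truth-level one-to-many mask matching
#'
#' Matches predicted masks to ground-truth masks for annotation-oriented
#' evaluation. Unlike conventional one-to-one assignment, the rule here is
#' existential and applied per ground-truth instance: a ground-truth mask is
#' a true positive iff at least one predicted mask has IoU strictly greater
#' than `iou_threshold` with it (otherwise a false negative), and a predicted
#' mask is a false positive iff it exceeds the threshold with no ground-truth
#' mask. A single predicted mask may certify several ground-truth instances
#' (e.g. stacked occluded objects), so `tp` can exceed the number of distinct
#' predictions involved; duplicate predictions never change the counts. Each
#' predicted mask contributes at most one false positive regardless of how
#' many ground-truth masks it misses.
#'
#' A bounding-box prefilter skips pixel counting for pairs whose boxes do not
#' intersect (their IoU is exactly 0); results are identical to the naive
#' double loop.
#'
#' @param gt,pred [mask_set()] objects sharing `image_shape`.
#' @param iou_threshold matching threshold in (0, 1); the comparison is
#'   strict (`>`) unless `strict = FALSE` requests `>=` semantics.
#' @param strict logical; compare IoU with `>` (default) or `>=`.
#' @return an object of class `match_outcome`: list with `iou_threshold`,
#'   counts `tp`, `fp`, `fn`, a `per_gt` data frame (`gt_id`, `best_iou`,
#'   list-column `matched_pred_ids`) and `unmatched_pred_ids`.
#' @seealso [precision_recall()]
#' @export
match_masks <- function(gt, pred, iou_threshold = 0.8, strict = TRUE) {
  stopifnot(inherits(gt, "mask_set"), inherits(pred, "mask_set"))
  if (!identical(gt$image_shape, pred$image_shape)) {
    stop("gt and pred must share image_shape")
  }
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must lie in (0, 1)")
  }
  exceeds <- if (strict) function(v) v > iou_threshold else function(v) v >= iou_threshold
  n_gt <- length(gt$instances); n_pred <- length(pred$instances)
  gt_boxes <- lapply(gt$instances, mask_extent)
  pred_boxes <- lapply(pred$instances, mask_extent)
  iou_mat <- matrix(0, n_gt, n_pred)
  for (i in seq_len(n_gt)) {
    for (j in seq_len(n_pred)) {
      if (boxes_intersect(gt_boxes[[i]], pred_boxes[[j]])) {
        iou_mat[i, j] <- as.numeric(iou(gt$instances[[i]], pred$instances[[j]]))
      }
    }
  }
  matched_per_gt <- lapply(seq_len(n_gt), function(i) {
    pred$instance_ids[exceeds(iou_mat[i, ])]
  })
  gt_hit <- vapply(matched_per_gt, function(ids) length(ids) > 0, logical(1))
  pred_hit <- if (n_pred > 0 && n_gt > 0) {
    apply(iou_mat, 2, function(col) any(exceeds(col)))
  } else {
    rep(FALSE, n_pred)
  }
  per_gt <- data.frame(
    gt_id = gt$instance_ids %||% integer(0),
    best_iou = if (n_pred > 0 && n_gt > 0) apply(iou_mat, 1, max) else rep(0, n_gt)
  )
  per_gt$matched_pred_ids <- matched_per_gt
  structure(
    list(iou_threshold = iou_threshold,
         tp = sum(gt_hit), fp = sum(!pred_hit), fn = sum(!gt_hit),
         per_gt = per_gt,
         unmatched_pred_ids = pred$instance_ids[!pred_hit]),
    class = "match_outcome"
  )
}

# half-open pixel extent [x0, x1) x [y0, y1); NULL for an empty mask
mask_extent <- function(m) {
  rs <- which(rowSums(m) > 0)
  if (length(rs) == 0) return(NULL)
  cs <- which(colSums(m) > 0)
  c(x0 = cs[1] - 1L, y0 = rs[1] - 1L, x1 = cs[length(cs)], y1 = rs[length(rs)])
}

boxes_intersect <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  a["x0"] < b["x1"] && b["x0"] < a["x1"] && a["y0"] < b["y1"] && b["y0"] < a["y1"]
}

#' @export
print.match_outcome <- function(x, ...) {
  cat(sprintf("<match_outcome> IoU > %.2f: TP=%d FP=%d FN=%d\n",
              x$iou_threshold, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F-beta from a match outcome
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`. A degenerate ratio (zero
#' denominator) is reported as 0 and flagged in the `degenerate` field rather
#' than returned as `NaN`.
#'
#' @param outcome a `match_outcome` from [match_masks()].
#' @param beta positive real passed to [f_beta()].
#' @return an object of class `prf`: list with `precision`, `recall`, `beta`,
#'   `f_score` and a named logical vector `degenerate`.
#' @export
precision_recall <- function(outcome, beta = 2) {
  stopifnot(inherits(outcome, "match_outcome"))
  p_den <- outcome$tp + outcome$fp
  r_den <- outcome$tp + outcome$fn
  precision <- if (p_den == 0) 0 else outcome$tp / p_den
  recall <- if (r_den == 0) 0 else outcome$tp / r_den
  structure(
    list(precision = precision, recall = recall, beta = beta,
         f_score = f_beta(precision, recall, beta),
         degenerate = c(precision = p_den == 0, recall = r_den == 0)),
    class = "prf"
  )
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("<prf> P=%.4f R=%.4f F%.3g=%.4f\n",
              x$precision, x$recall, x$beta, x$f_score))
  invisible(x)
}
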