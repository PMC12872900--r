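#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the union is
#' empty and the ratio is undefined; the function then returns 0 carrying a
#' `degenerate = TRUE` attribute so batch pipelines never propagate `NaN`.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return numeric scalar in \[0, 1\] with attribute `degenerate`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' iou(a, a)
#' @export
iou <- function(mask_a, mask_b) {
  mask_a <- as_binary_mask(mask_a); mask_b <- as_binary_mask(mask_b)
  check_same_shape(mask_a, mask_b)
  uni <- sum(mask_a | mask_b)
  if (uni == 0) return(structure(0, degenerate = TRUE))
  structure(sum(mask_a & mask_b) / uni, degenerate = FALSE)
}

#' Two-class generalized Dice score
#'
#' Class-weighted Dice overlap between a predicted mask and a ground-truth
#' mask over the two classes object/background, with per-class weight
#' `w_l = 1 / (ground-truth pixel count of class l)^2`. The inverse-square
#' weighting compensates the size imbalance between small object instances
#' and the large background, so a perfect background match alone cannot
#' dominate the score. A class with zero ground-truth pixels has an infinite
#' weight and is dropped from numerator and denominator (equivalent to
#' weight 0), which keeps the score finite and preserves a score of 1 for
#' perfect predictions.
#'
#' @param gt,pred logical matrices of identical shape; `gt` is the reference.
#' @return an object of class `dice_evaluation`: list with `gds` (score in
#'   \[0, 1\]) and `class_weights` (named vector, possibly infinite for an
#'   empty class).
#' @examples
#' gt <- matrix(FALSE, 4, 4); gt[1:2, 1:2] <- TRUE
#' pr <- matrix(FALSE, 4, 4); pr[2:3, 1:2] <- TRUE
#' generalized_dice(gt, pr)$gds
#' @export
generalized_dice <- function(gt, pred) {
  gt <- as_binary_mask(gt); pred <- as_binary_mask(pred)
  check_same_shape(gt, pred)
  num <- 0; den <- 0
  weights <- c(object = NA_real_, background = NA_real_)
  for (cls in c("object", "background")) {
    g <- if (cls == "object") gt else !gt
    p <- if (cls == "object") pred else !pred
    n_gt <- sum(g)
    w <- 1 / n_gt^2  # Inf when the class has no ground-truth pixels
    weights[cls] <- w
    if (!is.finite(w)) next  # empty class: dropped from both sums
    num <- num + w * sum(p & g)
    den <- den + w * (sum(p) + sum(g))
  }
  if (den == 0) stop("ground truth has zero pixels in both classes")
  structure(list(gds = 2 * num / den, class_weights = weights),
            class = "dice_evaluation")
}

#' @export
print.dice_evaluation <- function(x, ...) {
  cat(sprintf("<dice_evaluation> GDS = %.4f\n", x$gds))
  invisible(x)
}

#' F-beta score from precision and recall
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, defined as 0 when the
#' denominator vanishes. `beta = 2` weights recall `beta^2 = 4` times as
#' heavily as precision — the weighting used when over-proposing masks is
#' cheaper for an annotator than drawing missed ones by hand.
#'
#' @param precision,recall ratios in \[0, 1\].
#' @param beta positive real.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' f_beta(0.5, 1.0, 2)  # 2.5 / 3
#' @export
f_beta <- function(precision, recall, beta = 2) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a positive number")
  }
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  den <- beta^2 * precision + recall
  if (den == 0) return(0)
  (1 + beta^2) * precision * recall / den
}
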