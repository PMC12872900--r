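#' Geometric-median point prompt of a mask
#'
#' Returns a positive point prompt at the geometric median of the
#' foreground pixels — the point minimizing the summed Euclidean distance to
#' all foreground pixel centers. The continuous optimum is found by
#' Weiszfeld iteration with the Vardi-Zhang correction (which handles
#' iterates landing exactly on a data point), then snapped onto the mask by
#' taking the foreground pixel with the smallest summed-distance objective,
#' so the prompt always lies on the object — for ring-like or non-convex
#' masks the unconstrained median can fall in a hole, which would prompt
#' the background, and for L-shaped masks the pixel nearest the continuous
#' optimum need not be the best on-mask pixel. Snapping ties are broken in
#' row-major order (smallest y, then smallest x).
#'
#' Iteration stops when the iterate moves less than `1e-6` px or after 1000
#' iterations; sub-pixel accuracy suffices because the result is snapped to
#' a pixel.
#'
#' @param mask nonempty logical matrix.
#' @return an object of class `point_prompt`: list with integer `x`, `y`
#'   (0-based pixel coordinates) and `polarity = "positive"`.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' geometric_median_prompt(m)
#' @export
geometric_median_prompt <- function(mask) {
  mask <- as_binary_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot prompt an empty mask")
  # foreground pixel centers in (x, y)
  pts <- cbind(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5)
  med <- weiszfeld_median(pts)
  # snap: argmin of the summed-distance objective over foreground pixels.
  # On very large masks only the pixels closest to the continuous optimum
  # are considered (the optimum cannot snap far away).
  n <- nrow(pts)
  cand <- seq_len(n)
  if (n > 2048) {
    d2 <- (pts[, 1] - med[1])^2 + (pts[, 2] - med[2])^2
    cand <- order(d2)[seq_len(256)]
  }
  obj <- vapply(cand, function(k) {
    sum(sqrt((pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2))
  }, numeric(1))
  cand <- cand[obj <= min(obj) + 1e-9]
  if (length(cand) > 1) {  # row-major tie-break
    ord <- order(idx[cand, 1], idx[cand, 2])
    cand <- cand[ord[1]]
  }
  structure(
    list(x = as.integer(idx[cand, 2] - 1L), y = as.integer(idx[cand, 1] - 1L),
         polarity = "positive"),
    class = "point_prompt"
  )
}

# Weiszfeld iteration with the Vardi-Zhang step for iterates that coincide
# with a data point. pts: n x 2 matrix. Returns the continuous optimum.
weiszfeld_median <- function(pts, tol = 1e-6, max_iter = 1000) {
  if (nrow(pts) == 1) return(pts[1, ])
  y <- colMeans(pts)
  for (iter in seq_len(max_iter)) {
    d <- sqrt((pts[, 1] - y[1])^2 + (pts[, 2] - y[2])^2)
    on_pt <- d < 1e-12
    if (any(on_pt)) {
      if (all(on_pt)) break
      inv <- 1 / d[!on_pt]
      tt <- c(sum(pts[!on_pt, 1] * inv), sum(pts[!on_pt, 2] * inv)) / sum(inv)
      rvec <- c(sum((pts[!on_pt, 1] - y[1]) * inv),
                sum((pts[!on_pt, 2] - y[2]) * inv))
      rnorm <- sqrt(sum(rvec^2))
      eta <- sum(on_pt)  # multiplicity of the coincident data point
      if (rnorm <= eta) break  # the data point itself is the median
      gamma <- min(1, eta / rnorm)
      y_new <- (1 - gamma) * tt + gamma * y
    } else {
      inv <- 1 / d
      y_new <- c(sum(pts[, 1] * inv), sum(pts[, 2] * inv)) / sum(inv)
    }
    if (sqrt(sum((y_new - y)^2)) < tol) {
      y <- y_new
      break
    }
    y <- y_new
  }
  y
}

#' @export
print.point_prompt <- function(x, ...) {
  cat(sprintf("<point_prompt> (%d, %d) %s\n", x$x, x$y, x$polarity))
  invisible(x)
}

#' Tight bounding box of a mask
#'
#' The smallest half-open axis-aligned box `[x0, x1) x [y0, y1)` (0-based
#' pixel coordinates) containing all foreground pixels.
#'
#' @param mask nonempty logical matrix.
#' @return an object of class `bbox_prompt`: list with `x0`, `y0`, `x1`, `y1`.
#' @export
mask_to_bbox <- function(mask) {
  mask <- as_binary_mask(mask)
  ext <- mask_extent(mask)
  if (is.null(ext)) stop("cannot take the bounding box of an empty mask")
  bbox_prompt(ext["x0"], ext["y0"], ext["x1"], ext["y1"])
}

#' @rdname mask_to_bbox
#' @param x0,y0,x1,y1 box coordinates with `x0 < x1`, `y0 < y1`.
#' @export
bbox_prompt <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x0 >= x1 || y0 >= y1) stop("bbox requires x0 < x1 and y0 < y1")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "bbox_prompt")
}

#' @export
print.bbox_prompt <- function(x, ...) {
  cat(sprintf("<bbox_prompt> [%d,%d) x [%d,%d)\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

# logical mask of a bbox_prompt on a given frame
bbox_mask <- function(box, image_shape) {
  m <- matrix(FALSE, image_shape[1], image_shape[2])
  ys <- seq.int(max(box$y0, 0) + 1L, min(box$y1, image_shape[1]))
  xs <- seq.int(max(box$x0, 0) + 1L, min(box$x1, image_shape[2]))
  if (length(ys) > 0 && length(xs) > 0) m[ys, xs] <- TRUE
  m
}
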