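#' Rasterize a polygon into a binary mask
#'
#' Vertices are continuous 0-based image coordinates (`x` = column, `y` =
#' row, origin at the top-left pixel corner); the polygon is implicitly
#' closed. Pixel `(x, y)` spans the unit square `[x, x+1) x [y, y+1)` and is
#' set to foreground iff its center `(x + 0.5, y + 0.5)` lies inside the
#' polygon under the even-odd rule, with centers landing exactly on the
#' boundary counted as inside.
#'
#' @param vertices an `n x 2` matrix (columns `x`, `y`) with `n >= 3`, or a
#'   flat numeric vector `c(x1, y1, x2, y2, ...)` as found in COCO polygon
#'   segmentations.
#' @param image_shape integer `c(height, width)`.
#' @return logical matrix of dimension `image_shape`.
#' @examples
#' m <- rasterize_polygon(rbind(c(1, 1), c(5, 1), c(5, 4), c(1, 4)), c(6, 8))
#' sum(m)  # 4 x 3 pixel rectangle
#' @export
rasterize_polygon <- function(vertices, image_shape) {
  if (is.numeric(vertices) && is.null(dim(vertices))) {
    if (length(vertices) %% 2 != 0) stop("flat vertex vector must have even length")
    vertices <- matrix(vertices, ncol = 2, byrow = TRUE)
  }
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("a polygon needs at least 3 (x, y) vertices")
  }
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  mask <- matrix(FALSE, h, w)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  # candidate pixels: bounding box of the polygon, clipped to the frame
  cx0 <- max(0L, floor(min(xs) - 0.5)); cx1 <- min(w - 1L, ceiling(max(xs)))
  cy0 <- max(0L, floor(min(ys) - 0.5)); cy1 <- min(h - 1L, ceiling(max(ys)))
  if (cx0 > cx1 || cy0 > cy1) return(mask)
  px <- seq.int(cx0, cx1); py <- seq.int(cy0, cy1)
  grid <- expand.grid(x = px, y = py)
  inside <- pracma::inpolygon(grid$x + 0.5, grid$y + 0.5, xs, ys,
                              boundary = TRUE)
  mask[cbind(grid$y + 1L, grid$x + 1L)] <- inside
  mask
}
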