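#' @useDynLib maskwork, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library internals never perturb user randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed from a base seed and arbitrary key strings.
# Keeps every derived seed well below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  h <- 5381
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2147483647
  as.integer(h)
}

stop_stage <- function(stage, msg, class = "maskwork_error") {
  stop(structure(
    class = c(paste0("maskwork_", stage, "_error"), class, "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1))
  ))
}

#' Convert an image to a grayscale matrix
#'
#' Accepts an `height x width` numeric matrix or an `height x width x 3` array
#' (channels averaged). Values are used as-is; callers should supply data in
#' \[0, 1\].
#'
#' @param image matrix or 3-d array.
#' @return numeric matrix (rows = image rows).
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    return((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
  }
  stop("image must be a matrix or an h x w x 3 array")
}

# Vectorized bilinear sampling of a matrix in pixel-center coordinates:
# continuous (x, y) with integer positions at pixel centers, x = column - 1,
# y = row - 1. Coordinates outside the frame are clamped to the border.
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(r, c) m[cbind(r + 1, c + 1)]
  v00 <- idx(y0, x0); v01 <- idx(y0, x1)
  v10 <- idx(y1, x0); v11 <- idx(y1, x1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
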