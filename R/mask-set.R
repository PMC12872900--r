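#' Binary masks and instance mask sets
#'
#' A binary mask is a plain logical matrix: `mask[r, c]` is `TRUE` where pixel
#' `(x = c - 1, y = r - 1)` belongs to the object (0-based pixel coordinates,
#' x = column, y = row, origin at the top-left). A `mask_set` bundles the
#' per-instance masks of one image; instances may overlap (overlap is
#' measured, never forbidden), and every member mask shares the image shape.
#'
#' @param instances list of logical matrices, one per object instance.
#' @param image_shape integer `c(height, width)`; inferred from the first
#'   instance when omitted.
#' @param image_id character identifier of the image.
#' @param instance_ids positive integer ids, unique within the set; defaults
#'   to `seq_along(instances)`.
#' @return An object of class `mask_set` with fields `image_id`,
#'   `image_shape`, `instance_ids` and `instances`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
#' ms <- mask_set(list(m), image_id = "demo")
#' n_instances(ms)
#' @export
mask_set <- function(instances = list(), image_shape = NULL, image_id = "",
                     instance_ids = NULL) {
  if (!is.list(instances)) stop("instances must be a list of logical matrices")
  instances <- lapply(instances, as_binary_mask)
  if (is.null(image_shape)) {
    if (length(instances) == 0) {
      stop("image_shape is required for an empty mask_set")
    }
    image_shape <- dim(instances[[1]])
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop("image_shape must be c(height, width)")
  }
  for (m in instances) {
    if (!identical(dim(m), image_shape)) {
      stop("all instance masks must share image_shape")
    }
  }
  if (is.null(instance_ids)) instance_ids <- seq_along(instances)
  instance_ids <- as.integer(instance_ids)
  if (length(instance_ids) != length(instances)) {
    stop("instance_ids must match the number of instances")
  }
  if (anyDuplicated(instance_ids) || any(instance_ids < 1L)) {
    stop("instance_ids must be unique positive integers")
  }
  structure(
    list(image_id = as.character(image_id), image_shape = image_shape,
         instance_ids = instance_ids, instances = instances),
    class = "mask_set"
  )
}

as_binary_mask <- function(m) {
  if (is.matrix(m) && is.logical(m)) {
    if (anyNA(m)) stop("mask must not contain NA")
    return(m)
  }
  if (is.matrix(m) && is.numeric(m)) {
    if (anyNA(m)) stop("mask must not contain NA")
    return(m != 0)
  }
  stop("a binary mask must be a logical (or 0/1 numeric) matrix")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("masks must share the same shape (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")")
  }
  invisible(TRUE)
}

#' @rdname mask_set
#' @param x a `mask_set`.
#' @export
n_instances <- function(x) {
  stopifnot(inherits(x, "mask_set"))
  length(x$instances)
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> image_id='%s' shape=%dx%d instances=%d\n",
              x$image_id, x$image_shape[1], x$image_shape[2],
              length(x$instances)))
  invisible(x)
}

#' Look up one instance mask by id
#'
#' @param x a `mask_set`.
#' @param id instance id.
#' @return logical matrix.
#' @export
get_instance <- function(x, id) {
  stopifnot(inherits(x, "mask_set"))
  i <- match(as.integer(id), x$instance_ids)
  if (is.na(i)) stop("no instance with id ", id)
  x$instances[[i]]
}
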