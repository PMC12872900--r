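#' Read a COCO-style annotation file into a mask set
#'
#' Supports polygon segmentations (lists of flat `x1,y1,x2,y2,...` rings,
#' rasterized with [rasterize_polygon()]) and uncompressed RLE segmentations
#' (`counts` as an integer array in column-major order starting with a
#' background run). Compressed (string-encoded) RLE is rejected with a format
#' error naming the encoding. One file describes one image; RLE interchange
#' is lossless for overlapping instances.
#'
#' @param path path to a COCO-style JSON file.
#' @return a [mask_set()]; instance ids are the annotation ids.
#' @seealso [write_coco()]
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop_stage("io", paste0("file not found: ", path))
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  imgs <- js$images %||% list()
  if (length(imgs) == 0) stop_stage("format", "COCO file lists no images")
  if (length(imgs) > 1) {
    stop_stage("format", "COCO file lists multiple images; one mask_set per file")
  }
  info <- imgs[[1]]
  shape <- c(as.integer(info$height), as.integer(info$width))
  anns <- js$annotations %||% list()
  instances <- list(); ids <- integer(0)
  for (k in seq_along(anns)) {
    ann <- anns[[k]]
    seg <- ann$segmentation
    if (is.null(seg)) next
    if (!is.null(seg$counts)) {
      if (is.character(seg$counts)) {
        stop_stage("format",
                   "compressed (string) RLE segmentation is not supported; use uncompressed integer counts")
      }
      m <- rle_decode(unlist(seg$counts), shape)
    } else if (is.list(seg)) {
      m <- matrix(FALSE, shape[1], shape[2])
      for (ring in seg) {
        m <- m | rasterize_polygon(unlist(ring), shape)
      }
    } else {
      stop_stage("format", paste0("unsupported segmentation encoding of class ",
                                  class(seg)[1]))
    }
    instances <- c(instances, list(m))
    ids <- c(ids, as.integer(ann$id %||% k))
  }
  mask_set(instances, image_shape = shape,
           image_id = as.character(info$file_name %||% info$id %||% ""),
           instance_ids = if (length(ids)) ids else NULL)
}

#' Write a mask set as COCO-style JSON with uncompressed RLE
#'
#' Every instance is stored as an uncompressed run-length encoding, which
#' round-trips bit-exactly through [read_coco()] even for overlapping
#' instances.
#'
#' @param mask_set a [mask_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(mask_set, path) {
  stopifnot(inherits(mask_set, "mask_set"))
  shape <- mask_set$image_shape
  anns <- lapply(seq_along(mask_set$instances), function(i) {
    m <- mask_set$instances[[i]]
    bb <- if (any(m)) {
      rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
      c(cols[1] - 1L, rows[1] - 1L, cols[2] - cols[1] + 1L, rows[2] - rows[1] + 1L)
    } else {
      c(0L, 0L, 0L, 0L)
    }
    list(id = mask_set$instance_ids[i], image_id = 1L, category_id = 1L,
         segmentation = list(counts = I(rle_encode(m)), size = I(shape)),
         area = sum(m), bbox = I(bb), iscrowd = 0L)
  })
  js <- list(
    images = list(list(id = 1L, file_name = mask_set$image_id,
                       height = shape[1], width = shape[2])),
    annotations = anns,
    categories = list(list(id = 1L, name = "object"))
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Uncompressed COCO run-length encoding of a binary mask
#'
#' Runs are counted down columns (column-major order) and alternate
#' background/foreground, always starting with a (possibly zero-length)
#' background run — the uncompressed layout of COCO's RLE segmentations.
#'
#' @param mask logical matrix.
#' @return integer vector of run lengths.
#' @export
rle_encode <- function(mask) {
  mask <- as_binary_mask(mask)
  r <- rle(as.integer(mask))
  counts <- r$lengths
  if (length(counts) && r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

#' @rdname rle_encode
#' @param counts integer run lengths as produced by [rle_encode()].
#' @param image_shape integer `c(height, width)`.
#' @export
rle_decode <- function(counts, image_shape) {
  counts <- as.integer(counts)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (sum(counts) != h * w) {
    stop_stage("format", sprintf("RLE counts sum to %d but image has %d pixels",
                                 sum(counts), h * w))
  }
  vals <- rep(rep_len(c(FALSE, TRUE), length(counts)), counts)
  matrix(vals, h, w)
}
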