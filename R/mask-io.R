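#' Read an instance label map from a 16-bit PNG
#'
#' The file must be a single-channel integer PNG where value 0 marks
#' background and every distinct value `k > 0` marks instance `k`. Label PNGs
#' cannot represent overlapping instances; use COCO JSON
#' ([read_coco()]/[write_coco()]) for lossless interchange of overlapping
#' mask sets.
#'
#' @param path path to a grayscale PNG (bit depth up to 16).
#' @return a [mask_set()] with one instance per distinct nonzero label value;
#'   instance ids equal the label values.
#' @seealso [write_label_png()]
#' @export
read_label_png <- function(path) {
  if (!file.exists(path)) stop_stage("io", paste0("file not found: ", path))
  hdr <- png_header(path)
  if (hdr$color_type != 0L) {
    stop_stage("format", sprintf(
      "label PNG must be single-channel grayscale (color type 0), got color type %d in '%s'",
      hdr$color_type, path))
  }
  img <- png::readPNG(path)
  if (!is.matrix(img)) {
    stop_stage("format", paste0("label PNG decoded to multiple channels: ", path))
  }
  scale <- 2^hdr$bit_depth - 1
  lab <- matrix(as.integer(round(img * scale)), nrow(img), ncol(img))
  ids <- sort(unique(lab[lab > 0L]))
  instances <- lapply(ids, function(k) lab == k)
  mask_set(instances, image_shape = dim(lab),
           image_id = tools::file_path_sans_ext(basename(path)),
           instance_ids = if (length(ids)) ids else NULL)
}

#' Write an instance label map as a 16-bit PNG
#'
#' Bit-exact inverse of [read_label_png()] for mask sets without overlapping
#' instances. Overlap cannot be stored in a single-channel label map, so
#' overlapping sets are rejected rather than silently flattened.
#'
#' @param mask_set a [mask_set()] with pairwise-disjoint instances and ids
#'   below 65536.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(mask_set, path) {
  stopifnot(inherits(mask_set, "mask_set"))
  if (length(mask_set$instance_ids) &&
      max(mask_set$instance_ids) > 65535L) {
    stop_stage("format", "label PNG stores 16-bit ids; instance ids must be <= 65535")
  }
  lab <- matrix(0L, mask_set$image_shape[1], mask_set$image_shape[2])
  covered <- matrix(FALSE, mask_set$image_shape[1], mask_set$image_shape[2])
  for (i in seq_along(mask_set$instances)) {
    m <- mask_set$instances[[i]]
    if (any(covered & m)) {
      stop_stage("format", paste0(
        "mask set contains overlapping instances, which a label PNG cannot ",
        "represent; write COCO JSON (write_coco) instead"))
    }
    covered <- covered | m
    lab[m] <- mask_set$instance_ids[i]
  }
  write_png16_gray(lab, path)
}
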