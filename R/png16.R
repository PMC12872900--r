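# Minimal 16-bit grayscale PNG encoder.
#
# The CRAN `png` package reads 16-bit PNGs but only writes 8-bit ones, and
# EBImage's bits.per.sample applies to TIFF only, so the 16-bit label-map
# interchange format is encoded here directly: one IHDR/IDAT/IEND chunk
# sequence, scanlines filtered with the null filter, zlib stream produced by
# memCompress() (which emits RFC 1950 zlib framing), CRC32 via the compiled
# kernel in src/.

png_u32be <- function(n) {
  n <- as.numeric(n)
  as.raw(c(n %/% 16777216, (n %/% 65536) %% 256, (n %/% 256) %% 256, n %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png_u32be(length(data)), body, png_u32be(.crc32_raw(body)))
}

# lab: integer matrix (rows = image rows), values in [0, 65535]
write_png16_gray <- function(lab, path) {
  h <- nrow(lab); w <- ncol(lab)
  tl <- t(lab)  # w x h; each column is one scanline
  bytes <- matrix(0L, nrow = 2L * w + 1L, ncol = h)
  bytes[2L * seq_len(w), ] <- tl %/% 256L
  bytes[2L * seq_len(w) + 1L, ] <- tl %% 256L
  scanlines <- as.raw(bytes)  # column-major: filter byte then big-endian u16s
  ihdr <- c(png_u32be(w), png_u32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate, none
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scanlines, "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# Parse width/height/bit depth/color type from a PNG's IHDR.
png_header <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  magic <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(hdr) < 26L || !identical(hdr[1:8], magic)) {
    stop_stage("format", paste0("'", path, "' is not a PNG file"))
  }
  u32 <- function(b) sum(as.numeric(b) * c(16777216, 65536, 256, 1))
  list(width = u32(hdr[17:20]), height = u32(hdr[21:24]),
       bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}
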