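#' Read a 16-bit grayscale PNG depth image
#'
#' Depth images are stored as single-channel 16-bit PNGs whose pixel value
#' is the depth in millimeters; 0 encodes an unmeasured pixel.
#'
#' @param path Path to the PNG file.
#' @return An integer-valued numeric matrix (rows = image rows) in mm.
#' @seealso [write_depth_png()]
#' @export
read_depth_png <- function(path) {
  if (!file.exists(path)) stop("depth image not found: ", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] < 1L) stop("empty PNG: ", path)
    img <- img[, , 1L]
  }
  # readPNG scales both 8- and 16-bit samples to [0, 1]
  scale <- if (!is.null(info$bit.depth) && info$bit.depth == 8) 255 else 65535
  out <- round(img * scale)
  attributes(out) <- list(dim = dim(out))
  out
}

#' Write a depth image as a 16-bit grayscale PNG
#'
#' Values are written verbatim as 16-bit samples (depth in mm, 0 =
#' unmeasured), so the round trip through [read_depth_png()] is lossless
#' for integer depths in `[0, 65535]`.
#'
#' @param depth Numeric matrix of depths in mm; values are rounded to
#'   integers and must fall in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  if (!is.matrix(depth)) stop("'depth' must be a matrix")
  v <- round(depth)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 65535))
    stop("depth values must be finite and in [0, 65535] mm")
  writeLines_png16(v, path)
  invisible(path)
}

#' Read a directory of numbered depth PNGs as a frame stack
#'
#' @param dir Directory containing the frames as 16-bit PNGs; files are
#'   ordered by name.
#' @param pattern Regular expression selecting the frame files.
#' @return A list of depth matrices (the frame stack).
#' @export
read_depth_stack <- function(dir, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no depth frames found in ", dir)
  frames <- lapply(files, read_depth_png)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("depth frames differ in dimensions")
  frames
}

#' @param frames List of depth matrices.
#' @param prefix Filename prefix for the numbered frames.
#' @rdname read_depth_stack
#' @export
write_depth_stack <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) write_depth_png(frames[[i]], paths[i])
  invisible(paths)
}

## ---- minimal 16-bit grayscale PNG encoder ---------------------------------
## The png package reads 16-bit PNGs but writes only 8-bit samples, which
## would truncate millimeter depths. A PNG file is a signature plus CRC-tagged
## chunks; the IDAT payload is a zlib stream, which memCompress() produces
## directly, and the chunk CRC-32 comes from zlib via the compiled shim.

png_crc32 <- function(bytes) {
  .Call(C_crc32, bytes)
}

png_uint32 <- function(x) {
  # big-endian 4-byte encoding; x may exceed .Machine$integer.max (CRCs)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(png_uint32(length(data)), body, png_uint32(png_crc32(body)))
}

writeLines_png16 <- function(v, path) {
  h <- nrow(v); w <- ncol(v)
  pix <- as.integer(t(v))               # row-major pixel order
  bytes <- matrix(as.raw(rbind(pix %/% 256L, pix %% 256L)), nrow = 2L * w)
  scanlines <- as.vector(rbind(as.raw(0L), bytes))  # filter byte 0 per row
  ihdr <- c(png_uint32(w), png_uint32(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scanlines, "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
}
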