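# File formats: 16-bit grayscale depth PNG, headerless binary depth grids,
# camera intrinsics JSON, ASCII PLY point clouds, mask PNGs and plain-text
# bounding-box annotations.
#
# PNG reading goes through png::readPNG, which decodes 16-bit grayscale; the
# stored bit depth is sniffed from the IHDR so 8-bit masks and 16-bit depth
# rescale correctly. png::writePNG only emits 8-bit channels, so 16-bit depth
# output is written by a minimal PNG encoder (IHDR/IDAT/IEND chunks, zlib
# stream via memCompress, CRC-32 below).

.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(cc, 1L))  # 0xEDB88320, logical shift
      else bitwShiftR(cc, 1L)
    }
    tab[i + 1] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  tab <- .crc32_table
  for (i in seq_along(b))
    cc <- bitwXor(tab[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L], bitwShiftR(cc, 8L))
  bitwXor(cc, -1L)
}

.u32be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

.png_chunk <- function(type, data) {
  tb <- charToRaw(type)
  c(.u32be(length(data)), tb, data, .u32be(.crc32(c(tb, data))))
}

.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 32)
  if (length(hdr) < 25 || !identical(as.integer(hdr[1:4]), c(137L, 80L, 78L, 71L)))
    hc_stop(sprintf("'%s' is not a PNG file", path))
  as.integer(hdr[25])
}

#' Write a depth image as 16-bit grayscale PNG
#'
#' One grey level = 1 mm; depths are rounded to integer millimetres and
#' clamped to the 16-bit range. Missing pixels are stored as 0.
#'
#' @param depth An [depth_image()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  stopifnot(inherits(depth, "hc_depth"))
  img <- round(depth$values)
  img[depth$values == depth$missing_value] <- 0
  img[img < 0] <- 0; img[img > 65535] <- 65535
  storage.mode(img) <- "integer"
  h <- nrow(img); w <- ncol(img)
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  m <- t(img)                                   # scanlines are image rows
  sc <- array(as.raw(0), c(2L * w + 1L, h))     # filter byte 0 per scanline
  sc[seq(2L, 2L * w, 2L), ] <- as.raw(m %/% 256L)
  sc[seq(3L, 2L * w + 1L, 2L), ] <- as.raw(m %% 256L)
  idat <- memCompress(as.raw(sc), "gzip")       # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr), .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Read a depth image from PNG
#'
#' Accepts 16-bit (1 grey level = 1 mm) or 8-bit grayscale PNG; the stored
#' bit depth is detected from the file header.
#'
#' @param path PNG file path.
#' @return An [depth_image()] object.
#' @export
read_depth_png <- function(path) {
  bits <- .png_bit_depth(path)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  depth_image(round(v * (2^bits - 1)))
}

#' Read a headerless binary depth grid
#'
#' Raw little-endian 16-bit unsigned grid, row-major, 1 unit = 1 mm;
#' dimensions come from the caller (typically a camera intrinsics config).
#'
#' @param path File path.
#' @param width,height Grid dimensions in pixels.
#' @param endian Byte order, `"little"` (default) or `"big"`.
#' @return An [depth_image()] object.
#' @export
read_depth_raw <- function(path, width, height, endian = "little") {
  n <- as.integer(width) * as.integer(height)
  v <- readBin(path, "integer", n = n, size = 2, signed = FALSE, endian = endian)
  if (length(v) != n) hc_stop("file shorter than width x height values")
  depth_image(matrix(v, nrow = height, ncol = width, byrow = TRUE))
}

#' Read camera intrinsics from JSON
#'
#' Expected keys: `f_px`, `width`, `height` and optionally `cu`, `cv`
#' (principal point; defaults to the image centre when omitted).
#'
#' @param path JSON file path.
#' @return An [camera_model()] object.
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("f_px", "width", "height"))
    if (is.null(j[[k]])) hc_stop(sprintf("intrinsics JSON missing key '%s'", k))
  args <- list(f_px = j$f_px, width = j$width, height = j$height)
  if (!is.null(j$cu)) args$cu <- j$cu
  if (!is.null(j$cv)) args$cv <- j$cv
  do.call(camera_model, args)
}

#' Write camera intrinsics to JSON
#' @param cam An [camera_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_camera_json <- function(cam, path) {
  stopifnot(inherits(cam, "hc_camera"))
  jsonlite::write_json(unclass(cam), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a point cloud as PLY
#'
#' ASCII (default) or binary little-endian PLY with float x, y, z in mm.
#'
#' @param points `hc_points` or n x 3 matrix (mm).
#' @param path Output file path.
#' @param binary Write binary little-endian instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path, binary = FALSE) {
  p <- as_xyz(points)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(p)),
           "property float x", "property float y", "property float z",
           "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(p, trim = TRUE, scientific = FALSE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a binary mask as 8-bit PNG
#' @param mask Logical/0-1 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- (as.matrix(mask) != 0) * 1.0
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG file path.
#' @return Logical matrix (`TRUE` = foreground, threshold at half intensity).
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v > 0.5
}

#' Read bounding-box annotations
#'
#' Plain-text format, one box per line: `label x y w h [confidence]`, where
#' `x`, `y` are the 0-based column/row of the box's top-left pixel and `w`,
#' `h` its size in pixels. Lines starting with `#` are ignored. JSON files
#' (array of objects with the same fields) are also accepted.
#'
#' @param path Annotation file (`.txt`/`.box` or `.json`).
#' @return Data frame with columns `label`, `x`, `y`, `w`, `h`, `confidence`.
#' @export
read_boxes <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(df)
  } else {
    df <- utils::read.table(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) == 5L) df$V6 <- 1
    names(df) <- c("label", "x", "y", "w", "h", "confidence")
  }
  if (is.null(df$confidence)) df$confidence <- 1
  boxes_df(df$label, df$x, df$y, df$w, df$h, df$confidence)
}

#' Write bounding-box annotations to plain text
#' @param boxes Data frame as returned by [read_boxes()] / [boxes_df()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  utils::write.table(boxes[, c("label", "x", "y", "w", "h", "confidence")],
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
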