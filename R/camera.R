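# Camera geometry: pinhole relations between depth-image pixels and metric
# 3D coordinates in the camera-origin global frame.
#
# Conventions. The global origin Og sits at the camera; the depth value zp
# stored at pixel (ud, vd) is the z coordinate (mm) of the surface point seen
# there. Pixel offsets (ud, vd) are measured from the principal point, columns
# rightwards and rows downwards, and the back-projection is
#   xp = -(zp / f) * ud,   yp = -(zp / f) * vd,
# with f the focal length in pixels. The renderer uses the exact algebraic
# inverse, so the sign convention is self-consistent end to end.

#' Pinhole camera model
#'
#' Describes the depth sensor: focal length in pixels, principal point and
#' image size. The principal point defaults to the image centre (the sensor's
#' optical axis pierces the image plane there).
#'
#' @param f_px Focal length in pixels; must be positive.
#' @param width,height Image size in pixels.
#' @param cu,cv Principal point (0-based pixel coordinates, column and row).
#'   Defaults to the image centre.
#' @return An object of class `hc_camera`.
#' @examples
#' cam <- camera_model(600, 640, 480)
#' cam
#' @export
camera_model <- function(f_px, width, height,
                         cu = (width - 1) / 2, cv = (height - 1) / 2) {
  if (!is.numeric(f_px) || length(f_px) != 1L || !is.finite(f_px) || f_px <= 0)
    hc_stop("focal length f_px must be a single positive number")
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) hc_stop("image size must be positive")
  if (cu < 0 || cu >= width || cv < 0 || cv >= height)
    hc_stop("principal point must lie inside the image")
  structure(list(f_px = as.numeric(f_px), cu = as.numeric(cu),
                 cv = as.numeric(cv), width = width, height = height),
            class = "hc_camera")
}

#' @export
print.hc_camera <- function(x, ...) {
  cat(sprintf("Pinhole camera: %d x %d px, f = %g px, principal point (%g, %g)\n",
              x$width, x$height, x$f_px, x$cu, x$cv))
  invisible(x)
}

#' Depth image container
#'
#' Wraps a height x width grid of depth values in millimetres. The sensor
#' encodes "no return" as 0; `NA`/`NaN` values are normalized to the missing
#' sentinel on ingest. Values must fit the sensor's 16-bit range.
#'
#' @param values Numeric matrix of depths (mm), rows = image rows.
#' @param missing_value Sentinel for pixels without a depth return (default 0).
#' @return An object of class `hc_depth` with elements `values` and
#'   `missing_value`.
#' @export
depth_image <- function(values, missing_value = 0) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  v[!is.finite(v)] <- missing_value
  ok <- v == missing_value | (v > 0 & v < 65536)
  if (!all(ok))
    hc_stop("depth values must be missing, or in (0, 65536) mm")
  structure(list(values = v, missing_value = missing_value), class = "hc_depth")
}

#' @export
print.hc_depth <- function(x, ...) {
  v <- x$values
  valid <- v != x$missing_value
  cat(sprintf("Depth image %d x %d px; %d valid px (%.1f%%); range %s mm\n",
              nrow(v), ncol(v), sum(valid), 100 * mean(valid),
              if (any(valid)) sprintf("%.0f-%.0f", min(v[valid]), max(v[valid]))
              else "-"))
  invisible(x)
}

#' @export
dim.hc_depth <- function(x) dim(x$values)

#' Back-project a depth image to a metric point cloud
#'
#' Converts every valid (optionally mask-selected) pixel to a 3D point in the
#' camera-origin frame via `xp = -(zp/f) ud`, `yp = -(zp/f) vd`, where
#' `(ud, vd)` is the pixel offset from the principal point and `zp` the stored
#' depth. Missing pixels emit nothing. Points are emitted in row-major pixel
#' order.
#'
#' @param depth An [depth_image()] object.
#' @param cam An [camera_model()] matching the depth image dimensions.
#' @param mask Optional logical/0-1 matrix of the same size; only `TRUE`
#'   pixels are converted.
#' @return An object of class `hc_points`: list with `xyz` (n x 3 matrix, mm)
#'   and `pixel` (n x 2 matrix of source row/col, 1-based).
#' @export
depth_to_points <- function(depth, cam, mask = NULL) {
  stopifnot(inherits(depth, "hc_depth"), inherits(cam, "hc_camera"))
  v <- depth$values
  if (nrow(v) != cam$height || ncol(v) != cam$width)
    hc_stop("depth image dimensions do not match the camera model")
  keep <- v != depth$missing_value
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(v)))
      hc_stop("mask dimensions do not match the depth image")
    keep <- keep & (mask != 0)
  }
  # row-major emission order: walk the transposed grid
  kt <- t(keep)
  idx <- which(kt)                       # index into t(v)
  col_of <- (idx - 1L) %% nrow(kt) + 1L  # original column
  row_of <- (idx - 1L) %/% nrow(kt) + 1L # original row
  zp <- t(v)[idx]
  ud <- (col_of - 1) - cam$cu
  vd <- (row_of - 1) - cam$cv
  xyz <- cbind(x = -(zp / cam$f_px) * ud,
               y = -(zp / cam$f_px) * vd,
               z = zp)
  structure(list(xyz = xyz,
                 pixel = cbind(row = row_of, col = col_of)),
            class = "hc_points")
}

#' @export
print.hc_points <- function(x, ...) {
  cat(sprintf("Point cloud: %d points (mm, camera-origin frame)\n", nrow(x$xyz)))
  invisible(x)
}

#' Project 3D points to depth-image pixel coordinates
#'
#' Exact inverse of [depth_to_points()]: `ud = -f xp / zp`,
#' `vd = -f yp / zp`; the depth recorded is `zp`. Round-tripping through the
#' two functions reproduces coordinates to numerical precision.
#'
#' @param points `hc_points` object or n x 3 matrix (mm); all `z > 0`.
#' @param cam An [camera_model()].
#' @return Data frame with `ud`, `vd` (offsets from the principal point),
#'   `col`, `row` (0-based absolute pixel coordinates) and `depth` (mm).
#' @export
project_points <- function(points, cam) {
  stopifnot(inherits(cam, "hc_camera"))
  p <- as_xyz(points)
  if (any(p[, 3] <= 0))
    hc_stop("all points must have z > 0 (in front of the camera)")
  ud <- -cam$f_px * p[, 1] / p[, 3]
  vd <- -cam$f_px * p[, 2] / p[, 3]
  data.frame(ud = ud, vd = vd,
             col = ud + cam$cu, row = vd + cam$cv, depth = p[, 3])
}
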