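# Body-frame canonicalization. The supine body's longitudinal axis carries
# the largest variance of the body cloud, so the first principal component
# (projected into the mat plane) defines "head-to-foot"; the vertical axis is
# the mat normal on the camera side; the lateral axis completes a
# right-handed frame. The PCA sign ambiguity is resolved by the head-left
# rule: after orientation, the head centroid sits on the negative
# longitudinal side of the body centroid.

#' Body coordinate frame
#'
#' @param rotation 3x3 orthonormal matrix (det +1) whose rows are the
#'   longitudinal, lateral and vertical unit axes expressed in global
#'   coordinates.
#' @param origin Length-3 origin (body centroid, mm).
#' @return Object of class `hc_frame`.
#' @export
hc_frame <- function(rotation, origin) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0)
    hc_stop("rotation must be orthonormal with det +1 (to 1e-9)")
  structure(list(rotation = rotation, origin = as.numeric(origin)),
            class = "hc_frame")
}

#' @export
print.hc_frame <- function(x, ...) {
  cat("Body frame (rows: longitudinal, lateral, vertical):\n")
  print(round(x$rotation, 4))
  cat(sprintf("origin: (%.1f, %.1f, %.1f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Transform points into a body frame
#'
#' @param frame An [hc_frame()].
#' @param points `hc_points` or n x 3 matrix (mm, global frame).
#' @return n x 3 matrix with columns `longitudinal`, `lateral`, `vertical` (mm).
#' @export
frame_apply <- function(frame, points) {
  stopifnot(inherits(frame, "hc_frame"))
  p <- as_xyz(points)
  out <- sweep(p, 2, frame$origin) %*% t(frame$rotation)
  colnames(out) <- c("longitudinal", "lateral", "vertical")
  out
}

#' Align body orientation by PCA
#'
#' The first principal direction of the centered body cloud, projected into
#' the mat plane, is the longitudinal axis; the vertical axis is the mat
#' normal (camera side positive); the lateral axis is their cross product
#' chosen so the frame is right-handed. An `hc_error_ambiguous_orientation`
#' condition is raised when no dominant axis exists (largest/second
#' eigenvalue ratio below `condition_ratio`).
#'
#' @param body_points `hc_points` or n x 3 matrix of the body surface (mm).
#' @param mat An [hc_plane()] for the mat.
#' @param condition_ratio Minimum first/second eigenvalue ratio (default 1.5).
#' @return An [hc_frame()] centred at the body centroid. The longitudinal
#'   sign is arbitrary until [orient_head_left()] fixes it.
#' @export
pca_align <- function(body_points, mat, condition_ratio = 1.5) {
  stopifnot(inherits(mat, "hc_plane"))
  p <- as_xyz(body_points)
  if (nrow(p) < 3L) hc_stop("PCA alignment needs at least 3 points", "degenerate")
  centroid <- colMeans(p)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  if (ev$values[1] <= 0 || ev$values[1] / max(ev$values[2], 1e-300) < condition_ratio)
    hc_stop("no dominant principal axis: body orientation is ambiguous",
            "ambiguous_orientation")
  vert <- mat$normal                       # unit, camera side
  long <- ev$vectors[, 1]
  long <- long - sum(long * vert) * vert   # project into the mat plane
  if (vnorm(long) < 1e-9)
    hc_stop("principal axis is perpendicular to the mat plane",
            "ambiguous_orientation")
  long <- long / vnorm(long)
  lat <- cross3(vert, long)                # right-handed: det[long lat vert] = +1
  hc_frame(rbind(long, lat, vert, deparse.level = 0), centroid)
}

#' Enforce the head-left convention
#'
#' Flips the longitudinal and lateral axes (a 180-degree rotation about the
#' vertical axis, preserving handedness) iff the head centroid's
#' longitudinal coordinate exceeds the body centroid's, so that after the
#' call the head lies on the negative longitudinal side.
#'
#' @param frame An [hc_frame()] from [pca_align()].
#' @param head_centroid,body_centroid Length-3 global coordinates (mm).
#' @return The (possibly flipped) `hc_frame`.
#' @export
orient_head_left <- function(frame, head_centroid, body_centroid) {
  stopifnot(inherits(frame, "hc_frame"))
  head_centroid <- as.numeric(head_centroid)
  body_centroid <- as.numeric(body_centroid)
  if (vnorm(head_centroid - body_centroid) < 1e-9)
    hc_stop("head and body centroids coincide")
  lc <- frame_apply(frame, rbind(head_centroid, body_centroid))[, 1]
  if (lc[1] > lc[2]) {
    R <- frame$rotation
    R[1, ] <- -R[1, ]
    R[2, ] <- -R[2, ]
    frame <- hc_frame(R, frame$origin)
  }
  frame
}
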