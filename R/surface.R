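# Fitted geometric primitives: the mat plane in the A x + B y + C z = 1
# parameterization (least squares + RANSAC) and the head sphere via the
# linear standard form x^2 + y^2 + z^2 + k x + l y + m z + n = 0.

#' Plane in A x + B y + C z = 1 form
#'
#' This parameterization cannot represent planes through the origin; since
#' the camera sits at the origin and never lies on the mat, that is safe for
#' this pipeline, and degenerate configurations raise a classed error in the
#' fitters. The stored unit `normal` points to the camera side of the plane.
#'
#' @param coef Numeric length-3 vector `(A, B, C)`.
#' @return An object of class `hc_plane` with elements `coef`, `normal`
#'   (unit, camera side) and `offset_mm` (distance of the plane from the
#'   camera origin).
#' @export
hc_plane <- function(coef) {
  coef <- as.numeric(coef)
  if (length(coef) != 3L || !all(is.finite(coef)) || all(coef == 0))
    hc_stop("plane coefficients must be a finite non-zero length-3 vector",
            "degenerate")
  nn <- vnorm(coef)
  # the origin evaluates A x + B y + C z to 0 < 1, so the camera side is the
  # side where the form decreases: unit normal towards the camera is -coef/|coef|
  structure(list(coef = coef, normal = -coef / nn, offset_mm = 1 / nn),
            class = "hc_plane")
}

#' @export
print.hc_plane <- function(x, ...) {
  cat(sprintf("Plane %.3g x + %.3g y + %.3g z = 1 (%.1f mm from camera)\n",
              x$coef[1], x$coef[2], x$coef[3], x$offset_mm))
  invisible(x)
}

#' Least-squares plane fit
#'
#' Solves the stacked linear system `[x y z] (A B C)' = 1` for the plane
#' coefficients by QR least squares (the pseudoinverse solution). Requires at
#' least 3 points spanning a plane that does not pass through the origin;
#' rank-deficient configurations (collinear points, or points on a plane
#' through the origin, which this parameterization cannot express) raise a
#' `hc_error_degenerate` condition.
#'
#' @param points `hc_points` or n x 3 matrix (mm).
#' @return An [hc_plane()] object.
#' @export
fit_plane_lsq <- function(points) {
  p <- as_xyz(points)
  if (nrow(p) < 3L) hc_stop("plane fitting needs at least 3 points", "degenerate")
  qd <- qr(p)
  if (qd$rank < 3L)
    hc_stop("degenerate point configuration (collinear, or plane through the origin)",
            "degenerate")
  hc_plane(qr.coef(qd, rep(1, nrow(p))))
}

#' Signed height of points above a plane
#'
#' Perpendicular point-plane distance, positive on the camera side of the
#' plane. For the mat plane this is the height of a surface point above the
#' bedding.
#'
#' @param points `hc_points` or n x 3 matrix (mm).
#' @param plane An [hc_plane()] object.
#' @return Numeric vector of signed distances (mm).
#' @export
point_plane_height <- function(points, plane) {
  stopifnot(inherits(plane, "hc_plane"))
  p <- as_xyz(points)
  as.numeric((1 - p %*% plane$coef) / vnorm(plane$coef))
}

#' RANSAC plane fit
#'
#' Robust fit of the mat plane from noisy points with outliers: repeatedly
#' samples a minimal 3-point subset, fits a candidate plane and scores it by
#' the number of points within `tolerance_mm` perpendicular distance; the
#' candidate with the highest consensus wins (ties keep the earlier
#' iteration) and is refit by least squares on its full inlier set. Inlier
#' statistics are re-evaluated against the refit plane. Deterministic for a
#' fixed `seed`.
#'
#' @param points `hc_points` or n x 3 matrix (mm).
#' @param iterations Number of random hypotheses (default 500).
#' @param tolerance_mm Inlier distance threshold in mm (default 3).
#' @param seed Optional RNG seed for reproducible sampling.
#' @param min_inlier_fraction Consensus fraction below which the result is
#'   flagged low-confidence (default 0.3).
#' @return An object of class `hc_ransac`: `plane`, `inlier_count`,
#'   `inlier_fraction`, `iterations_run`, `inliers` (indices) and
#'   `low_confidence` flag.
#' @export
fit_plane_ransac <- function(points, iterations = 500, tolerance_mm = 3,
                             seed = NULL, min_inlier_fraction = 0.3) {
  p <- as_xyz(points)
  n <- nrow(p)
  if (n < 3L) hc_stop("RANSAC needs at least 3 points", "degenerate")
  if (tolerance_mm <= 0) hc_stop("tolerance_mm must be positive")
  if (iterations < 1) hc_stop("iterations must be >= 1")

  with_seed(seed, {
    best_count <- -1L
    best_coef <- NULL
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 3L)
      coef <- tryCatch(solve(p[idx, , drop = FALSE], rep(1, 3)),
                       error = function(e) NULL)
      if (is.null(coef) || !all(is.finite(coef)) || all(coef == 0)) next
      d <- abs(1 - p %*% coef) / vnorm(coef)
      cnt <- sum(d <= tolerance_mm)
      if (cnt > best_count) {  # strict: ties keep the earlier iteration
        best_count <- cnt
        best_coef <- coef
      }
    }
    if (is.null(best_coef))
      hc_stop("all RANSAC samples were degenerate", "degenerate")
    inl <- which(abs(1 - p %*% best_coef) / vnorm(best_coef) <= tolerance_mm)
    plane <- fit_plane_lsq(p[inl, , drop = FALSE])
    # consistency: inliers re-evaluated against the refit plane
    inl <- which(abs(point_plane_height(p, plane)) <= tolerance_mm)
    structure(list(plane = plane,
                   inlier_count = length(inl),
                   inlier_fraction = length(inl) / n,
                   iterations_run = iterations,
                   inliers = inl,
                   tolerance_mm = tolerance_mm,
                   low_confidence = length(inl) / n < min_inlier_fraction),
              class = "hc_ransac")
  })
}

#' @export
print.hc_ransac <- function(x, ...) {
  cat(sprintf("RANSAC plane: %d/%d inliers (%.1f%%) at %.3g mm tolerance%s\n",
              x$inlier_count, round(x$inlier_count / max(x$inlier_fraction, 1e-12)),
              100 * x$inlier_fraction, x$tolerance_mm,
              if (x$low_confidence) " [LOW CONFIDENCE]" else ""))
  print(x$plane)
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Fits `(x-a)^2 + (y-b)^2 + (z-c)^2 = r^2` by rewriting it in the standard
#' form `x^2+y^2+z^2 + kx + ly + mz + n = 0`, which is linear in
#' `(k, l, m, n)` and solved by QR least squares (the pseudoinverse
#' solution); then `a = -k/2, b = -l/2, c = -m/2` and
#' `r^2 = a^2 + b^2 + c^2 - n`. Exact on noiseless spherical data, including
#' upper-hemisphere-only samples (the system stays full rank for any
#' non-coplanar configuration).
#'
#' @param points `hc_points` or n x 3 matrix (mm); at least 4 non-coplanar
#'   points.
#' @return An object of class `hc_sphere`: `center` (mm), `radius` (mm) and
#'   the standard-form coefficients `coef` = (k, l, m, n).
#' @export
fit_sphere_lsq <- function(points) {
  p <- as_xyz(points)
  if (nrow(p) < 4L) hc_stop("sphere fitting needs at least 4 points", "degenerate")
  X <- cbind(p, 1)
  qd <- qr(X)
  if (qd$rank < 4L)
    hc_stop("degenerate point configuration (coplanar points)", "degenerate")
  klmn <- unname(qr.coef(qd, -rowSums(p^2)))
  center <- -klmn[1:3] / 2
  r2 <- sum(center^2) - klmn[4]
  if (!is.finite(r2) || r2 <= 0)
    hc_stop("sphere fit failed: non-positive squared radius", "fit_failure")
  structure(list(center = unname(center), radius = sqrt(r2),
                 coef = unname(klmn)),
            class = "hc_sphere")
}

#' @export
print.hc_sphere <- function(x, ...) {
  cat(sprintf("Sphere: center (%.1f, %.1f, %.1f) mm, radius %.1f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}
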