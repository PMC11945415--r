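# Synthetic incubator scenes with analytic ground truth.
#
# Each scene is a head ellipsoid and a body ellipsoid resting tangent on an
# undulating mat, viewed top-down by the pinhole camera and rendered to a
# depth image by exact ray casting (the algebraic inverse of the
# back-projection), with per-pixel Gaussian depth noise and sparse large
# outliers emulating specular/transparency artifacts. The head is an
# ellipsoid rather than a scanned mesh so the circumference at the coronal
# plane through its centre has a closed-form ground truth, while still
# exercising the sphere-fit stage under realistic non-sphericity. The mat
# "undulation" is a sum of two seeded sinusoids standing in for towel folds;
# tangency is enforced against the ideal (flat) mat plane, which is also
# what the measurement pipeline estimates.

.rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

# support radius of an ellipsoid (semi-axes a, world rotation R, columns =
# axes) along unit direction n: max over the surface of n . (x - center)
.ellipsoid_support <- function(semi_axes, R, n) {
  sqrt(sum((semi_axes * as.numeric(crossprod(R, n)))^2))
}

#' True circumference of the coronal section ellipse
#'
#' Perimeter of the ellipse with semi-axes `p_mm` (lateral) and `q_mm`
#' (vertical), by adaptive numerical quadrature of the arc-length integral.
#' Serves as the ground truth a tape measurement would give at the coronal
#' plane through the head centre.
#'
#' @param p_mm,q_mm Positive semi-axes in mm.
#' @return Circumference in cm.
#' @export
true_circumference <- function(p_mm, q_mm) {
  if (!is.finite(p_mm) || !is.finite(q_mm) || p_mm <= 0 || q_mm <= 0)
    hc_stop("semi-axes must be positive")
  per <- stats::integrate(function(t) sqrt((p_mm * sin(t))^2 + (q_mm * cos(t))^2),
                          0, 2 * pi, rel.tol = 1e-12)$value
  mm_to_cm(per)
}

#' Synthetic scene specification
#'
#' All geometry in mm, angles in degrees, in the camera-origin frame (z away
#' from the camera, mat roughly at `mat_depth_mm`). Both ellipsoids are
#' placed tangent to the ideal mat plane (the head touches the mat — the
#' constraint the whole measurement rests on). `head_tilt_deg` is
#' (pitch about the lateral axis, roll about the longitudinal axis);
#' `body_yaw_deg` rotates the body axis within the mat plane; the head sits
#' at the `-longitudinal` end of the body, `head_gap_mm` from its surface.
#'
#' @param head_semi_axes Length-3: (longitudinal, lateral, vertical) mm.
#' @param head_tilt_deg Length-2 head tilt (pitch, roll), degrees.
#' @param body_semi_axes Length-3 body ellipsoid semi-axes, mm.
#' @param body_yaw_deg Body axis direction within the mat plane, degrees.
#' @param head_gap_mm Gap between head and body surfaces along the axis.
#' @param offset_mm Length-2 in-plane offset (mm) of the midpoint of the
#'   head+body assembly.
#' @param mat_depth_mm Distance from camera to the ideal mat plane.
#' @param mat_tilt_deg Length-2 mat plane tilt, degrees.
#' @param mat_extent_mm Half-size of the rendered mat square; rays beyond it
#'   miss (depth 0).
#' @param undulation_amp_mm Length-2 sinusoid amplitudes (mm).
#' @param undulation_wavelength_mm Length-2 wavelengths (mm).
#' @param undulation_phase Length-2 phases (radians).
#' @param undulation_dir_deg Length-2 in-plane directions (degrees).
#' @param camera An [camera_model()].
#' @param noise_sd_mm Gaussian depth noise sd (mm), >= 0.
#' @param outlier_fraction Fraction of valid pixels hit by outliers.
#' @param outlier_range_mm Magnitude range of outlier displacement (mm).
#' @param seed Scene RNG seed (noise and outliers).
#' @return Object of class `hc_scene_spec`.
#' @export
scene_spec <- function(head_semi_axes = c(52, 50, 47),
                       head_tilt_deg = c(0, 0),
                       body_semi_axes = c(160, 55, 40),
                       body_yaw_deg = 0,
                       head_gap_mm = 10,
                       offset_mm = c(0, 0),
                       mat_depth_mm = 800,
                       mat_tilt_deg = c(0, 0),
                       mat_extent_mm = 400,
                       undulation_amp_mm = c(0, 0),
                       undulation_wavelength_mm = c(200, 280),
                       undulation_phase = c(0, 0),
                       undulation_dir_deg = c(0, 90),
                       camera = camera_model(600, 640, 480),
                       noise_sd_mm = 0,
                       outlier_fraction = 0,
                       outlier_range_mm = c(30, 80),
                       seed = 1) {
  stopifnot(inherits(camera, "hc_camera"))
  if (any(head_semi_axes <= 0) || any(body_semi_axes <= 0))
    hc_stop("ellipsoid semi-axes must be positive", "spec")
  if (noise_sd_mm < 0 || outlier_fraction < 0 || outlier_fraction > 1)
    hc_stop("noise sd must be >= 0 and outlier fraction in [0, 1]", "spec")
  if (mat_depth_mm <= 0) hc_stop("mat_depth_mm must be positive", "spec")
  spec <- list(head_semi_axes = as.numeric(head_semi_axes),
               head_tilt_deg = as.numeric(head_tilt_deg),
               body_semi_axes = as.numeric(body_semi_axes),
               body_yaw_deg = as.numeric(body_yaw_deg),
               head_gap_mm = as.numeric(head_gap_mm),
               offset_mm = as.numeric(offset_mm),
               mat_depth_mm = as.numeric(mat_depth_mm),
               mat_tilt_deg = as.numeric(mat_tilt_deg),
               mat_extent_mm = as.numeric(mat_extent_mm),
               undulation_amp_mm = as.numeric(undulation_amp_mm),
               undulation_wavelength_mm = as.numeric(undulation_wavelength_mm),
               undulation_phase = as.numeric(undulation_phase),
               undulation_dir_deg = as.numeric(undulation_dir_deg),
               camera = camera,
               noise_sd_mm = as.numeric(noise_sd_mm),
               outlier_fraction = as.numeric(outlier_fraction),
               outlier_range_mm = as.numeric(outlier_range_mm),
               seed = as.integer(seed))
  class(spec) <- "hc_scene_spec"
  spec
}

#' @export
print.hc_scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene spec: head (%.0f, %.0f, %.0f) mm, mat at %.0f mm, noise %.1f mm, %.1f%% outliers, seed %d\n",
    x$head_semi_axes[1], x$head_semi_axes[2], x$head_semi_axes[3],
    x$mat_depth_mm, x$noise_sd_mm, 100 * x$outlier_fraction, x$seed))
  invisible(x)
}

# Resolve the world-frame geometry of a spec: mat basis, ellipsoid poses,
# the true mat plane and the analytic circumference. Deterministic.
.scene_geometry <- function(spec) {
  d2r <- pi / 180
  # mat plane: upward normal (towards the camera) tilted from (0,0,-1)
  n_up <- as.numeric(.rot_y(spec$mat_tilt_deg[2] * d2r) %*%
                     .rot_x(spec$mat_tilt_deg[1] * d2r) %*% c(0, 0, -1))
  n_up <- n_up / vnorm(n_up)
  p0 <- c(0, 0, spec$mat_depth_mm)
  # in-plane orthonormal basis
  u1 <- cross3(c(0, 1, 0), n_up); u1 <- u1 / vnorm(u1)
  u2 <- cross3(n_up, u1)
  yaw <- spec$body_yaw_deg * d2r
  b_long <- cos(yaw) * u1 + sin(yaw) * u2
  b_lat <- cross3(n_up, b_long)
  R_body <- cbind(b_long, b_lat, n_up, deparse.level = 0)
  tilt <- spec$head_tilt_deg * d2r
  R_head <- R_body %*% (.rot_y(tilt[1]) %*% .rot_x(tilt[2]))

  # offset positions the midpoint of the head+body assembly; the body sits
  # half the axis distance towards +longitudinal, the head the other half
  axis_dist <- spec$body_semi_axes[1] + spec$head_gap_mm + spec$head_semi_axes[1]
  p_mid <- p0 + spec$offset_mm[1] * u1 + spec$offset_mm[2] * u2
  p_body <- p_mid + b_long * (axis_dist / 2)
  body_center <- p_body + n_up * .ellipsoid_support(spec$body_semi_axes, R_body, n_up)
  p_head <- p_body - b_long * axis_dist
  head_center <- p_head + n_up * .ellipsoid_support(spec$head_semi_axes, R_head, n_up)

  mat_plane <- hc_plane(n_up / sum(n_up * p0))
  list(n_up = n_up, p0 = p0, u1 = u1, u2 = u2,
       body = list(center = body_center, rotation = R_body,
                   semi_axes = spec$body_semi_axes),
       head = list(center = head_center, rotation = R_head,
                   semi_axes = spec$head_semi_axes),
       mat_plane = mat_plane,
       circumference_cm = true_circumference(spec$head_semi_axes[2],
                                             spec$head_semi_axes[3]))
}

# Nearest positive ray parameter (z, since rays are (x,y,z) = z * d with
# d_z = 1) for each ray against an ellipsoid; NA where the ray misses.
.ray_ellipsoid_z <- function(D, center, rotation, semi_axes) {
  M <- diag(1 / semi_axes) %*% t(rotation)
  DM <- D %*% t(M)
  Mc <- as.numeric(M %*% center)
  A <- rowSums(DM^2)
  B <- -2 * (DM %*% Mc)
  C0 <- sum(Mc^2) - 1
  disc <- B^2 - 4 * A * C0
  z <- rep(NA_real_, nrow(D))
  hit <- disc >= 0
  zh <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
  zh[zh <= 0] <- NA_real_
  z[hit] <- zh
  z
}

#' Render a synthetic scene to a depth image
#'
#' Ray-casts the spec's geometry: per pixel, the nearest surface among
#' undulating mat, body and head gives the depth; oracle masks record which
#' surface won before noise is applied; rays beyond the mat extent miss
#' (depth 0). Gaussian noise and outliers are then applied under the spec's
#' seed, so the same spec renders bit-identically.
#'
#' @param spec An [scene_spec()].
#' @return Object of class `hc_scene`: `depth` ([depth_image()]), `masks`
#'   (logical `head`/`body`/`mat`), `boxes` (oracle bounding boxes),
#'   `mat_plane` (true ideal plane, [hc_plane()]), `circumference_cm`
#'   (analytic truth), `geometry` (resolved poses) and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "hc_scene_spec"))
  geo <- .scene_geometry(spec)
  cam <- spec$camera
  h <- cam$height; w <- cam$width; f <- cam$f_px

  # frustum check: projected bounding circle of each ellipsoid inside image
  for (obj in list(geo$head, geo$body)) {
    zc <- obj$center[3]; amax <- max(obj$semi_axes)
    if (zc - amax <= 0) hc_stop("geometry behind the camera", "spec")
    pc <- project_points(matrix(obj$center, 1), cam)
    rad_px <- f * amax / (zc - amax)
    if (pc$col - rad_px < 0 || pc$col + rad_px > w - 1 ||
        pc$row - rad_px < 0 || pc$row + rad_px > h - 1)
      hc_stop("geometry outside the camera frustum", "spec")
  }
  # interpenetration check on a deterministic head-surface sample
  sph <- .unit_sphere_grid(24L)
  hs <- t(geo$head$rotation %*% (t(sph) * geo$head$semi_axes)) +
    matrix(geo$head$center, nrow(sph), 3, byrow = TRUE)
  Mb <- diag(1 / geo$body$semi_axes) %*% t(geo$body$rotation)
  bn <- sqrt(rowSums((sweep(hs, 2, geo$body$center) %*% t(Mb))^2))
  if ((1 - min(bn)) * min(geo$body$semi_axes) > 2)
    hc_stop("head and body ellipsoids interpenetrate beyond tolerance", "spec")

  # rays, column-major pixel order
  ud <- rep((0:(w - 1)) - cam$cu, each = h)
  vd <- rep((0:(h - 1)) - cam$cv, times = w)
  D <- cbind(-ud / f, -vd / f, rep(1, length(ud)))

  # ideal mat plane, then sinusoidal undulation as a depth offset
  nd <- as.numeric(D %*% geo$n_up)
  z_plane <- sum(geo$n_up * geo$p0) / nd
  xm <- z_plane * D[, 1]; ym <- z_plane * D[, 2]
  d2r <- pi / 180
  u <- rep(0, length(z_plane))
  for (k in 1:2) {
    amp <- spec$undulation_amp_mm[k]
    if (amp > 0) {
      th <- spec$undulation_dir_deg[k] * d2r
      u <- u + amp * sin(2 * pi * (xm * cos(th) + ym * sin(th)) /
                           spec$undulation_wavelength_mm[k] +
                           spec$undulation_phase[k])
    }
  }
  z_mat <- z_plane - u
  # in-plane extent limit (positions measured in the mat basis)
  rel1 <- (xm - geo$p0[1]) * geo$u1[1] + (ym - geo$p0[2]) * geo$u1[2] +
    (z_plane - geo$p0[3]) * geo$u1[3]
  rel2 <- (xm - geo$p0[1]) * geo$u2[1] + (ym - geo$p0[2]) * geo$u2[2] +
    (z_plane - geo$p0[3]) * geo$u2[3]
  z_mat[abs(rel1) > spec$mat_extent_mm | abs(rel2) > spec$mat_extent_mm |
          z_mat <= 0] <- NA_real_

  z_head <- .ray_ellipsoid_z(D, geo$head$center, geo$head$rotation,
                             geo$head$semi_axes)
  z_body <- .ray_ellipsoid_z(D, geo$body$center, geo$body$rotation,
                             geo$body$semi_axes)

  Z <- cbind(z_head, z_body, z_mat)
  Z[is.na(Z)] <- Inf
  id <- max.col(-Z, ties.method = "first")
  zbest <- Z[cbind(seq_len(nrow(Z)), id)]
  miss <- !is.finite(zbest)
  id[miss] <- 0L

  depth_v <- zbest
  valid_idx <- which(!miss)
  with_seed(spec$seed, {
    if (spec$noise_sd_mm > 0)
      depth_v[valid_idx] <- depth_v[valid_idx] +
        stats::rnorm(length(valid_idx), 0, spec$noise_sd_mm)
    k <- round(spec$outlier_fraction * length(valid_idx))
    if (k > 0) {
      pick <- sample(valid_idx, k)
      mag <- stats::runif(k, spec$outlier_range_mm[1], spec$outlier_range_mm[2])
      depth_v[pick] <- depth_v[pick] + sample(c(-1, 1), k, replace = TRUE) * mag
    }
  })
  depth_v[miss] <- 0
  depth_v <- pmin(pmax(depth_v, 0), 65535)
  depth_v[depth_v > 0 & depth_v < 1] <- 1  # keep valid returns off the sentinel

  dim_px <- c(h, w)
  as_mask <- function(which_id) matrix(id == which_id, dim_px[1], dim_px[2])
  masks <- list(head = as_mask(1L), body = as_mask(2L), mat = as_mask(3L))
  box_of <- function(mask, label) {
    rc <- which(mask, arr.ind = TRUE)
    boxes_df(label,
             x = min(rc[, 2]) - 1, y = min(rc[, 1]) - 1,
             w = diff(range(rc[, 2])) + 1, h = diff(range(rc[, 1])) + 1,
             confidence = 1)
  }
  if (!any(masks$head) || !any(masks$body))
    hc_stop("head or body not visible in the rendered frame", "spec")
  boxes <- rbind(box_of(masks$head, "head"), box_of(masks$body, "body"))

  structure(list(depth = depth_image(matrix(depth_v, dim_px[1], dim_px[2])),
                 masks = masks, boxes = boxes,
                 mat_plane = geo$mat_plane,
                 circumference_cm = geo$circumference_cm,
                 geometry = geo, spec = spec),
            class = "hc_scene")
}

#' @export
print.hc_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: true circumference %.2f cm, seed %d\n",
              x$circumference_cm, x$spec$seed))
  print(x$depth)
  invisible(x)
}

# deterministic quasi-uniform grid on the unit sphere
.unit_sphere_grid <- function(n_theta = 24L) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = 2L * n_theta + 1L)[-1]
  g <- expand.grid(th = th, ph = ph)
  cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
}

#' Render a hemispherical dome validation scene
#'
#' A noiseless analytic fixture: a hemispherical dome (a sphere whose centre
#' lies exactly on the flat mat plane, so only the upper hemisphere stands
#' above the bedding) on the optical axis. Its coronal section through the
#' apex is a semicircle of known radius, giving closed-form expectations for
#' the cross-section features. Note that the visible section of a rendered
#' dome ends one pixel footprint short of the rim, so the observed arc is
#' the quadrature of the generating semicircle over the visible lateral
#' span, not the full `pi * r`.
#'
#' @param radius_mm Dome radius (default 50).
#' @param mat_depth_mm Camera-to-mat distance (default 800).
#' @param camera An [camera_model()].
#' @return A list of class `hc_scene` with `depth`, `masks` (`head` = dome,
#'   `mat`), `mat_plane`, `geometry` and `circumference_cm` (the full circle
#'   `2 pi r`, for reference).
#' @export
render_dome <- function(radius_mm = 50, mat_depth_mm = 800,
                        camera = camera_model(600, 640, 480)) {
  if (radius_mm <= 0 || mat_depth_mm <= radius_mm)
    hc_stop("dome must have positive radius and lie in front of the camera",
            "spec")
  cam <- camera
  h <- cam$height; w <- cam$width; f <- cam$f_px
  ud <- rep((0:(w - 1)) - cam$cu, each = h)
  vd <- rep((0:(h - 1)) - cam$cv, times = w)
  D <- cbind(-ud / f, -vd / f, rep(1, length(ud)))
  center <- c(0, 0, mat_depth_mm)
  zs <- .ray_ellipsoid_z(D, center, diag(3), rep(radius_mm, 3))
  zm <- rep(mat_depth_mm, nrow(D))
  Z <- cbind(zs, zm)
  Z[is.na(Z)] <- Inf
  id <- max.col(-Z, ties.method = "first")
  zb <- Z[cbind(seq_len(nrow(Z)), id)]
  masks <- list(head = matrix(id == 1L, h, w),
                body = matrix(FALSE, h, w),
                mat = matrix(id == 2L, h, w))
  structure(list(depth = depth_image(matrix(zb, h, w)),
                 masks = masks,
                 boxes = NULL,
                 mat_plane = hc_plane(c(0, 0, 1 / mat_depth_mm)),
                 circumference_cm = mm_to_cm(2 * pi * radius_mm),
                 geometry = list(head = list(center = center,
                                             rotation = diag(3),
                                             semi_axes = rep(radius_mm, 3))),
                 spec = list(camera = cam, radius_mm = radius_mm,
                             mat_depth_mm = mat_depth_mm)),
            class = "hc_scene")
}

#' Generate a seeded cohort of synthetic scenes
#'
#' Samples `n` scenes with true circumferences uniform in
#' `circumference_range_cm`, randomized head shape (lateral/vertical
#' anisotropy in `anisotropy_range`), head tilt, body pose and size, mat
#' depth/tilt, towel-like undulation and sensor noise, then renders each.
#' Fully reproducible under `seed` (each scene carries its own derived
#' seed).
#'
#' @param n Number of scenes, >= 1.
#' @param circumference_range_cm Sampling range for the ground truth (cm).
#' @param seed Cohort seed.
#' @param noise_sd_mm Depth noise sd (default 1 mm).
#' @param undulation_amp_mm Cap on the summed undulation amplitude
#'   (default 8 mm).
#' @param outlier_fraction Outlier pixel fraction (default 0.02).
#' @param tilt_max_deg Max |head tilt| per axis (default 10).
#' @param anisotropy_range Vertical/lateral semi-axis ratio range.
#' @param camera An [camera_model()] shared by the cohort.
#' @param render Render each scene (default `TRUE`); with `FALSE` the cohort
#'   holds the `hc_scene_spec`s only (the manifest and ground truth are
#'   available without ray casting — useful for large distributional checks).
#' @return Object of class `hc_cohort`: list of `hc_scene`s (or specs) with
#'   a `manifest` attribute (`data.frame` of id, truth, seed).
#' @export
generate_cohort <- function(n, circumference_range_cm = c(22, 38), seed = 1,
                            noise_sd_mm = 1, undulation_amp_mm = 8,
                            outlier_fraction = 0.02, tilt_max_deg = 10,
                            anisotropy_range = c(0.85, 1.15),
                            camera = camera_model(600, 640, 480),
                            render = TRUE) {
  if (n < 1) hc_stop("n must be >= 1")
  if (circumference_range_cm[1] >= circumference_range_cm[2])
    hc_stop("circumference range must have low < high")
  specs <- with_seed(seed, lapply(seq_len(n), function(i) {
    target_cm <- stats::runif(1, circumference_range_cm[1],
                              circumference_range_cm[2])
    ratio <- stats::runif(1, anisotropy_range[1], anisotropy_range[2])
    # perimeter scales linearly in the section size, so solve by scaling
    p_lat <- target_cm / true_circumference(1, ratio)
    scene_spec(
      head_semi_axes = c(p_lat * stats::runif(1, 1.0, 1.25), p_lat,
                         ratio * p_lat),
      head_tilt_deg = stats::runif(2, -tilt_max_deg, tilt_max_deg),
      body_semi_axes = c(stats::runif(1, 110, 140), stats::runif(1, 45, 60),
                         stats::runif(1, 35, 50)),
      body_yaw_deg = stats::runif(1, 0, 360),
      head_gap_mm = stats::runif(1, 5, 15),
      offset_mm = stats::runif(2, -20, 20),
      mat_depth_mm = stats::runif(1, 850, 950),
      mat_tilt_deg = stats::runif(2, -2, 2),
      undulation_amp_mm = undulation_amp_mm *
        c(stats::runif(1, 0.25, 0.55), stats::runif(1, 0.15, 0.45)),
      undulation_wavelength_mm = stats::runif(2, 150, 350),
      undulation_phase = stats::runif(2, 0, 2 * pi),
      undulation_dir_deg = stats::runif(2, 0, 360),
      camera = camera,
      noise_sd_mm = noise_sd_mm,
      outlier_fraction = outlier_fraction,
      seed = sample.int(2147483646L, 1))
  }))
  scenes <- if (render) lapply(specs, render_scene) else specs
  manifest <- data.frame(
    id = seq_len(n),
    circumference_cm = vapply(specs, function(s)
      true_circumference(s$head_semi_axes[2], s$head_semi_axes[3]), numeric(1)),
    seed = vapply(specs, function(s) s$seed, integer(1)))
  structure(scenes, class = "hc_cohort", manifest = manifest)
}

#' @export
print.hc_cohort <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Synthetic cohort: %d scenes, circumference %.1f-%.1f cm\n",
              nrow(man), min(man$circumference_cm), max(man$circumference_cm)))
  invisible(x)
}

#' Cohort manifest
#' @param cohort An [generate_cohort()] result.
#' @return Data frame with `id`, `circumference_cm`, `seed`.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")

#' Persist a scene to disk
#'
#' Writes `<id>_depth.png` (16-bit), `<id>_mask_{head,body,mat}.png`,
#' `<id>_boxes.txt`, `<id>_spec.json` and `<id>_truth.json` into `dir`.
#'
#' @param scene An `hc_scene`.
#' @param dir Output directory (created if needed).
#' @param id Scene identifier used as filename prefix.
#' @return `dir`, invisibly.
#' @export
scene_write <- function(scene, dir, id = "scene") {
  stopifnot(inherits(scene, "hc_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, id)
  write_depth_png(scene$depth, paste0(pre, "_depth.png"))
  for (m in names(scene$masks))
    write_mask_png(scene$masks[[m]], paste0(pre, "_mask_", m, ".png"))
  write_boxes(scene$boxes, paste0(pre, "_boxes.txt"))
  sp <- scene$spec
  sp$camera <- unclass(sp$camera)
  jsonlite::write_json(unclass(sp), paste0(pre, "_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(circumference_cm = scene$circumference_cm),
                       paste0(pre, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Reload a scene specification from JSON
#' @param path A `*_spec.json` written by [scene_write()].
#' @return An [scene_spec()]; re-rendering it reproduces the scene exactly.
#' @export
scene_spec_read <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- do.call(camera_model, j$camera[c("f_px", "width", "height", "cu", "cv")])
  j$camera <- NULL
  do.call(scene_spec, c(j, list(camera = cam)))
}
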