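# Shared fixtures, built in code. Rendered scenes are cached per session so
# multiple test files can reuse them without re-rendering.

.fixture_env <- new.env(parent = emptyenv())

# a clean, noiseless flat-mat scene
clean_scene <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- render_scene(scene_spec(
      noise_sd_mm = 0, outlier_fraction = 0, undulation_amp_mm = c(0, 0),
      head_tilt_deg = c(0, 0), mat_tilt_deg = c(0, 0), seed = 1))
  }
  .fixture_env$clean
}

# the study-conditions scene: noise, undulation, outliers
noisy_scene <- function() {
  if (is.null(.fixture_env$noisy)) {
    .fixture_env$noisy <- render_scene(scene_spec(
      noise_sd_mm = 1, outlier_fraction = 0.02, undulation_amp_mm = c(4, 3),
      head_tilt_deg = c(5, -4), body_yaw_deg = 20, seed = 7))
  }
  .fixture_env$noisy
}

# points sampled on a sphere surface (upper hemisphere only if cap = TRUE)
sphere_points <- function(n, center, radius, cap = FALSE, seed = 1) {
  withr::with_seed(seed, {
    th <- if (cap) runif(n, 0, pi / 2) else acos(runif(n, -1, 1))
    ph <- runif(n, 0, 2 * pi)
    # "up" towards the camera is -z
    cbind(center[1] + radius * sin(th) * cos(ph),
          center[2] + radius * sin(th) * sin(ph),
          center[3] - radius * cos(th))
  })
}

# dense surface samples of a hemispherical dome (sphere centre on the mat
# plane z = depth, upper half), uniform in area
dome_points <- function(n, radius = 50, depth = 800, seed = 1) {
  withr::with_seed(seed, {
    z <- runif(n, 0, radius)          # height above the plane, uniform (Archimedes)
    ph <- runif(n, 0, 2 * pi)
    s <- sqrt(radius^2 - z^2)
    cbind(s * cos(ph), s * sin(ph), depth - z)
  })
}

# canonical frame for a flat mat at depth d: longitudinal x, lateral -y,
# vertical -z (towards the camera)
flat_frame <- function(depth = 800) {
  hc_frame(rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1)), c(0, 0, depth))
}

expect_hc_error <- function(expr, type) {
  expect_error(expr, class = paste0("hc_error_", type))
}
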