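# Cross-section extraction and the mat-referenced features.

flat_mat <- function(depth = 800)
  fit_plane_lsq(cbind(c(-100, 100, 0, 60), c(0, 0, 100, -40), depth))

test_that("a dense dome section is the expected semicircular profile", {
  pts <- dome_points(200000, radius = 50, depth = 800, seed = 2)
  sph <- fit_sphere_lsq(pts)
  sec <- extract_cross_section(pts, sph, flat_mat(), flat_frame(),
                               slab_half_width_mm = 2, bin_width_mm = 1)
  # apex height 50 mm at s ~ 0
  expect_equal(max(sec$h), 50, tolerance = 0.1)
  expect_lt(abs(sec$s[which.max(sec$h)]), 2)
  # profile matches h = sqrt(r^2 - s^2) at the bin centres
  inner <- abs(sec$s) < 45
  expect_equal(sec$h[inner], sqrt(pmax(50^2 - sec$s[inner]^2, 0)),
               tolerance = 0.5)
  # every contributing point lies within the slab of the plane through the
  # sphere centre: points far from the plane cannot alter the section
  shifted <- pts
  shifted[, 1] <- shifted[, 1] + 500   # move all points out of the slab
  expect_hc_error(
    extract_cross_section(shifted, sph, flat_mat(), flat_frame(),
                          slab_half_width_mm = 2),
    "insufficient_section")
})

test_that("arc length approaches the analytic semicircle as bins refine", {
  pts <- dome_points(400000, radius = 50, depth = 800, seed = 3)
  sph <- fit_sphere_lsq(pts)
  arcs <- vapply(c(2, 1, 0.5), function(bw) {
    sec <- extract_cross_section(pts, sph, flat_mat(), flat_frame(),
                                 slab_half_width_mm = 2, bin_width_mm = bw)
    compute_features(sec)$top_arc_length_cm
  }, numeric(1))
  # monotone refinement: finer bins never shorten the arc materially
  expect_gte(arcs[2], arcs[1] - 0.05)
  expect_gte(arcs[3], arcs[2] - 0.05)
  # the deficit against the full semicircle shrinks as bins refine: the
  # extreme bin's median height sinks towards the rim like sqrt(bin width)
  expect_lt(pi * 5 - arcs[3], pi * 5 - arcs[1] + 0.05)
  expect_lt(abs(arcs[3] - pi * 5), 0.06 * pi * 5)
})

test_that("a flat plateau yields equal edge heights and width-long arc", {
  withr::with_seed(12, {
    s <- runif(20000, -40, 40)
    t <- runif(20000, -30, 30)
    pts <- cbind(s, -t, 800 - 25)        # constant 25 mm above the mat
  })
  sph <- list(center = c(0, 0, 775), radius = 40, coef = rep(0, 4))
  class(sph) <- "hc_sphere"
  sec <- extract_cross_section(pts, sph, flat_mat(), flat_frame(),
                               slab_half_width_mm = 2, bin_width_mm = 1.5)
  ft <- compute_features(sec, extras = TRUE)
  expect_equal(ft$left_height_cm, 2.5, tolerance = 1e-6)
  expect_equal(ft$right_height_cm, 2.5, tolerance = 1e-6)
  # arc = lateral width of the binned curve
  expect_equal(ft$top_arc_length_cm, ft$section_width_cm, tolerance = 1e-6)
  expect_equal(ft$section_width_cm, 8, tolerance = 0.05 * 8)
})

test_that("a truncated profile reports the truncation height and the
           quadrature arc of the generating curve", {
  # dome visible only above 20 mm: emulates the visibility limit
  pts <- dome_points(300000, radius = 50, depth = 800, seed = 6)
  pts <- pts[800 - pts[, 3] >= 20, ]
  sph <- fit_sphere_lsq(dome_points(50000, 50, 800, seed = 7))
  sec <- extract_cross_section(pts, sph, flat_mat(), flat_frame(),
                               slab_half_width_mm = 2, bin_width_mm = 1)
  ft <- compute_features(sec)
  expect_equal(ft$left_height_cm, 2, tolerance = 0.1)
  expect_equal(ft$right_height_cm, 2, tolerance = 0.1)
  # oracle: quadrature of the generating circle over the extracted span
  span <- range(sec$s)
  oracle <- stats::integrate(function(s) sqrt(1 + s^2 / (50^2 - s^2)),
                             span[1], span[2], rel.tol = 1e-10)$value
  expect_lt(abs(ft$top_arc_length_cm - oracle / 10), 0.01 * oracle / 10)
})

test_that("arc length is invariant under rigid motion about the mat normal", {
  sc <- clean_scene()
  cam <- sc$spec$camera
  base <- hc_measure(sc$depth, cam, detector_oracle(sc))
  rot <- render_scene(scene_spec(noise_sd_mm = 0, outlier_fraction = 0,
                                 undulation_amp_mm = c(0, 0),
                                 head_tilt_deg = c(0, 0), mat_tilt_deg = c(0, 0),
                                 body_yaw_deg = 75, offset_mm = c(15, -10),
                                 seed = 1))
  moved <- hc_measure(rot$depth, cam, detector_oracle(rot))
  expect_null(base$error); expect_null(moved$error)
  # invariant up to pixel-grid discretization: rotating the scene re-samples
  # the surface on a different grid, which moves bin medians slightly
  expect_lt(abs(base$features$top_arc_length_cm -
                  moved$features$top_arc_length_cm),
            0.025 * base$features$top_arc_length_cm)
})

test_that("feature bounds hold: non-negative, below max height, arc >= width", {
  sc <- noisy_scene()
  rep <- hc_measure(sc$depth, sc$spec$camera, detector_oracle(sc))
  ft <- compute_features_section <- rep$features
  expect_true(all(unlist(ft) >= 0))
  pts <- depth_to_points(sc$depth, sc$spec$camera, sc$masks$head)
  hmax <- max(point_plane_height(pts, sc$mat_plane))
  expect_lte(ft$left_height_cm, hmax / 10 + 0.1)
  expect_lte(ft$right_height_cm, hmax / 10 + 0.1)
})

test_that("degenerate sections raise classed errors", {
  pts <- dome_points(1000, 50, 800, seed = 4)
  sph <- fit_sphere_lsq(pts)
  one_side <- pts[pts[, 1] > 30, ]   # entirely on one side of the plane
  expect_hc_error(
    extract_cross_section(one_side, sph, flat_mat(), flat_frame(),
                          slab_half_width_mm = 2),
    "insufficient_section")
  few <- pts[1:6, ]
  expect_error(extract_cross_section(few, sph, flat_mat(), flat_frame(),
                                     slab_half_width_mm = 0.01),
               class = "hc_error")
})
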