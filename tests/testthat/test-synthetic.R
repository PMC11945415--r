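# The synthetic scene generator: ground truth, rendering consistency,
# tangency and reproducibility.

test_that("ellipse perimeter quadrature agrees with closed forms", {
  # circle: 2 pi r
  expect_equal(true_circumference(50, 50), 10 * pi, tolerance = 1e-9)
  # Ramanujan approximation for p = 60, q = 40 (agreement < 0.01%)
  ram <- pi * (3 * (60 + 40) - sqrt((3 * 60 + 40) * (60 + 3 * 40))) / 10
  expect_equal(true_circumference(60, 40), ram, tolerance = 1e-4)
  # strictly increasing in each axis
  expect_gt(true_circumference(61, 40), true_circumference(60, 40))
  expect_gt(true_circumference(60, 41), true_circumference(60, 40))
  expect_error(true_circumference(-1, 40), "positive")
})

test_that("rendering is bit-reproducible for a fixed spec and seed", {
  sp <- scene_spec(noise_sd_mm = 1, outlier_fraction = 0.02,
                   undulation_amp_mm = c(4, 3), seed = 123)
  s1 <- render_scene(sp)
  s2 <- render_scene(sp)
  expect_identical(s1$depth$values, s2$depth$values)
  expect_identical(s1$masks, s2$masks)
})

test_that("noiseless mat pixels back-project exactly onto the true plane", {
  sc <- clean_scene()
  pts <- depth_to_points(sc$depth, sc$spec$camera, sc$masks$mat)
  res <- point_plane_height(pts, sc$mat_plane)
  expect_lt(max(abs(res)), 1e-6)
})

test_that("depth noise propagates to mat height residuals at the set sd", {
  sc <- render_scene(scene_spec(noise_sd_mm = 1, outlier_fraction = 0,
                                undulation_amp_mm = c(0, 0), seed = 5))
  pts <- depth_to_points(sc$depth, sc$spec$camera, sc$masks$mat)
  res <- point_plane_height(pts, sc$mat_plane)
  expect_gt(stats::sd(res), 0.9)
  expect_lt(stats::sd(res), 1.1)
})

test_that("the head rests tangent on the ideal mat plane", {
  for (sp in list(scene_spec(seed = 1),
                  scene_spec(head_tilt_deg = c(9, -7), mat_tilt_deg = c(2, -1),
                             body_yaw_deg = 130, seed = 2))) {
    sc <- render_scene(sp)
    geo <- sc$geometry$head
    # dense analytic sample of the head surface
    g <- headcirc:::.unit_sphere_grid(80L)
    surf <- t(geo$rotation %*% (t(g) * geo$semi_axes)) +
      matrix(geo$center, nrow(g), 3, byrow = TRUE)
    h <- point_plane_height(surf, sc$mat_plane)
    expect_gte(min(h), -0.1)
    expect_lte(min(h), 0.1)
  }
})

test_that("oracle masks and boxes delineate the rendered surfaces", {
  sc <- clean_scene()
  expect_gt(sum(sc$masks$head), 500)
  expect_gt(sum(sc$masks$body), 5000)
  expect_equal(sum(sc$masks$head & sc$masks$body), 0)
  hb <- sc$boxes[sc$boxes$label == "head", ]
  rc <- which(sc$masks$head, arr.ind = TRUE)
  expect_equal(hb$x, min(rc[, 2]) - 1)
  expect_equal(hb$w, diff(range(rc[, 2])) + 1)
})

test_that("impossible geometry is rejected with a spec error", {
  expect_hc_error(render_scene(scene_spec(head_gap_mm = -80)), "spec")
  expect_hc_error(render_scene(scene_spec(offset_mm = c(400, 0))), "spec")
})

test_that("cohorts are reproducible and uniform in circumference", {
  c1 <- generate_cohort(12, seed = 31)
  c2 <- generate_cohort(12, seed = 31)
  m1 <- cohort_manifest(c1); m2 <- cohort_manifest(c2)
  expect_identical(m1, m2)
  expect_identical(c1[[5]]$depth$values, c2[[5]]$depth$values)
  expect_true(all(m1$circumference_cm > 22 & m1$circumference_cm < 38))

  # distributional check on the sampled truths (specs only, not rendered)
  big <- generate_cohort(1000, seed = 8, render = FALSE)
  tr <- cohort_manifest(big)$circumference_cm
  ks <- suppressWarnings(stats::ks.test(tr, "punif", 22, 38))
  expect_gt(ks$p.value, 0.01)
})

test_that("scene persistence round-trips through spec JSON and 16-bit PNG", {
  sc <- noisy_scene()
  dir <- withr::local_tempdir()
  scene_write(sc, dir, "s1")
  sp <- scene_spec_read(file.path(dir, "s1_spec.json"))
  sc2 <- render_scene(sp)
  expect_identical(sc$depth$values, sc2$depth$values)
  d <- read_depth_png(file.path(dir, "s1_depth.png"))
  expect_equal(d$values, round(pmin(pmax(sc$depth$values, 0), 65535)),
               tolerance = 1e-12)
  expect_identical(read_mask_png(file.path(dir, "s1_mask_head.png")),
                   sc$masks$head)
})

test_that("the dome validation scene is consistent with its analytic shape", {
  dome <- render_dome(radius_mm = 50, mat_depth_mm = 800)
  pts <- depth_to_points(dome$depth, dome$spec$camera, dome$masks$head)
  s <- fit_sphere_lsq(pts)
  expect_equal(s$center, c(0, 0, 800), tolerance = 1e-6)
  expect_equal(s$radius, 50, tolerance = 1e-6)
  h <- point_plane_height(pts, dome$mat_plane)
  expect_gte(min(h), 0)
  expect_lte(max(h), 50 + 1e-6)
})
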