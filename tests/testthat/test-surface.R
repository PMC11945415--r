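# Plane and sphere fitting in the linear parameterizations.

test_that("least-squares plane recovers axis-aligned and oblique planes", {
  withr::with_seed(5, {
    xy <- cbind(runif(40, -200, 200), runif(40, -150, 150))
  })
  # z = 500 everywhere -> (0, 0, 1/500)
  pl <- fit_plane_lsq(cbind(xy, 500))
  expect_equal(pl$coef, c(0, 0, 0.002), tolerance = 1e-12)
  # x + z = 1000 -> (0.001, 0, 0.001)
  pl2 <- fit_plane_lsq(cbind(xy[, 1], xy[, 2], 1000 - xy[, 1]))
  expect_equal(pl2$coef, c(0.001, 0, 0.001), tolerance = 1e-12)
})

test_that("plane fit rejects degenerate geometry", {
  expect_hc_error(fit_plane_lsq(rbind(c(0, 0, 500), c(1, 1, 500))), "degenerate")
  # collinear
  t <- 1:20
  expect_hc_error(fit_plane_lsq(cbind(t, 2 * t, 500 + t)), "degenerate")
  # a plane through the origin cannot be written as Ax+By+Cz=1
  expect_hc_error(fit_plane_lsq(rbind(c(1, 0, 1), c(0, 1, 0), c(2, 3, 2),
                                      c(-1, 1, -1))), "degenerate")
})

test_that("plane fit is a least-squares optimum", {
  withr::with_seed(8, {
    p <- cbind(runif(30, -100, 100), runif(30, -100, 100),
               500 + rnorm(30, 0, 2))
    pl <- fit_plane_lsq(p)
    ssr <- function(coef) sum((p %*% coef - 1)^2)
    base <- ssr(pl$coef)
    for (k in 1:20) {
      expect_gte(ssr(pl$coef + rnorm(3, 0, 1e-5)), base)
    }
  })
})

test_that("signed point-plane height is perpendicular and camera-positive", {
  pl <- fit_plane_lsq(cbind(runif(20, -50, 50), runif(20, -50, 50), 500))
  # any point satisfying the plane equation has height 0
  expect_equal(point_plane_height(matrix(c(30, -10, 500), 1), pl), 0,
               tolerance = 1e-9)
  # 50 mm towards the camera
  expect_equal(point_plane_height(matrix(c(0, 0, 450), 1), pl), 50,
               tolerance = 1e-9)
  # translation parallel to the plane leaves the height unchanged
  h1 <- point_plane_height(matrix(c(5, 5, 470), 1), pl)
  h2 <- point_plane_height(matrix(c(125, -80, 470), 1), pl)
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("RANSAC on clean data equals the all-points least-squares plane", {
  withr::with_seed(2, {
    p <- cbind(runif(200, -200, 200), runif(200, -200, 200), 500)
  })
  r <- fit_plane_ransac(p, seed = 1)
  expect_equal(r$inlier_count, 200L)
  expect_equal(r$plane$coef, fit_plane_lsq(p)$coef, tolerance = 1e-12)
  expect_false(r$low_confidence)
})

test_that("RANSAC rejects gross outliers and is seed-deterministic", {
  withr::with_seed(31, {
    inl <- cbind(runif(200, -200, 200), runif(200, -200, 200),
                 500 + rnorm(200, 0, 1))
    out <- cbind(runif(40, -200, 200), runif(40, -200, 200),
                 500 + sample(c(-1, 1), 40, TRUE) * runif(40, 30, 80))
  })
  p <- rbind(inl, out)
  r <- fit_plane_ransac(p, tolerance_mm = 3, seed = 4)
  nrm <- r$plane$normal
  angle <- acos(min(1, abs(sum(nrm * c(0, 0, 1))))) * 180 / pi
  expect_lt(angle, 0.5)
  expect_gte(r$inlier_count, 180)
  expect_lt(abs(r$plane$offset_mm - 500), 1)

  r2 <- fit_plane_ransac(p, tolerance_mm = 3, seed = 4)
  expect_identical(r$plane$coef, r2$plane$coef)
  expect_identical(r$inliers, r2$inliers)
})

test_that("structureless clouds are flagged low-confidence", {
  withr::with_seed(9, {
    p <- cbind(runif(300, -100, 100), runif(300, -100, 100),
               runif(300, 400, 600))
  })
  r <- fit_plane_ransac(p, tolerance_mm = 3, seed = 1)
  expect_lt(r$inlier_fraction, 0.3)
  expect_true(r$low_confidence)
})

test_that("sphere fit is exact, including the hand-worked standard form", {
  # centre (10, -20, 500), r = 60: k = -20, l = 40, m = -1000, n = 246900
  p <- sphere_points(50, c(10, -20, 500), 60, seed = 21)
  s <- fit_sphere_lsq(p)
  expect_equal(s$center, c(10, -20, 500), tolerance = 1e-9)
  expect_equal(s$radius, 60, tolerance = 1e-9)
  expect_equal(s$coef, c(-20, 40, -1000, 246900), tolerance = 1e-6)
  # invariant r^2 = a^2 + b^2 + c^2 - n
  expect_equal(s$radius^2, sum(s$center^2) - s$coef[4], tolerance = 1e-6)
})

test_that("sphere recovery stays exact from upper-hemisphere samples", {
  withr::with_seed(13, {
    for (k in 1:10) {
      c0 <- c(runif(1, -100, 100), runif(1, -100, 100), runif(1, 400, 900))
      r0 <- runif(1, 30, 80)
      s <- fit_sphere_lsq(sphere_points(60, c0, r0, cap = TRUE, seed = k))
      expect_lt(max(abs(s$center - c0)) / r0, 1e-9)
      expect_lt(abs(s$radius - r0) / r0, 1e-9)
    }
  })
})

test_that("sphere fit rejects underdetermined and coplanar input", {
  expect_hc_error(fit_sphere_lsq(matrix(rnorm(9), 3, 3)), "degenerate")
  cop <- cbind(runif(10, -50, 50), runif(10, -50, 50), 500)
  expect_hc_error(fit_sphere_lsq(cop), "degenerate")
})
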