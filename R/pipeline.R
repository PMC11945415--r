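# End-to-end measurement flow:
# detect -> masks/cleanup -> mat ring -> back-projection -> RANSAC mat plane
# -> PCA alignment + head-left -> sphere fit -> coronal cross-section ->
# features -> regression. Every stage runs under a stage tag; a failure
# anywhere yields a report carrying that tag, never a partial silent result.

#' Pipeline configuration
#'
#' One place for every tolerance and seed the stages use; the effective
#' config is embedded in each measurement report for provenance.
#'
#' @param ransac_iterations RANSAC hypothesis count (default 500).
#' @param ransac_tolerance_mm Mat-plane inlier tolerance (default 10 mm).
#'   Sized to the bedding's own roughness: towel folds undulate the mat by
#'   around a centimetre, and the tolerance must cover that band so the
#'   consensus plane averages the folds (the reference the head heights
#'   need) while still rejecting gross depth artifacts, which sit tens of
#'   mm off the surface. A tolerance below the fold amplitude would lock
#'   the plane onto a crest and bias every height in the scene.
#' @param seed Seed for the RANSAC sampling (default 1).
#' @param mask_kernel Morphological cleanup element size (default 5).
#' @param mat_ring_px Mat ring width around the body (default 40 px).
#' @param mask_threshold_mm Elevation threshold of the depth fill (default 10).
#' @param refine_masks Use box-seeded refinement in segmentation.
#' @param mat_max_points Subsample cap for plane fitting (default 4000).
#' @param slab_half_width_mm Section slab half-width (default 2).
#' @param bin_width_mm Section bin width (default 1.5).
#' @param min_section_bins Minimum occupied bins (default 5).
#' @param smooth_section Moving-median smoothing of the section.
#' @param sphere_trim_mm Trimming tolerance (mm) for the head sphere stage
#'   and section despiking: after a first least-squares sphere fit, points
#'   farther than this from the sphere surface are discarded as depth
#'   artifacts and the sphere is refit; the same tolerance despikes the
#'   section slab (default 15).
#' @param extra_features Append auxiliary features (default `FALSE`; must
#'   match the trained model).
#' @return Named list of class `hc_config`.
#' @export
hc_config <- function(ransac_iterations = 500, ransac_tolerance_mm = 10,
                      seed = 1, mask_kernel = 5, mat_ring_px = 40,
                      mask_threshold_mm = 10, refine_masks = FALSE,
                      mat_max_points = 4000, slab_half_width_mm = 2,
                      bin_width_mm = 1.5, min_section_bins = 5,
                      smooth_section = FALSE, extra_features = FALSE,
                      sphere_trim_mm = 15) {
  structure(list(ransac_iterations = ransac_iterations,
                 ransac_tolerance_mm = ransac_tolerance_mm, seed = seed,
                 mask_kernel = mask_kernel, mat_ring_px = mat_ring_px,
                 mask_threshold_mm = mask_threshold_mm,
                 refine_masks = refine_masks, mat_max_points = mat_max_points,
                 slab_half_width_mm = slab_half_width_mm,
                 bin_width_mm = bin_width_mm,
                 min_section_bins = min_section_bins,
                 smooth_section = smooth_section,
                 extra_features = extra_features,
                 sphere_trim_mm = sphere_trim_mm),
            class = "hc_config")
}

#' Measure head circumference from one depth image
#'
#' Runs the full pipeline. Any stage failure is caught and reported with its
#' stage tag in the returned report (`$error`); the estimate is `NA` in that
#' case. With `model = NULL` the pipeline stops after feature extraction
#' (useful for building training sets).
#'
#' @param depth An [depth_image()].
#' @param cam An [camera_model()].
#' @param detector A detector provider: `function(depth) -> boxes`
#'   (see [detector_oracle()], [detector_from_file()]).
#' @param model Optional trained [hc_train()] model.
#' @param config An [hc_config()].
#' @param scene_id Identifier recorded in the report.
#' @return Object of class `hc_report`: `scene_id`, `estimate_cm`,
#'   `features`, `diagnostics`, `warnings`, `error` (`NULL` or
#'   `list(stage, message)`), `config`.
#' @export
hc_measure <- function(depth, cam, detector, model = NULL,
                       config = hc_config(), scene_id = "scene") {
  stopifnot(inherits(depth, "hc_depth"), inherits(cam, "hc_camera"),
            is.function(detector))
  report <- list(scene_id = scene_id, estimate_cm = NA_real_,
                 features = NULL, diagnostics = list(), warnings = list(),
                 error = NULL, config = unclass(config))
  class(report) <- "hc_report"
  warn <- function(stage, msg)
    report$warnings[[length(report$warnings) + 1L]] <<- list(stage = stage,
                                                             message = msg)
  fail <- local({
    function(stage, e) {
      report$error <<- list(stage = stage, message = conditionMessage(e))
      report
    }
  })
  run <- function(stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warn(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
  }
  boxes <- run("detection", {
    b <- detector(depth)
    if (!all(c("head", "body") %in% b$label))
      hc_stop("detector did not return both head and body boxes",
              "segmentation")
    b
  })
  if (inherits(boxes, "error")) return(fail("detection", boxes))

  masks <- run("segmentation", masks_from_boxes(
    depth, boxes, refine = config$refine_masks,
    threshold_mm = config$mask_threshold_mm,
    kernel_size = config$mask_kernel, ring_px = config$mat_ring_px))
  if (inherits(masks, "error")) return(fail("segmentation", masks))
  report$diagnostics$mask_px <- lapply(masks[c("head", "body", "mat")], sum)

  clouds <- run("back_projection", list(
    head = depth_to_points(depth, cam, masks$head),
    body = depth_to_points(depth, cam, masks$body),
    mat = depth_to_points(depth, cam, masks$mat)))
  if (inherits(clouds, "error")) return(fail("back_projection", clouds))

  ransac <- run("mat_plane", {
    mp <- clouds$mat$xyz
    if (nrow(mp) > config$mat_max_points)
      mp <- mp[with_seed(config$seed,
                         sample.int(nrow(mp), config$mat_max_points)), ]
    r <- fit_plane_ransac(mp, iterations = config$ransac_iterations,
                          tolerance_mm = config$ransac_tolerance_mm,
                          seed = config$seed)
    if (r$low_confidence)
      warning("mat plane has low consensus: scene may lack a dominant plane")
    r
  })
  if (inherits(ransac, "error")) return(fail("mat_plane", ransac))
  report$diagnostics$plane_inlier_fraction <- ransac$inlier_fraction
  report$diagnostics$plane_coef <- ransac$plane$coef

  frame <- run("alignment", {
    fr <- pca_align(clouds$body$xyz, ransac$plane)
    orient_head_left(fr, colMeans(clouds$head$xyz), colMeans(clouds$body$xyz))
  })
  if (inherits(frame, "error")) return(fail("alignment", frame))

  sphere <- run("sphere_fit", {
    sp <- fit_sphere_lsq(clouds$head$xyz)
    # trimmed refit: discard far-off-surface artifacts, fit once more
    res <- abs(sqrt(rowSums(sweep(clouds$head$xyz, 2, sp$center)^2)) -
                 sp$radius)
    keep <- res <= config$sphere_trim_mm
    if (sum(keep) >= 4 && any(!keep))
      sp <- fit_sphere_lsq(clouds$head$xyz[keep, , drop = FALSE])
    sp
  })
  if (inherits(sphere, "error")) return(fail("sphere_fit", sphere))
  report$diagnostics$sphere_radius_mm <- sphere$radius

  section <- run("cross_section", extract_cross_section(
    clouds$head$xyz, sphere, ransac$plane, frame,
    slab_half_width_mm = config$slab_half_width_mm,
    bin_width_mm = config$bin_width_mm,
    min_bins = config$min_section_bins,
    smooth = config$smooth_section,
    sphere_residual_mm = config$sphere_trim_mm))
  if (inherits(section, "error")) return(fail("cross_section", section))
  report$diagnostics$section_bins <- nrow(section)

  feats <- run("features", compute_features(section,
                                            extras = config$extra_features))
  if (inherits(feats, "error")) return(fail("features", feats))
  report$features <- feats

  if (!is.null(model)) {
    est <- run("prediction", predict(model, feats))
    if (inherits(est, "error")) return(fail("prediction", est))
    report$estimate_cm <- est
  }
  report
}

#' @export
print.hc_report <- function(x, ...) {
  cat(sprintf("Measurement report [%s]\n", x$scene_id))
  if (!is.null(x$error)) {
    cat(sprintf("  FAILED at stage '%s': %s\n", x$error$stage,
                x$error$message))
  } else {
    if (!is.na(x$estimate_cm))
      cat(sprintf("  estimated head circumference: %.2f cm\n", x$estimate_cm))
    if (!is.null(x$features))
      cat(sprintf("  features: left %.2f cm, right %.2f cm, top arc %.2f cm\n",
                  x$features$left_height_cm, x$features$right_height_cm,
                  x$features$top_arc_length_cm))
    if (!is.null(x$diagnostics$plane_inlier_fraction))
      cat(sprintf("  mat plane inliers: %.1f%%; sphere radius: %.1f mm; section bins: %d\n",
                  100 * x$diagnostics$plane_inlier_fraction,
                  x$diagnostics$sphere_radius_mm %||% NA,
                  x$diagnostics$section_bins %||% NA))
  }
  for (w in x$warnings)
    cat(sprintf("  warning [%s]: %s\n", w$stage, w$message))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a measurement report
#'
#' Reports round-trip losslessly through JSON.
#'
#' @param report An `hc_report`.
#' @param path JSON file path.
#' @return `path` invisibly ([hc_report_write()]); an `hc_report`
#'   ([hc_report_read()]).
#' @export
hc_report_write <- function(report, path) {
  stopifnot(inherits(report, "hc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname hc_report_write
#' @export
hc_report_read <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(r$features)) r$features <- as.data.frame(r$features)
  if (length(r$warnings) == 0) r$warnings <- list()
  class(r) <- "hc_report"
  r
}

#' Extract a feature/truth dataset from a cohort
#'
#' Runs the measurement pipeline (oracle detector, no model) on every scene
#' and assembles the feature rows together with the analytic ground truth.
#' Scenes failing at any stage are dropped with a warning.
#'
#' @param cohort An [generate_cohort()] result (or list of `hc_scene`s).
#' @param config An [hc_config()].
#' @return Data frame: `id`, feature columns, `truth_cm`.
#' @export
hc_extract_dataset <- function(cohort, config = hc_config()) {
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sc <- cohort[[i]]
    rep_i <- hc_measure(sc$depth, sc$spec$camera, detector_oracle(sc),
                        model = NULL, config = config, scene_id = i)
    if (!is.null(rep_i$error)) {
      warning(sprintf("scene %d dropped: stage '%s' failed (%s)", i,
                      rep_i$error$stage, rep_i$error$message))
      next
    }
    rows[[i]] <- cbind(data.frame(id = i), rep_i$features,
                       data.frame(truth_cm = sc$circumference_cm))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
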