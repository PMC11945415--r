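# Cross-section extraction and the mat-referenced feature vector.
#
# The measurement plane is the coronal plane: it contains the mat normal and
# the lateral (left-right) axis and passes through the fitted sphere centre,
# i.e. it is orthogonal to the longitudinal body axis. For a supine infant
# this is the slice a tape would take from the occiput over the brow. Because
# only the top of the head is visible, the curve stops where the camera loses
# sight of the head; the heights of its two endpoints above the mat
# ("left/right heights") plus the arc length of the visible top are the
# features the regressor consumes — the mat-contact constraint supplies the
# missing lower part implicitly.

#' Extract the head cross-section at the sphere centre
#'
#' Selects head points within `slab_half_width_mm` of the coronal plane
#' through the sphere centre, expresses them as (lateral coordinate `s`,
#' height `h` above the mat), bins by `s` and keeps the median height per bin
#' (robust to stray pixels), returning the ordered planar curve.
#'
#' @param head_points `hc_points` or n x 3 matrix of the visible head
#'   surface (mm, global frame).
#' @param sphere An [fit_sphere_lsq()] result; its centre anchors the plane.
#' @param mat An [hc_plane()] for the mat.
#' @param frame An [hc_frame()] fixing longitudinal/lateral/vertical axes.
#' @param slab_half_width_mm Half-thickness of the selection slab (default 2).
#' @param bin_width_mm Lateral bin width (default 1.5).
#' @param min_bins Minimum occupied bins for a usable section (default 5).
#' @param smooth Apply a moving median of window 3 to the binned heights
#'   (default `FALSE`).
#' @param sphere_residual_mm Despiking tolerance: slab points farther than
#'   this from the fitted sphere surface are treated as depth artifacts
#'   (specular/transparency returns sit tens of mm off the true surface)
#'   and dropped before binning. The default 15 mm comfortably covers the
#'   true head's deviation from its spherical approximation. `NULL`
#'   disables the filter.
#' @return Object of class `hc_section`: data frame with columns `s`, `h`
#'   (mm), plus attributes describing the section plane and binning.
#' @export
extract_cross_section <- function(head_points, sphere, mat, frame,
                                  slab_half_width_mm = 2, bin_width_mm = 1.5,
                                  min_bins = 5, smooth = FALSE,
                                  sphere_residual_mm = 15) {
  stopifnot(inherits(sphere, "hc_sphere"), inherits(mat, "hc_plane"),
            inherits(frame, "hc_frame"))
  if (slab_half_width_mm <= 0 || bin_width_mm <= 0)
    hc_stop("slab_half_width_mm and bin_width_mm must be positive")
  p <- as_xyz(head_points)
  bc <- frame_apply(frame, p)
  c_long <- frame_apply(frame, matrix(sphere$center, 1))[1, 1]
  sel <- abs(bc[, 1] - c_long) <= slab_half_width_mm
  if (!any(sel))
    hc_stop("no head points within the section slab", "insufficient_section")
  if (!is.null(sphere_residual_mm)) {
    dev <- abs(sqrt(rowSums(sweep(p[sel, , drop = FALSE], 2,
                                  sphere$center)^2)) - sphere$radius)
    sel[sel] <- dev <= sphere_residual_mm
    if (!any(sel))
      hc_stop("no head points within the section slab after despiking",
              "insufficient_section")
  }
  s <- bc[sel, 2]
  hgt <- point_plane_height(p[sel, , drop = FALSE], mat)
  bin <- floor((s - min(s)) / bin_width_mm)
  occupied <- sort(unique(bin))
  if (length(occupied) < min_bins)
    hc_stop(sprintf("only %d occupied section bins (< %d)",
                    length(occupied), min_bins), "insufficient_section")
  sb <- min(s) + (occupied + 0.5) * bin_width_mm
  hb <- vapply(occupied, function(b) stats::median(hgt[bin == b]), numeric(1))
  ord <- order(sb)
  sb <- sb[ord]; hb <- hb[ord]
  if (smooth && length(hb) >= 3)
    hb <- stats::runmed(hb, 3, endrule = "keep")
  structure(data.frame(s = sb, h = hb),
            class = c("hc_section", "data.frame"),
            center = sphere$center,
            normal = frame$rotation[1, ],
            slab_half_width_mm = slab_half_width_mm,
            bin_width_mm = bin_width_mm)
}

#' @export
print.hc_section <- function(x, ...) {
  cat(sprintf(
    "Head cross-section: %d bins over %.1f mm lateral span, max height %.1f mm\n",
    nrow(x), diff(range(x$s)), max(x$h)))
  invisible(x)
}

#' Compute the circumference feature vector from a section
#'
#' Three features in cm, following the visible-geometry-plus-mat-contact
#' idea: the height above the mat at the two lateral extremes of the visible
#' curve (`left_height_cm`, `right_height_cm`) and the polyline arc length
#' of the visible top (`top_arc_length_cm`). Heights are clamped at zero
#' (sensor noise can push mat-grazing points marginally negative). With
#' `extras = TRUE`, `max_height_cm` and `section_width_cm` are appended.
#'
#' @param section An [extract_cross_section()] result with >= 5 bins.
#' @param extras Append auxiliary features (default `FALSE`).
#' @return One-row data frame of features (cm).
#' @export
compute_features <- function(section, extras = FALSE) {
  stopifnot(inherits(section, "hc_section"))
  if (nrow(section) < 5L)
    hc_stop("section has fewer than 5 bins", "insufficient_section")
  s <- section$s
  h <- pmax(section$h, 0)
  arc <- sum(sqrt(diff(s)^2 + diff(h)^2))
  out <- data.frame(left_height_cm = mm_to_cm(h[1]),
                    right_height_cm = mm_to_cm(h[length(h)]),
                    top_arc_length_cm = mm_to_cm(arc))
  if (extras) {
    out$max_height_cm <- mm_to_cm(max(h))
    out$section_width_cm <- mm_to_cm(diff(range(s)))
  }
  out
}
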