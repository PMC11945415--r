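# Body/head segmentation and detection evaluation.
#
# The trained detector used in the clinic is external to this package; it is
# represented by a pluggable provider contract: any function taking an
# hc_depth and returning a bounding-box data frame. Two providers ship here:
# the oracle provider (boxes rendered with the synthetic scene) and the
# file-based provider (annotation files). Morphological cleanup and connected
# components are delegated to EBImage.

#' Construct a bounding-box data frame
#'
#' @param label Character vector, `"head"` or `"body"`.
#' @param x,y 0-based column/row of the top-left pixel of each box.
#' @param w,h Box width/height in pixels (positive).
#' @param confidence Detector confidence in `[0, 1]` (default 1).
#' @return Data frame with columns `label`, `x`, `y`, `w`, `h`, `confidence`.
#' @export
boxes_df <- function(label, x, y, w, h, confidence = 1) {
  df <- data.frame(label = as.character(label), x = as.numeric(x),
                   y = as.numeric(y), w = as.numeric(w), h = as.numeric(h),
                   confidence = as.numeric(confidence),
                   stringsAsFactors = FALSE)
  if (any(df$w <= 0 | df$h <= 0)) hc_stop("box width and height must be positive")
  if (any(df$confidence < 0 | df$confidence > 1))
    hc_stop("confidence must be in [0, 1]")
  df
}

#' Morphological mask cleanup
#'
#' Opening followed by closing with a square structuring element: isolated
#' foreground specks smaller than the element are removed and object
#' boundaries are refined. Idempotent.
#'
#' @param mask Logical/0-1 matrix.
#' @param kernel_size Odd side length of the square element, >= 3.
#' @return Logical matrix, same dimensions.
#' @export
clean_mask <- function(mask, kernel_size = 3) {
  if (length(kernel_size) != 1L || kernel_size < 3 || kernel_size %% 2 == 0)
    hc_stop("kernel_size must be an odd integer >= 3")
  m <- (as.matrix(mask) != 0) * 1
  brush <- EBImage::makeBrush(as.integer(kernel_size), shape = "box")
  out <- EBImage::closing(EBImage::opening(m, brush), brush)
  as.matrix(out) > 0.5
}

#' Intersection over union of two boxes
#'
#' Boxes are axis-aligned pixel rectangles `(x, y, w, h)`; disjoint boxes
#' score 0, identical boxes 1.
#'
#' @param a,b Single-row box data frames (or lists) with `x`, `y`, `w`, `h`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  iw <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
  ih <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

# Largest connected foreground component of a binary matrix.
.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  if (max(lab) < 1) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

# Otsu threshold on a numeric vector (maximizes between-class variance over
# a 256-bin histogram). Used by the box-seeded refinement.
.otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  br <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[256]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Derive head/body/mat masks from detector boxes
#'
#' Seeds a foreground mask inside each detected box and cleans it
#' morphologically. With `refine = FALSE`, foreground is the depth-threshold
#' fill: pixels closer to the camera than the background depth (median valid
#' depth outside all boxes) by at least `threshold_mm`. With `refine = TRUE`,
#' a box-seeded foreground/background refinement is applied instead: an Otsu
#' split of the in-box depth histogram keeps the near class. In both modes
#' the largest connected component inside the box is kept. The mat mask is
#' the ring of valid-depth pixels around the body mask (dilation by
#' `ring_px`), excluding body and head.
#'
#' @param depth An [depth_image()] object.
#' @param boxes Box data frame with at least one `"head"` and one `"body"`
#'   row; the highest-confidence box per label is used.
#' @param refine Use the box-seeded Otsu refinement (default `FALSE`).
#' @param threshold_mm Elevation threshold for the depth fill (default 10).
#' @param kernel_size Cleanup element size (default 5).
#' @param ring_px Mat ring width in pixels (default 40).
#' @return An object of class `hc_masks`: logical matrices `head`, `body`,
#'   `mat`. Head/body are disjoint from mat by construction.
#' @export
masks_from_boxes <- function(depth, boxes, refine = FALSE, threshold_mm = 10,
                             kernel_size = 5, ring_px = 40) {
  stopifnot(inherits(depth, "hc_depth"))
  v <- depth$values
  valid <- v != depth$missing_value
  h <- nrow(v); w <- ncol(v)
  if (any(boxes$x < 0 | boxes$y < 0 |
          boxes$x + boxes$w > w | boxes$y + boxes$h > h))
    hc_stop("boxes must lie within the image bounds")

  box_area <- matrix(FALSE, h, w)
  box_mask_of <- function(b) {
    rows <- (floor(b$y) + 1):min(h, ceiling(b$y + b$h))
    cols <- (floor(b$x) + 1):min(w, ceiling(b$x + b$w))
    m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE
    m
  }
  picked <- list()
  for (lab in c("head", "body")) {
    rows <- boxes[boxes$label == lab, , drop = FALSE]
    if (nrow(rows) == 0L)
      hc_stop(sprintf("no '%s' box provided", lab), "segmentation")
    b <- rows[which.max(rows$confidence), , drop = FALSE]
    picked[[lab]] <- b
    box_area <- box_area | box_mask_of(b)
  }
  bg_depth <- stats::median(v[valid & !box_area])
  if (!is.finite(bg_depth))
    hc_stop("no valid background pixels outside the boxes", "segmentation")

  seg_one <- function(b) {
    inbox <- box_mask_of(b)
    if (refine) {
      d <- v[inbox & valid]
      if (length(d) < 10)
        hc_stop("too few valid pixels in box", "segmentation")
      thr <- .otsu_threshold(d)
      # keep the near (elevated) class, but never at or beyond background
      thr <- min(thr, bg_depth - threshold_mm / 2)
      fg <- inbox & valid & (v < thr)
    } else {
      fg <- inbox & valid & (v < bg_depth - threshold_mm)
    }
    fg <- clean_mask(fg, kernel_size)
    if (!any(fg))
      hc_stop("empty foreground after refinement (box contains no elevated surface)",
              "segmentation")
    .largest_component(fg)
  }
  head_mask <- seg_one(picked$head)
  body_mask <- seg_one(picked$body)

  ring <- as.matrix(EBImage::dilate(
    (body_mask | head_mask) * 1,
    EBImage::makeBrush(2L * as.integer(ring_px) + 1L, shape = "box"))) > 0.5
  mat_mask <- ring & valid & !body_mask & !head_mask

  structure(list(head = head_mask, body = body_mask, mat = mat_mask),
            class = "hc_masks")
}

#' @export
print.hc_masks <- function(x, ...) {
  cat(sprintf("Scene masks: head %d px, body %d px, mat ring %d px\n",
              sum(x$head), sum(x$body), sum(x$mat)))
  invisible(x)
}

#' Mean average precision of box detections
#'
#' Per class, predictions are ranked by confidence and greedily matched to
#' unmatched ground-truth boxes at the given IoU threshold (each ground
#' truth matches at most once); AP is the area under the all-point
#' (continuous) precision envelope of the resulting precision-recall curve,
#' and mAP the mean of the per-class APs. Classes with no ground truth are
#' excluded with a warning. Boxes may carry an `image` column to restrict
#' matches within images.
#'
#' @param predictions Box data frame with `confidence` (and optional `image`).
#' @param ground_truth Box data frame (confidence ignored).
#' @param iou_threshold Match threshold in `(0, 1)` (default 0.5).
#' @return An object of class `hc_detmetrics`: per-class `ap`, `map`, `n_classes`.
#' @export
mean_average_precision <- function(predictions, ground_truth,
                                   iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    hc_stop("iou_threshold must be in (0, 1)")
  if (is.null(predictions$image))
    predictions$image <- rep(1L, nrow(predictions))
  if (is.null(ground_truth$image))
    ground_truth$image <- rep(1L, nrow(ground_truth))
  classes <- sort(unique(ground_truth$label))
  pred_only <- setdiff(unique(predictions$label), classes)
  if (length(pred_only))
    warning("classes with predictions but no ground truth excluded: ",
            paste(pred_only, collapse = ", "))
  ap <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    gt <- ground_truth[ground_truth$label == cl, , drop = FALSE]
    pr <- predictions[predictions$label == cl, , drop = FALSE]
    npos <- nrow(gt)
    if (nrow(pr) == 0L) { ap[cl] <- 0; next }
    pr <- pr[order(-pr$confidence), , drop = FALSE]
    matched <- logical(npos)
    tp <- logical(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      cand <- which(!matched & gt$image == pr$image[i])
      if (!length(cand)) next
      ious <- vapply(cand, function(j) iou(pr[i, ], gt[j, ]), numeric(1))
      jbest <- which.max(ious)
      if (ious[jbest] >= iou_threshold) {
        tp[i] <- TRUE
        matched[cand[jbest]] <- TRUE
      }
    }
    cum_tp <- cumsum(tp)
    precision <- cum_tp / seq_along(tp)
    recall <- cum_tp / npos
    # all-point envelope: precision made non-increasing from the right,
    # integrated over recall increments
    penv <- rev(cummax(rev(precision)))
    ap[cl] <- sum(diff(c(0, recall)) * penv)
  }
  structure(list(ap = ap, map = mean(ap), n_classes = length(classes),
                 iou_threshold = iou_threshold),
            class = "hc_detmetrics")
}

#' @export
print.hc_detmetrics <- function(x, ...) {
  cat(sprintf("Detection metrics @ IoU %.2f\n", x$iou_threshold))
  for (cl in names(x$ap)) cat(sprintf("  AP[%s] = %.4f\n", cl, x$ap[cl]))
  cat(sprintf("  mAP    = %.4f over %d classes\n", x$map, x$n_classes))
  invisible(x)
}

#' Oracle detector provider from a synthetic scene
#'
#' Returns a detector function (signature `function(depth) -> boxes`) that
#' replays the scene's ground-truth bounding boxes. Used wherever the
#' external trained detector is unavailable.
#'
#' @param scene An `hc_scene` from [render_scene()].
#' @return A detector function.
#' @export
detector_oracle <- function(scene) {
  stopifnot(inherits(scene, "hc_scene"))
  boxes <- scene$boxes
  function(depth) boxes
}

#' File-based detector provider
#'
#' Returns a detector function that reads boxes from an annotation file (see
#' [read_boxes()] for the format).
#'
#' @param path Annotation file path.
#' @return A detector function.
#' @export
detector_from_file <- function(path) {
  force(path)
  function(depth) read_boxes(path)
}
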