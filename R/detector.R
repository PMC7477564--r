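# Classical baseline cell detector: estimate the background colour as the
# per-channel median of the field (the smear background dominates), Otsu-
# threshold the colour distance from it, solidify with a morphological
# closing, label connected components, filter by area, and tag each box
# "applicable" (nucleated-cell-like) when a sufficient fraction of its
# pixels are nucleus-dark. This fills the detector contract that a trained
# object-detection network would occupy in a clinical deployment; such a
# network can be plugged in by supplying boxes directly.

#' Detector configuration
#'
#' @param min_area,max_area connected-component area bounds (pixels^2).
#' @param threshold_method "otsu" (adaptive) or "fixed".
#' @param fixed_threshold colour-distance threshold when method = "fixed".
#' @param min_threshold floor under the adaptive threshold; Otsu assumes a
#'   bimodal histogram and would otherwise split the background noise of a
#'   cell-free field.
#' @param crop_margin margin added around each box by [crop_cells()].
#' @param min_nucleus_frac minimum fraction of nucleus-dark pixels
#'   (luminance below `dark_level`) for a box to be tagged applicable.
#' @param dark_level luminance cut-off defining "nucleus-dark".
#' @param closing_size diameter of the morphological closing brush.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(min_area = 120, max_area = 20000,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = 0.12, min_threshold = 0.12,
                            crop_margin = 8L,
                            min_nucleus_frac = 0.05, dark_level = 0.55,
                            closing_size = 5L) {
  threshold_method <- match.arg(threshold_method)
  if (min_area >= max_area) stop("min_area must be < max_area",
                                 call. = FALSE)
  if (crop_margin < 0) stop("crop_margin must be >= 0", call. = FALSE)
  structure(list(min_area = min_area, max_area = max_area,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_threshold = min_threshold,
                 crop_margin = as.integer(crop_margin),
                 min_nucleus_frac = min_nucleus_frac,
                 dark_level = dark_level,
                 closing_size = as.integer(closing_size)),
            class = "detector_config")
}

#' Detect cells in a field image
#'
#' @param f a [field_image()] or bare raster.
#' @param cfg a [detector_config()].
#' @return list of [bounding_box()] sorted by (y, x), each tagged
#'   applicable or not; empty list when nothing is found.
#' @export
detect_cells <- function(f, cfg = detector_config()) {
  raster <- if (inherits(f, "field_image")) f$raster else f
  assert_raster(raster)
  bg <- apply(raster, 3, stats::median)
  dist2 <- (raster[, , 1] - bg[1])^2 + (raster[, , 2] - bg[2])^2 +
    (raster[, , 3] - bg[3])^2
  # saturate the colour distance so Otsu lands between the (huge) background
  # mode and cell matter rather than between pale cytoplasm and dark nuclei
  dist <- pmin(sqrt(dist2), 0.2)
  thr <- if (cfg$threshold_method == "otsu") {
    max(EBImage::otsu(EBImage::Image(t(dist)), range = c(0, 0.2)),
        cfg$min_threshold)
  } else cfg$fixed_threshold
  fg <- EBImage::Image(t(dist > thr))
  brush <- EBImage::makeBrush(cfg$closing_size, shape = "disc")
  fg <- EBImage::closing(fg, brush)
  lab <- EBImage::bwlabel(fg)
  m <- t(EBImage::imageData(lab))  # row = y, col = x
  n <- max(m)
  if (n == 0) return(list())
  lum <- luminance(raster)
  boxes <- list()
  for (i in seq_len(n)) {
    px <- which(m == i, arr.ind = TRUE)
    area <- nrow(px)
    if (area < cfg$min_area || area > cfg$max_area) next
    y0 <- min(px[, 1]); y1 <- max(px[, 1])
    x0 <- min(px[, 2]); x1 <- max(px[, 2])
    dark_frac <- mean(lum[px] < cfg$dark_level)
    boxes[[length(boxes) + 1L]] <-
      bounding_box(x0 - 1L, y0 - 1L, x1 - x0 + 1L, y1 - y0 + 1L,
                   applicable = dark_frac >= cfg$min_nucleus_frac)
  }
  ord <- order(vapply(boxes, function(b) b$y, numeric(1)),
               vapply(boxes, function(b) b$x, numeric(1)))
  boxes[ord]
}

#' Crop applicable cells out of a field
#'
#' One margin-padded crop per applicable box, clipped at field edges;
#' not-applicable boxes (red cells, platelets, debris) are skipped.
#'
#' @param f a [field_image()] or raster.
#' @param boxes list of [bounding_box()].
#' @param margin margin in pixels added on each side.
#' @return list of [labelled_image()] with unset targets and provenance
#'   recording the source box.
#' @export
crop_cells <- function(f, boxes, margin = 8L) {
  raster <- if (inherits(f, "field_image")) f$raster else f
  assert_raster(raster)
  src <- if (inherits(f, "field_image")) f$source_id else list()
  out <- list()
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (!box_in_bounds(b, raster)) {
      stop("box ", i, " (", b$x, ",", b$y, ",", b$width, ",", b$height,
           ") is out of bounds", call. = FALSE)
    }
    if (!isTRUE(b$applicable)) next
    x0 <- max(0, b$x - margin); y0 <- max(0, b$y - margin)
    x1 <- min(raster_width(raster), b$x + b$width + margin)
    y1 <- min(raster_height(raster), b$y + b$height + margin)
    crop <- raster[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
    out[[length(out) + 1L]] <-
      labelled_image(sprintf("crop%04d", i), crop,
                     provenance = list(smear = src$smear, field = src$field,
                                       box = b))
  }
  out
}

#' Apply human corrections to a detector's box list
#'
#' Edits reference boxes by their (1-based) position in the input list:
#' \describe{
#'   \item{delete}{`list(op = "delete", id = i)`}
#'   \item{adjust}{`list(op = "adjust", id = i, box = bounding_box(...))`}
#'   \item{add}{`list(op = "add", box = bounding_box(...))`}
#'   \item{split}{`list(op = "split", id = i, boxes = list(b1, b2, ...))`}
#' }
#' Ids always refer to the original list; deletions/splits are resolved at
#' the end, so an edit script is order-independent and invertible.
#'
#' @param boxes list of [bounding_box()].
#' @param corrections list of edits.
#' @return corrected box list with the applied edit script attached as
#'   attribute `audit`.
#' @export
apply_box_corrections <- function(boxes, corrections) {
  n <- length(boxes)
  keep <- rep(TRUE, n)
  replacement <- vector("list", n)
  added <- list()
  for (ed in corrections) {
    op <- ed$op
    if (op %in% c("delete", "adjust", "split")) {
      if (is.null(ed$id) || ed$id < 1 || ed$id > n) {
        stop("edit references unknown box id: ", ed$id, call. = FALSE)
      }
    }
    if (op == "delete") {
      keep[ed$id] <- FALSE
    } else if (op == "adjust") {
      replacement[[ed$id]] <- list(ed$box)
    } else if (op == "split") {
      replacement[[ed$id]] <- ed$boxes
    } else if (op == "add") {
      added[[length(added) + 1L]] <- ed$box
    } else {
      stop("unknown edit op: ", op, call. = FALSE)
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (is.null(replacement[[i]])) out[[length(out) + 1L]] <- boxes[[i]]
    else for (b in replacement[[i]]) out[[length(out) + 1L]] <- b
  }
  for (b in added) out[[length(out) + 1L]] <- b
  attr(out, "audit") <- corrections
  out
}

#' Intersection-over-union of two boxes
#' @param a,b [bounding_box()] objects.
#' @return IoU in [0, 1].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$width, b$x + b$width) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$height, b$y + b$height) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$width * a$height + b$width * b$height - inter
  inter / union
}

#' Match detections to ground truth and score the detector
#'
#' Greedy IoU matching (standard detection convention, IoU >= `iou_min`).
#' Only applicable boxes on both sides take part.
#'
#' @param detected,truth lists of [bounding_box()].
#' @param iou_min match threshold.
#' @return list with `precision`, `recall`, `n_matched`.
#' @export
detection_scores <- function(detected, truth, iou_min = 0.5) {
  det <- Filter(function(b) isTRUE(b$applicable), detected)
  tru <- Filter(function(b) isTRUE(b$applicable), truth)
  used <- rep(FALSE, length(tru))
  matched <- 0L
  for (d in det) {
    ious <- vapply(seq_along(tru), function(j) {
      if (used[j]) -1 else box_iou(d, tru[[j]])
    }, numeric(1))
    if (length(ious) && max(ious) >= iou_min) {
      used[which.max(ious)] <- TRUE
      matched <- matched + 1L
    }
  }
  list(precision = if (length(det)) matched / length(det) else NA_real_,
       recall = if (length(tru)) matched / length(tru) else NA_real_,
       n_matched = matched)
}
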