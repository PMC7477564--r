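# Anti-imbalance training pipeline: every crop is first pasted into the
# centre of a fixed-size canvas (removing boundary effects so later
# rotations never clip the cell), then randomly translated / rotated /
# flipped / scaled each epoch, and items carrying rare labels are repeated
# within the epoch until per-label totals are approximately equal.

#' Augmentation configuration
#'
#' @param canvas side length of the square paste canvas (pixels).
#' @param scale_range multiplicative scale range; must contain 1.
#' @param rotate full-circle random rotation on/off.
#' @param flip allow horizontal and vertical mirror flips.
#' @param max_translate maximum |translation| per axis, in pixels;
#'   default 10% of the canvas.
#' @param seed base seed for the epoch stream.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(canvas = 96L, scale_range = c(0.8, 1.2),
                           rotate = TRUE, flip = TRUE,
                           max_translate = NULL, seed = 1L) {
  if (scale_range[1] <= 0 || scale_range[1] > 1 || scale_range[2] < 1) {
    stop("scale_range must be positive and contain 1", call. = FALSE)
  }
  if (is.null(max_translate)) max_translate <- round(0.1 * canvas)
  structure(list(canvas = as.integer(canvas),
                 scale_range = as.numeric(scale_range),
                 rotate = isTRUE(rotate), flip = isTRUE(flip),
                 max_translate = as.numeric(max_translate),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Paste a crop into the centre of a fixed-size canvas
#'
#' The canvas is filled with the crop's mean border colour so the paste is
#' seamless; output size is constant across all crops, which a fixed-input
#' regressor requires.
#'
#' @param crop (h, w, 3) raster.
#' @param cfg an [augment_config()].
#' @return (canvas, canvas, 3) raster.
#' @export
paste_to_canvas <- function(crop, cfg = augment_config()) {
  assert_raster(crop)
  s <- cfg$canvas
  h <- raster_height(crop); w <- raster_width(crop)
  if (h > s || w > s) {
    stop("crop (", h, "x", w, ") larger than canvas (", s, ")",
         call. = FALSE)
  }
  fill <- border_colour(crop)
  canvas <- array(rep(fill, each = s * s), c(s, s, 3))
  y0 <- floor((s - h) / 2); x0 <- floor((s - w) / 2)
  canvas[y0 + seq_len(h), x0 + seq_len(w), ] <- crop
  canvas
}

#' Randomly transform a pasted canvas
#'
#' Samples scale ~ U(scale_range), rotation ~ U[0, 360), an independent
#' fair-coin flip per axis, and integer translations within the bound,
#' and applies them as one bilinear affine warp about the canvas centre,
#' filling exposed pixels with the border colour. Deterministic given the
#' seed; output size equals input size.
#'
#' @param img pasted canvas raster.
#' @param cfg an [augment_config()].
#' @param seed transform seed.
#' @return transformed raster.
#' @export
random_transform <- function(img, cfg = augment_config(), seed = 1L) {
  assert_raster(img)
  par <- with_seed(seed, {
    list(scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
         angle = if (cfg$rotate) stats::runif(1, 0, 360) else 0,
         flip_h = cfg$flip && stats::runif(1) < 0.5,
         flip_v = cfg$flip && stats::runif(1) < 0.5,
         tx = stats::runif(1, -cfg$max_translate, cfg$max_translate),
         ty = stats::runif(1, -cfg$max_translate, cfg$max_translate))
  })
  out <- apply_transform(img, par)
  attr(out, "transform") <- par
  out
}

# Deterministic core of random_transform: p' = T R S F (p - c) + c + t.
apply_transform <- function(img, par) {
  th <- par$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(c(par$scale * if (par$flip_h) -1 else 1,
              par$scale * if (par$flip_v) -1 else 1))
  L <- R %*% S
  cx <- (raster_width(img) + 1) / 2
  cy <- (raster_height(img) + 1) / 2
  b <- c(cx + par$tx, cy + par$ty) - L %*% c(cx, cy)
  identity_op <- par$scale == 1 && par$angle == 0 && !par$flip_h &&
    !par$flip_v && par$tx == 0 && par$ty == 0
  if (identity_op) return(img)
  affine_raster(img, L, b, fill = border_colour(img))
}

#' Per-item repeat counts equalizing label frequencies within an epoch
#'
#' Each item's primary label is its highest-graded label (ties broken by
#' schema order; items with no positive grade pool as "none"). An item is
#' repeated `max(1, round(C_max / C_primary))` times, so the per-label
#' epoch totals become approximately equal -- the oversampling counterpart
#' of loss re-weighting for extreme class imbalance.
#'
#' @param d a `cell_dataset` with labelled items.
#' @return named integer vector of multiplicities (names = item ids), with
#'   the per-item primary label attached as attribute `primary`.
#' @export
balanced_multiplicities <- function(d) {
  stopifnot(inherits(d, "cell_dataset"))
  if (length(d$items) == 0) stop("empty dataset", call. = FALSE)
  tm <- target_matrix(d)
  primary <- apply(tm, 1, function(v) {
    if (all(v == 0)) "none" else colnames(tm)[which.max(v)]
  })
  counts <- table(primary)
  cmax <- max(counts)
  mult <- vapply(primary, function(p) {
    max(1L, as.integer(round(cmax / counts[[p]])))
  }, integer(1))
  names(mult) <- rownames(tm)
  attr(mult, "primary") <- primary
  mult
}

#' Expand a dataset into one epoch's (item, transform-seed) stream
#'
#' Applies [balanced_multiplicities()], repeats item ids accordingly,
#' shuffles, and attaches a fresh transform seed to every occurrence.
#'
#' @param d a `cell_dataset`.
#' @param epoch epoch number (>= 1).
#' @param seed base seed.
#' @return data.frame with columns `id`, `transform_seed`.
#' @export
epoch_stream <- function(d, epoch, seed) {
  mult <- balanced_multiplicities(d)
  ids <- rep(names(mult), times = mult)
  es <- split_seed(seed, 2L)[1] %% 1000000L + epoch
  with_seed(es, {
    ids <- sample(ids)
    data.frame(id = ids,
               transform_seed = sample.int(.Machine$integer.max - 1L,
                                           length(ids)),
               stringsAsFactors = FALSE)
  })
}
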