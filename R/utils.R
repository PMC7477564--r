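# Internal helpers: seeded RNG scoping, seed splitting, raster <-> EBImage
# conversion and affine warps. Rasters throughout the package are numeric
# arrays dim(height, width, 3) with values in [0, 1] (the png convention);
# EBImage stores (width, height, channel), hence the aperm pair below.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded internals never
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Split one seed into n child seeds
#'
#' Hierarchical seeding: a parent seed deterministically yields a vector of
#' independent child seeds, so per-cell / per-fold randomness is reproducible
#' regardless of evaluation order.
#'
#' @param seed parent integer seed.
#' @param n number of child seeds.
#' @return integer vector of length n, each in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# raster validation ------------------------------------------------------

assert_raster <- function(x, what = "raster") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop(what, " must be an array of dim (height, width, 3)", call. = FALSE)
  }
  invisible(x)
}

raster_height <- function(x) dim(x)[1]
raster_width <- function(x) dim(x)[2]

as_ebimage <- function(raster) {
  EBImage::Image(aperm(raster, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(img) {
  a <- aperm(EBImage::imageData(img), c(2, 1, 3))
  a[a < 0] <- 0
  a[a > 1] <- 1
  a
}

#' Luminance (grayscale) channel of a raster
#' @param raster (h, w, 3) array.
#' @return (h, w) matrix of Rec. 601 luma values.
#' @keywords internal
luminance <- function(raster) {
  0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

#' Mean colour of a raster's 1-pixel border
#' @keywords internal
border_colour <- function(raster) {
  h <- raster_height(raster)
  w <- raster_width(raster)
  vapply(1:3, function(ch) {
    m <- raster[, , ch]
    mean(c(m[1, ], m[h, ], m[, 1], m[, w]))
  }, numeric(1))
}

# affine warp ------------------------------------------------------------

#' Affine-warp a raster
#'
#' Applies the forward map p' = L p + b (p = (x, y) pixel coordinates,
#' x = column, y = row, 1-based centres) with bilinear interpolation,
#' filling exposed pixels with a constant colour.
#'
#' @param raster (h, w, 3) array.
#' @param L 2x2 linear part.
#' @param b length-2 offset.
#' @param fill length-3 RGB fill colour.
#' @param output_dim optional c(width, height) of the result.
#' @return warped raster.
#' @keywords internal
affine_raster <- function(raster, L, b, fill = c(0, 0, 0), output_dim = NULL) {
  img <- as_ebimage(raster)
  m <- rbind(t(L), as.numeric(b))
  bg <- grDevices::rgb(fill[1], fill[2], fill[3])
  if (is.null(output_dim)) {
    output_dim <- c(raster_width(raster), raster_height(raster))
  }
  out <- EBImage::affine(img, m, filter = "bilinear", bg.col = bg,
                         output.dim = output_dim, antialias = FALSE)
  from_ebimage(out)
}

#' Rotate a raster about its centre
#'
#' @param raster (h, w, 3) array.
#' @param degrees counter-clockwise rotation angle.
#' @param fill RGB fill for exposed corners; defaults to the border mean.
#' @return rotated raster of identical size.
#' @export
rotate_raster <- function(raster, degrees, fill = NULL) {
  assert_raster(raster)
  if (is.null(fill)) fill <- border_colour(raster)
  th <- degrees * pi / 180
  L <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cx <- (raster_width(raster) + 1) / 2
  cy <- (raster_height(raster) + 1) / 2
  b <- c(cx, cy) - L %*% c(cx, cy)
  affine_raster(raster, L, b, fill = fill)
}

#' Read / write a raster as PNG
#' @param path file path.
#' @return `read_raster` returns an (h, w, 3) array; grayscale and RGBA
#'   inputs are promoted/flattened to 8-bit RGB.
#' @export
read_raster <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3), c(dim(a)[1:2], 3L))
  a
}

#' @rdname read_raster
#' @param raster (h, w, 3) array in [0, 1].
#' @export
write_raster <- function(raster, path) {
  assert_raster(raster)
  png::writePNG(raster, path)
  invisible(path)
}

#' Round half away from zero
#'
#' Grade rounding used when collapsing a continuous DG score to an integer
#' grade; x.5 rounds up (towards more severe dysplasia), favouring
#' sensitivity in a screening setting.
#' @param x numeric vector (non-negative grades).
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))
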