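# The multi-label ordinal regressor. Architecture: a feature stem, one
# hidden fully connected layer (the "backbone part"), dropout, and a fully
# connected head with one output per schema label passed through a sigmoid
# and scaled by the label's max_grade -- so every score is confined to
# [0, max_grade] by construction (an unconstrained linear/ReLU output can
# stray far outside the legitimate grade range and destabilise the loss).
#
# Two backbone profiles fill the pluggable-extractor contract:
#   "tiny"     -- a fixed image stem (per-channel block-mean downsample plus
#                 a high-pass granule-texture channel) feeding the trainable
#                 hidden layer; small enough to train on a CPU in seconds.
#   "transfer" -- wraps a user-supplied pretrained feature extractor
#                 function; the hidden layer adapts its features.
# In both cases the optimizer keeps two parameter groups with separate
# learning rates: backbone (hidden layer) and head.
#
# Training: Adam, weighted-mean-quartic loss, L2 regularization added to
# the gradient of every trainable tensor, inverted dropout between the two
# parts, and the epoch stream from the augmentation module (oversampled,
# pasted, randomly transformed).

#' Model configuration
#'
#' @param schema the `label_schema`; the head has one output per label and
#'   each output is scaled by that label's max_grade.
#' @param profile "tiny" (built-in image stem) or "transfer" (wrap a
#'   pretrained extractor).
#' @param input_size side of the downsampled image grid used by the tiny
#'   stem.
#' @param hidden hidden-layer width.
#' @param dropout dropout rate between backbone and head, in [0, 1).
#' @param highpass_sigma Gaussian sd (pixels) of the blur subtracted to
#'   form the tiny stem's granule-texture channel.
#' @param extractor for profile "transfer": function(raster) -> numeric
#'   feature vector.
#' @param feature_dim for profile "transfer": length of the extractor's
#'   output.
#' @return object of class `model_config`.
#' @export
model_config <- function(schema = default_schema(),
                         profile = c("tiny", "transfer"),
                         input_size = 24L, hidden = 32L, dropout = 0.5,
                         highpass_sigma = 1.5, extractor = NULL,
                         feature_dim = NULL) {
  profile <- match.arg(profile)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  if (profile == "transfer") {
    if (!is.function(extractor) || is.null(feature_dim)) {
      stop("transfer profile needs an extractor function and feature_dim",
           call. = FALSE)
    }
  } else {
    g <- as.integer(input_size)
    feature_dim <- 3L * (g %/% 2L)^2 + g^2 + 15L
  }
  structure(list(schema = schema, profile = profile,
                 input_size = as.integer(input_size),
                 hidden = as.integer(hidden), dropout = dropout,
                 highpass_sigma = highpass_sigma, extractor = extractor,
                 feature_dim = as.integer(feature_dim)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults are the reference protocol for the full-scale transfer setting:
#' 120 epochs, batch size 10, Adam learning rates 1e-5 (backbone part) and
#' 1e-4 (head part), and L2 regularization 1e-6. Desk-scale tiny-profile
#' runs pass larger rates and fewer epochs explicitly.
#'
#' @param epochs number of passes over the (oversampled) dataset.
#' @param batch_size minibatch size.
#' @param lr_backbone,lr_head Adam learning rates of the two groups.
#' @param weight_decay L2 coefficient applied to all trainable parameters.
#' @param seed training seed (epoch shuffles, transforms, dropout).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 10L,
                         lr_backbone = 1e-5, lr_head = 1e-4,
                         weight_decay = 1e-6, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr_backbone > 0, lr_head > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_backbone = lr_backbone, lr_head = lr_head,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Per-label loss weights
#'
#' All labels weigh 1 except the focused label, which is up-weighted so its
#' errors dominate the mean (default: DG at 10x).
#'
#' @param schema a `label_schema`.
#' @param focus abbreviation of the focused label.
#' @param focus_weight its weight.
#' @return named positive numeric vector over the schema labels.
#' @export
loss_weights <- function(schema = default_schema(), focus = "DG",
                         focus_weight = 10) {
  w <- stats::setNames(rep(1, length(schema)),
                       schema$labels$abbreviation)
  if (!is.null(focus)) w[schema_index(schema, focus)] <- focus_weight
  if (any(w <= 0)) stop("loss weights must be positive", call. = FALSE)
  w
}

#' Weighted-mean-quartic loss
#'
#' `sum(w * (pred - target)^4) / sum(w)`: a weighted mean of fourth-power
#' deviations. The quartic penalises large grade errors much harder than
#' squared error (doubling one deviation multiplies its contribution by
#' 16), which suits a screening task where a two-grade mistake is far worse
#' than two one-grade mistakes.
#'
#' @param pred,target numeric vectors of equal length.
#' @param w positive weights, same length.
#' @return non-negative scalar; zero iff `pred == target`.
#' @export
weighted_mean_quartic_loss <- function(pred, target, w = rep(1,
                                                             length(pred))) {
  if (length(pred) != length(target) || length(pred) != length(w)) {
    stop("pred, target and w must have equal length", call. = FALSE)
  }
  sum(w * (pred - target)^4) / sum(w)
}

# feature stem -----------------------------------------------------------

# Averaging matrix mapping `from` samples onto `to` bins (area overlap
# weights), used for block-mean downsampling as a plain matrix product.
pool_matrix <- function(from, to) {
  P <- matrix(0, to, from)
  step <- from / to
  for (i in seq_len(to)) {
    a <- (i - 1) * step; b <- i * step
    j0 <- floor(a) + 1L; j1 <- ceiling(b)
    for (j in j0:min(j1, from)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) P[i, j] <- ov
    }
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

# Row-normalized 1-D Gaussian filter matrix (separable blur).
gauss_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  sweep(K, 1, rowSums(K), "/")
}

# Rotation-invariant whole-image summaries: cell / nucleus / cytoplasm
# area fractions, granule-texture (high-pass) energy, the fraction of
# granule-coloured pixels (azurophilic pink has a strong red-minus-green
# gap that survives mild rescaling), and mean stain colour of cytoplasm
# and nucleus. Centred/scaled to roughly [-0.5, 0.5].
cell_summaries <- function(raster, lum, hp) {
  bc <- border_colour(raster)
  cd <- sqrt((raster[, , 1] - bc[1])^2 + (raster[, , 2] - bc[2])^2 +
               (raster[, , 3] - bc[3])^2)
  cell <- cd > 0.1
  dark <- lum < 0.55
  cyto <- cell & !dark
  tot <- length(lum)
  ncell <- sum(cell); ncyto <- sum(cyto); ndark <- sum(dark & cell)
  mz <- function(x, mask, n) if (n == 0) 0 else sum(x[mask]) / n
  c(ncell / tot - 0.25,
    if (ncell == 0) 0 else ndark / ncell - 0.3,
    ncyto / tot - 0.2,
    20 * mz(hp, cyto, ncyto) - 0.5,
    20 * mz(hp, cell, ncell) - 0.5,
    mz(raster[, , 1], cyto, ncyto) - 0.5,
    mz(raster[, , 2], cyto, ncyto) - 0.5,
    mz(raster[, , 3], cyto, ncyto) - 0.5,
    mz(raster[, , 1], dark, ndark) - 0.5,
    mz(raster[, , 2], dark, ndark) - 0.5,
    mz(raster[, , 3], dark, ndark) - 0.5,
    mz(cd, cell, ncell) - 0.25,
    # granule-coloured pixel fractions at three contrast thresholds, so a
    # rescaled (interpolation-softened) image stays decodable
    vapply(c(0.22, 0.30, 0.38), function(th) {
      gmask <- (raster[, , 1] - raster[, , 2]) > th & cell
      if (ncell == 0) 0 else 10 * sum(gmask) / ncell - 0.5
    }, numeric(1)))
}

tiny_stem <- function(model, raster) {
  mc <- model$config
  h <- raster_height(raster); w <- raster_width(raster)
  g_hp <- mc$input_size; g_rgb <- mc$input_size %/% 2L
  key <- paste0(h, "x", w)
  cache <- model$cache
  if (is.null(cache[[key]])) {
    cache[[key]] <- list(Ph = pool_matrix(h, g_hp),
                         Pw = pool_matrix(w, g_hp),
                         Qh = pool_matrix(h, g_rgb),
                         Qw = pool_matrix(w, g_rgb),
                         Kh = gauss_matrix(h, mc$highpass_sigma),
                         Kw = gauss_matrix(w, mc$highpass_sigma))
  }
  cm <- cache[[key]]
  bc <- border_colour(raster)
  # centre the grids on the background so only cell matter carries signal
  ds <- lapply(1:3, function(k) cm$Qh %*% raster[, , k] %*% t(cm$Qw) -
                 bc[k])
  lum <- luminance(raster)
  hp <- abs(lum - cm$Kh %*% lum %*% t(cm$Kw))
  hp_ds <- pmin(8 * (cm$Ph %*% hp %*% t(cm$Pw)), 1) - 0.06
  c(ds[[1]], ds[[2]], ds[[3]], hp_ds,
    cell_summaries(raster, lum, hp))
}

featurize <- function(model, raster) {
  if (model$config$profile == "tiny") tiny_stem(model, raster)
  else as.numeric(model$config$extractor(raster)) - 0.5
}

# model ------------------------------------------------------------------

#' Create an untrained regressor
#'
#' @param mc a [model_config()].
#' @param seed weight-initialization seed.
#' @return object of class `dg_regressor`.
#' @export
new_regressor <- function(mc = model_config(), seed = 1L) {
  d_in <- mc$feature_dim; d_h <- mc$hidden; d_out <- length(mc$schema)
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d_in * d_h, 0, sqrt(2 / d_in)), d_in, d_h),
    b1 = numeric(d_h),
    W2 = matrix(stats::rnorm(d_h * d_out, 0, 0.002), d_h, d_out),
    b2 = numeric(d_out)))
  structure(list(config = mc, params = params, cache = new.env()),
            class = "dg_regressor")
}

LEAKY_SLOPE <- 0.05  # leaky rectifier; keeps hidden units recoverable

# Batch forward pass. X: n x d_in. Returns activations for backprop.
forward_pass <- function(model, X, drop_mask = NULL) {
  p <- model$params
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  H <- pmax(Z1, 0) + LEAKY_SLOPE * pmin(Z1, 0)
  if (!is.null(drop_mask)) H <- H * drop_mask
  Z2 <- sweep(H %*% p$W2, 2, p$b2, "+")
  sig <- 1 / (1 + exp(-Z2))
  G <- matrix(schema_max_grades(model$config$schema), nrow(X),
              ncol(Z2), byrow = TRUE)
  list(X = X, Z1 = Z1, H = H, sig = sig, P = G * sig, G = G)
}

#' Predict grade scores for one image
#'
#' Inference mode: dropout disabled, deterministic. The generic also
#' accepts a plain function `model(raster) -> numeric vector`, which lets
#' tests stub the regressor.
#'
#' @param model a trained `dg_regressor` (or a stub function).
#' @param img raster (a pasted canvas for the tiny profile).
#' @return `grade_vector` of scores, each strictly inside
#'   (0, max_grade).
#' @export
forward_scores <- function(model, img) UseMethod("forward_scores")

#' @export
forward_scores.dg_regressor <- function(model, img) {
  assert_raster(img)
  x <- featurize(model, img)
  if (length(x) != model$config$feature_dim) {
    stop("feature length ", length(x), " does not match feature_dim ",
         model$config$feature_dim, call. = FALSE)
  }
  out <- forward_pass(model, matrix(x, 1))
  grade_vector(model$config$schema, .values = as.numeric(out$P))
}

#' @export
forward_scores.function <- function(model, img) model(img)

# Gradient of the per-sample weighted-mean-quartic loss w.r.t. all
# parameters, averaged over the batch.
backward_pass <- function(model, fwd, Tm, w) {
  n <- nrow(fwd$X)
  Wn <- matrix(w / sum(w), n, length(w), byrow = TRUE)
  dP <- 4 * Wn * (fwd$P - Tm)^3
  delta2 <- dP * fwd$G * fwd$sig * (1 - fwd$sig)
  gW2 <- crossprod(fwd$H, delta2) / n
  gb2 <- colMeans(delta2)
  deltaH <- (delta2 %*% t(model$params$W2)) *
    ifelse(fwd$Z1 > 0, 1, LEAKY_SLOPE)
  if (!is.null(fwd$drop_mask)) deltaH <- deltaH * fwd$drop_mask
  gW1 <- crossprod(fwd$X, deltaH) / n
  gb1 <- colMeans(deltaH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lrs, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lrs[[nm]] * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the regressor
#'
#' Runs the full augmentation pipeline each epoch: rare-label oversampling
#' ([balanced_multiplicities()]), paste-to-canvas, one random geometric
#' transform per occurrence, minibatching, and an Adam update with two
#' parameter groups -- the backbone part at `lr_backbone` and the head at
#' `lr_head` -- plus L2 regularization on every trainable tensor. Fully
#' reproducible for a fixed seed.
#'
#' @param d a labelled `cell_dataset`.
#' @param mc a [model_config()].
#' @param tc a [train_config()].
#' @param ac an [augment_config()].
#' @param w loss weights (default: DG 10x).
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained `dg_regressor`) and `history`
#'   (numeric vector of per-epoch mean losses, length = epochs).
#' @export
train_model <- function(d, mc = model_config(), tc = train_config(),
                        ac = augment_config(), w = loss_weights(mc$schema),
                        verbose = FALSE) {
  stopifnot(inherits(d, "cell_dataset"))
  if (length(d$items) == 0) stop("cannot train on an empty dataset",
                                 call. = FALSE)
  model <- new_regressor(mc, seed = tc$seed)
  if (tc$epochs == 0L) return(list(model = model, history = numeric(0)))

  canvases <- lapply(d$items, function(it) paste_to_canvas(it$raster, ac))
  Tm_all <- target_matrix(d)
  lrs <- list(W1 = tc$lr_backbone, b1 = tc$lr_backbone,
              W2 = tc$lr_head, b2 = tc$lr_head)
  state <- adam_init(model$params)
  history <- numeric(tc$epochs)
  step <- 0L

  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      stream <- epoch_stream(d, ep, ac$seed)
      losses <- numeric(0)
      i <- 1L
      while (i <= nrow(stream)) {
        idx <- i:min(i + tc$batch_size - 1L, nrow(stream))
        X <- t(vapply(idx, function(j) {
          img <- random_transform(canvases[[stream$id[j]]], ac,
                                  seed = stream$transform_seed[j])
          featurize(model, img)
        }, numeric(mc$feature_dim)))
        Tm <- Tm_all[stream$id[idx], , drop = FALSE]
        drop_mask <- if (mc$dropout > 0) {
          matrix(stats::rbinom(length(idx) * mc$hidden, 1,
                               1 - mc$dropout) / (1 - mc$dropout),
                 length(idx), mc$hidden)
        } else NULL
        fwd <- forward_pass(model, X, drop_mask)
        fwd$drop_mask <- drop_mask
        losses <- c(losses, rowSums(sweep((fwd$P - Tm)^4, 2, w / sum(w),
                                          "*")))
        grads <- backward_pass(model, fwd, Tm, w)
        step <- step + 1L
        upd <- adam_step(model$params, grads, state, lrs,
                         tc$weight_decay, step)
        model$params <- upd$params
        state <- upd$state
        i <- i + tc$batch_size
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep,
                                   tc$epochs, history[ep]))
    }
  })
  list(model = model, history = history)
}
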