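# Shared fixtures and independent oracles for the test suite.

# Desk-scale training protocol used by the end-to-end checks: the tiny
# backbone with learning rates sized for its 2-layer scale.
tiny_protocol <- function(schema = default_schema(), epochs = 60L) {
  list(mc = model_config(schema, "tiny", input_size = 24L, hidden = 48L,
                         dropout = 0.5),
       tc = train_config(epochs = epochs, batch_size = 10L,
                         lr_backbone = 5e-3, lr_head = 5e-3,
                         weight_decay = 1e-6, seed = 9L),
       ac = augment_config(canvas = 96L, seed = 5L),
       ec = ensemble_config())
}

# The published 4x4 DG confusion matrix used as a worked-example fixture
# (rows = true grade 0..3, columns = predicted grade 0..3).
reference_confusion <- function() {
  m <- rbind(c(1623, 3, 25, 1),
             c(5, 21, 19, 1),
             c(6, 16, 50, 5),
             c(1, 2, 7, 1))
  # expand into per-cell grade sequences
  true <- integer(0); pred <- integer(0)
  for (i in 1:4) for (j in 1:4) {
    true <- c(true, rep(i - 1L, m[i, j]))
    pred <- c(pred, rep(j - 1L, m[i, j]))
  }
  list(matrix = m, true = true, pred = pred)
}

# --- independent granule-decoding oracle -------------------------------
# Decodes the planted DG grade from a rendered raster alone: segment
# granule-coloured pixels, measure their coverage of the cytoplasm,
# invert the Boolean (overlapping-discs) model to a density estimate, and
# pick the nearest grade density. Calibrated once on renders of known
# density; independent of the package's regressor.

oracle_masks <- function(raster) {
  lum <- 0.299 * raster[, , 1] + 0.587 * raster[, , 2] +
    0.114 * raster[, , 3]
  h <- dim(raster)[1]; w <- dim(raster)[2]
  bc <- vapply(1:3, function(k) {
    mean(c(raster[1, , k], raster[h, , k], raster[, 1, k], raster[, w, k]))
  }, numeric(1))
  cd <- sqrt((raster[, , 1] - bc[1])^2 + (raster[, , 2] - bc[2])^2 +
               (raster[, , 3] - bc[3])^2)
  cell <- cd > 0.1
  dark <- lum < 0.40
  list(granule = (raster[, , 1] - raster[, , 2]) > 0.33 & cell & !dark,
       cyto = cell & !dark)
}

oracle_coverage_density <- function(raster, core_area = 1.0) {
  m <- oracle_masks(raster)
  cov <- sum(m$granule) / max(1, sum(m$cyto | m$granule))
  -log(max(1 - cov, 1e-6)) / core_area
}

# blob-count of clearly separated granules (connected components); used to
# calibrate the single-granule core area
oracle_blob_count <- function(raster) {
  m <- oracle_masks(raster)
  lab <- EBImage::bwlabel(EBImage::Image(t(m$granule)))
  c(n = max(lab), area = sum(m$granule))
}

dg_density_factors <- function() c(1, 1 - 0.98 / 3, 1 - 2 * 0.98 / 3, 0.02)

# memoized calibration (core area from sparse renders, coverage gain from
# known-density renders)
oracle_calibration <- local({
  cache <- NULL
  function(d0 = 0.2) {
    if (!is.null(cache)) return(cache)
    counts <- vapply(1:20, function(i) {
      it <- render_cell(cell_params("granulocyte", granule_density = 0.01,
                                    lobe_count = 4, cell_radius = 19,
                                    stain_noise = 0, seed = 600000 + i))
      oracle_blob_count(it$raster)
    }, numeric(2))
    core <- sum(counts["area", ]) / sum(counts["n", ])
    beta <- mean(vapply(1:40, function(i) {
      it <- render_cell(cell_params("granulocyte", granule_density = d0,
                                    lobe_count = 4, cell_radius = 19,
                                    stain_noise = 0, seed = 700000 + i))
      oracle_coverage_density(it$raster, core)
    }, numeric(1))) / d0
    cache <<- list(core_area = core, beta = beta, d0 = d0)
    cache
  }
})

oracle_decode_grade <- function(raster, cal = oracle_calibration()) {
  lam <- oracle_coverage_density(raster, cal$core_area) / cal$beta / cal$d0
  fac <- dg_density_factors()
  # geometric-mean boundaries (variance-stabilizing for Poisson counts);
  # arithmetic for the near-zero grade-3 density
  bounds <- c(sqrt(fac[1] * fac[2]), sqrt(fac[2] * fac[3]),
              (fac[3] + fac[4]) / 2)
  sum(lam < bounds)
}

render_background_fixture <- function(h = 64, w = 64) {
  array(0.9, c(h, w, 3))
}

# brute-force max per-label fold imbalance over all k^n assignments
exhaustive_min_imbalance <- function(M, k) {
  n <- nrow(M)
  best <- Inf
  asg <- rep(1L, n)
  repeat {
    counts <- vapply(seq_len(ncol(M)), function(l) {
      tab <- tabulate(asg[M[, l] == 1], nbins = k)
      max(tab) - min(tab)
    }, numeric(1))
    best <- min(best, max(counts))
    # increment base-k counter
    i <- 1L
    while (i <= n) {
      asg[i] <- asg[i] + 1L
      if (asg[i] <= k) break
      asg[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}
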