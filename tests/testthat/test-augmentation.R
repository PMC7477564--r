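test_that("paste_to_canvas centres crops on a constant-size canvas", {
  ac <- augment_config(canvas = 128)
  crop <- render_cell(cell_params("granulocyte", seed = 3))$raster
  cv <- paste_to_canvas(crop, ac)
  expect_equal(dim(cv), c(128L, 128L, 3L))
  # corners equal the background fill (mean border colour of the crop)
  h <- dim(crop)[1]; w <- dim(crop)[2]
  fill <- vapply(1:3, function(k) {
    m <- crop[, , k]
    mean(c(m[1, ], m[h, ], m[, 1], m[, w]))
  }, numeric(1))
  expect_equal(as.numeric(cv[1, 1, ]), fill)
  expect_equal(as.numeric(cv[128, 128, ]), fill)
  # a canvas-size crop passes through unchanged
  big <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_identical(paste_to_canvas(big, ac), big)
  # oversize crops error
  expect_error(paste_to_canvas(array(0, c(200, 10, 3)), ac), "larger")
})

test_that("non-background centroid stays within a pixel of the canvas centre", {
  ac <- augment_config(canvas = 96)
  offs <- vapply(1:40, function(i) {
    crop <- render_cell(cell_params("granulocyte", seed = 880 + i))$raster
    cv <- paste_to_canvas(crop, ac)
    fg <- abs(cv[, , 2] - cv[1, 1, 2]) > 0.05
    ctr <- colMeans(which(fg, arr.ind = TRUE))
    max(abs(ctr - (96 + 1) / 2))
  }, numeric(1))
  expect_lt(max(offs), 1.5)
})

test_that("random transforms are seed-deterministic with identity special case", {
  ac <- augment_config(canvas = 96)
  cv <- paste_to_canvas(render_cell(cell_params(seed = 4))$raster, ac)
  expect_identical(random_transform(cv, ac, seed = 11),
                   random_transform(cv, ac, seed = 11))
  id_cfg <- augment_config(canvas = 96, scale_range = c(1, 1),
                           rotate = FALSE, flip = FALSE, max_translate = 0)
  expect_equal(random_transform(cv, id_cfg, seed = 1), cv,
               ignore_attr = "transform")
})

test_that("transforms preserve raster dimensions and value range", {
  ac <- augment_config(canvas = 96)
  cv <- paste_to_canvas(render_cell(cell_params(seed = 6))$raster, ac)
  for (s in 1:5) {
    tr <- random_transform(cv, ac, seed = s)
    expect_equal(dim(tr), dim(cv))
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("sampled scales are uniform on the configured range", {
  ac <- augment_config(canvas = 16, scale_range = c(0.8, 1.2))
  img <- array(0.5, c(16, 16, 3))
  scales <- vapply(1:10000, function(s) {
    attr(random_transform(img, ac, seed = s), "transform")$scale
  }, numeric(1))
  expect_gte(stats::ks.test(scales, "punif", 0.8, 1.2)$p.value, 0.01)
})

test_that("a centred disc keeps its foreground mass under rotation and flips", {
  ac <- augment_config(canvas = 96, scale_range = c(1, 1),
                       max_translate = 0)
  disc <- array(0.9, c(96, 96, 3))
  ctr <- (96 + 1) / 2
  for (i in 1:96) for (j in 1:96) {
    if ((i - ctr)^2 + (j - ctr)^2 < 30^2) disc[i, j, ] <- c(0.3, 0.2, 0.5)
  }
  n0 <- sum(disc[, , 1] < 0.6)
  for (s in 1:8) {
    tr <- random_transform(disc, ac, seed = s)
    expect_lt(abs(sum(tr[, , 1] < 0.6) - n0) / n0, 0.02)
  }
})

test_that("oversampling multiplicities equalize per-label epoch totals", {
  sch <- default_schema()
  mk <- function(n, label, grade, offset) {
    lapply(seq_len(n), function(i) {
      it <- render_cell(cell_params("granulocyte", seed = offset + i),
                        schema = sch, id = sprintf("%s%03d", label, i))
      v <- stats::setNames(numeric(34), sch$labels$abbreviation)
      v[label] <- grade
      it$target <- structure(v, class = "grade_vector")
      it
    })
  }
  # counts {A:100, B:10}: every B item repeated 10x, equal totals
  d <- cell_dataset(sch, c(mk(100, "NN", 1, 0), mk(10, "DG", 2, 500)))
  m <- balanced_multiplicities(d)
  expect_true(all(m[1:100] == 1))
  expect_true(all(m[101:110] == 10))
  tot <- tapply(m, attr(m, "primary"), sum)
  expect_equal(unname(tot["NN"]), unname(tot["DG"]))

  # counts {A:100, B:7}: multiplicity round(100/7) = 14, ratio <= 1.05
  d2 <- cell_dataset(sch, c(mk(100, "NN", 1, 0), mk(7, "DG", 2, 900)))
  m2 <- balanced_multiplicities(d2)
  expect_true(all(m2[101:107] == 14))
  tot2 <- tapply(m2, attr(m2, "primary"), sum)
  expect_lte(max(tot2) / min(tot2), 1.05)

  # single shared label: all multiplicities 1
  d3 <- cell_dataset(sch, mk(12, "NN", 1, 0))
  expect_true(all(balanced_multiplicities(d3) == 1))
  expect_error(balanced_multiplicities(cell_dataset(sch, list())),
               "empty")
})

test_that("epoch totals stay within 2x across random label-count mixes", {
  sch <- default_schema()
  set.seed(77)
  labels <- c("NN", "DG", "HS", "IG", "NE")
  for (rep in 1:5) {
    counts <- sample(1:40, length(labels), replace = TRUE)
    items <- list()
    for (li in seq_along(labels)) {
      for (i in seq_len(counts[li])) {
        it <- render_cell(cell_params(seed = 1000 * rep + 50 * li + i),
                          schema = sch,
                          id = sprintf("r%d_%s%03d", rep, labels[li], i))
        v <- stats::setNames(numeric(34), sch$labels$abbreviation)
        v[labels[li]] <- 1
        it$target <- structure(v, class = "grade_vector")
        items[[length(items) + 1L]] <- it
      }
    }
    m <- balanced_multiplicities(cell_dataset(sch, items))
    tot <- tapply(m, attr(m, "primary"), sum)
    expect_lte(max(tot) / min(tot), 2)
  }
})
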