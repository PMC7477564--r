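test_that("rendering is deterministic for a fixed seed", {
  a <- render_cell(cell_params("granulocyte", dg_grade = 1, seed = 5))
  b <- render_cell(cell_params("granulocyte", dg_grade = 1, seed = 5))
  expect_identical(a$raster, b$raster)
  expect_identical(attr(a, "n_granules"), attr(b, "n_granules"))
})

test_that("severe decreased-granules cells are near agranular with target DG 3", {
  counts <- vapply(1:10, function(i) {
    it <- render_cell(cell_params("granulocyte", dg_grade = 3,
                                  seed = 100 + i, stain_noise = 0))
    expect_equal(it$target[["DG"]], 3)
    attr(it, "n_granules")
  }, numeric(1))
  expect_lt(mean(counts), 6)
})

test_that("mean granule count strictly decreases with DG grade", {
  means <- vapply(0:3, function(g) {
    mean(vapply(1:50, function(i) {
      it <- render_cell(cell_params("granulocyte", dg_grade = g,
                                    seed = 2000 + 97L * g + i))
      as.numeric(attr(it, "n_granules"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("oversize cells are rejected for a fixed crop size", {
  expect_error(cell_params("granulocyte", cell_radius = 18, seed = 1,
                           crop_size = 30), "too large")
  p <- cell_params("granulocyte", cell_radius = 18, seed = 1)
  p$crop_size <- 30
  expect_error(render_cell(p), "too large")
})

test_that("planted grades decode from the raster by the granule-coverage oracle", {
  cal <- oracle_calibration()
  fac <- dg_density_factors()
  ok <- 0L
  for (i in 1:200) {
    g <- (i - 1L) %% 4L
    it <- render_cell(cell_params(
      "granulocyte", dg_grade = g, granule_density = cal$d0 * fac[g + 1],
      lobe_count = 4, cell_radius = 19, stain_noise = 0, seed = 3000 + i))
    if (oracle_decode_grade(it$raster, cal) == g) ok <- ok + 1L
  }
  expect_gte(ok / 200, 0.95)
})

test_that("a granule-count threshold separates binarized DG on noiseless populations", {
  spec <- population_spec(n_cells = 200,
                          label_counts = list(DG = c(30, 30, 30)),
                          stain_noise = 0, seed = 17)
  d <- sample_population(spec)
  counts <- vapply(d$items, function(it) as.numeric(attr(it,
                                                         "n_granules")),
                   numeric(1))
  pos <- target_matrix(d)[, "DG"] >= 1
  floor_val <- 0
  for (th in sort(unique(counts))) {
    floor_val <- max(floor_val, min(mean(counts[pos] < th),
                                    mean(counts[!pos] >= th)))
  }
  expect_gte(floor_val, 0.9)
})

test_that("a sampled population carries exactly the requested grade counts", {
  spec <- population_spec(n_cells = 60,
                          label_counts = list(DG = c(5, 7, 2),
                                              HS = c(1, 2, 3), IG = 6,
                                              NE = 8),
                          seed = 3)
  d <- sample_population(spec)
  st <- summarize_dataset(d)
  expect_equal(attr(st, "n_items"), 60L)
  dg <- st[st$abbreviation == "DG", ]
  expect_equal(c(dg$grade1, dg$grade2, dg$grade3), c(5L, 7L, 2L))
  hs <- st[st$abbreviation == "HS", ]
  expect_equal(c(hs$grade1, hs$grade2, hs$grade3), c(1L, 2L, 3L))
  expect_equal(st$total[st$abbreviation == "IG"], 6)
  expect_equal(st$total[st$abbreviation == "NE"], 8)
  # remainder are normal neutrophils; per-grade counts conserve n_cells
  expect_equal(st$total[st$abbreviation == "NN"], 60 - 5 - 7 - 2 - 6 - 8 - 6)
})

test_that("population sampling is seed-deterministic and rejects infeasible specs", {
  s <- population_spec(n_cells = 12, label_counts = list(DG = c(2, 1, 1)),
                       seed = 8)
  d1 <- sample_population(s)
  d2 <- sample_population(s)
  expect_identical(target_matrix(d1), target_matrix(d2))
  expect_identical(d1$items[[3]]$raster, d2$items[[3]]$raster)
  expect_error(population_spec(n_cells = 3,
                               label_counts = list(DG = c(2, 2, 2))),
               "n_cells")
})

test_that("all-zero planted frequencies yield only grade-0 dysplasia", {
  s <- population_spec(n_cells = 10, label_counts = list(), seed = 2)
  d <- sample_population(s)
  expect_true(all(target_matrix(d)[, "DG"] == 0))
})

test_that("field rendering places disjoint boxes whose crops match stand-alone renders", {
  spec <- population_spec(n_cells = 5, label_counts = list(DG = c(1, 0, 1)),
                          field_size = c(300, 400), max_overlap = 0,
                          seed = 21)
  rf <- render_field(spec)
  expect_length(rf$field$boxes, 5L)
  # pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(box_iou(rf$field$boxes[[i]], rf$field$boxes[[j]]), 0)
  }
  # compositing oracle: re-cropping a ground-truth box reproduces the crop
  for (i in 1:5) {
    b <- rf$field$boxes[[i]]
    crop <- rf$field$raster[b$y + seq_len(b$height),
                            b$x + seq_len(b$width), , drop = FALSE]
    expect_identical(crop, rf$dataset$items[[i]]$raster)
  }
})

test_that("an empty population renders a background-only field", {
  spec <- population_spec(n_cells = 0, label_counts = list(),
                          field_size = c(100, 120), seed = 4)
  rf <- render_field(spec)
  expect_length(rf$field$boxes, 0L)
  expect_length(rf$dataset$items, 0L)
  expect_equal(dim(rf$field$raster), c(100L, 120L, 3L))
})

test_that("impossible placement fails loudly rather than dropping cells", {
  spec <- population_spec(n_cells = 40,
                          label_counts = list(),
                          field_size = c(90, 90), max_overlap = 0,
                          max_attempts = 25, seed = 5)
  expect_error(render_field(spec), "could not place")
})
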