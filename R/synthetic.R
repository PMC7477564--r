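# Synthetic bone-marrow smear generator. Emulates Romanowsky-stained
# single cells on a pale smear background: a lobed purple nucleus, pink
# cytoplasm, and Poisson-scattered fine pink granules whose density encodes
# the DG (decreased granules) grade -- grade 0 has full granulation, grade 3
# is near agranular. Nuclear lobation encodes the HS (hyposegmentation)
# confounder: a single round nucleus marks an HS-dysplastic or immature
# cell. All randomness is driven by one seed split hierarchically.

CATEGORY_RADIUS <- list(erythrocyte = c(10, 14), granulocyte = c(16, 18),
                        megakaryocyte = c(26, 34), not_applicable = c(11, 16))

# Stain palette (RGB in [0,1]); chosen so cytoplasm is separable from the
# background by colour distance but granules are a fine texture, not a blob.
PALETTE <- list(
  background = c(0.90, 0.89, 0.92),
  nucleus = c(0.35, 0.20, 0.50),
  granule = c(0.80, 0.30, 0.52),
  cytoplasm = list(erythrocyte = c(0.62, 0.66, 0.88),
                   granulocyte = c(0.93, 0.74, 0.78),
                   megakaryocyte = c(0.90, 0.78, 0.82),
                   not_applicable = c(0.88, 0.76, 0.82)),
  rbc = c(0.93, 0.60, 0.60))

# Granule density multiplier per DG grade: piecewise linear from full
# granulation to 2% of it at grade 3, so grades are ordered on a continuum.
DG_DENSITY_FACTOR <- c(1, 1 - 0.98 / 3, 1 - 2 * 0.98 / 3, 0.02)
BASE_GRANULE_DENSITY <- 0.2  # granules per cytoplasm pixel at DG0

#' Parameters of one synthetic cell
#'
#' Unspecified morphology fields are sampled deterministically from the
#' seed: radius within the category's range, lobe count 3-5 for a normal
#' granulocyte, granule density from the DG grade with +/-10% within-grade
#' jitter (grades are ordinal judgements on a continuum, not constants).
#'
#' @param category one of `CELL_CATEGORIES`.
#' @param dg_grade integer 0-3; planted "decreased granules" severity
#'   (granulocytes only).
#' @param lobe_count nuclear lobes; 1 marks hyposegmentation.
#' @param cell_radius cytoplasm radius in pixels.
#' @param granule_density expected granules per cytoplasm pixel.
#' @param stain_noise sd of additive per-pixel noise.
#' @param seed integer seed for this cell.
#' @param target_label,target_grade the schema label (and grade) this cell
#'   exemplifies; defaults derived from category/dg_grade/lobe_count.
#' @param crop_size optional fixed crop side; error if the cell cannot fit.
#' @return object of class `cell_params`.
#' @export
cell_params <- function(category = "granulocyte", dg_grade = 0L,
                        lobe_count = NULL, cell_radius = NULL,
                        granule_density = NULL, stain_noise = 0.01,
                        seed = 1L, target_label = NULL, target_grade = NULL,
                        crop_size = NULL) {
  category <- match.arg(category, CELL_CATEGORIES)
  dg_grade <- as.integer(dg_grade)
  stopifnot(dg_grade >= 0L, dg_grade <= 3L)
  fill <- with_seed(seed, {
    r <- if (is.null(cell_radius)) {
      rng <- CATEGORY_RADIUS[[category]]
      stats::runif(1, rng[1], rng[2])
    } else cell_radius
    lb <- if (is.null(lobe_count)) {
      switch(category,
             granulocyte = sample(3:5, 1),
             erythrocyte = 1L,
             megakaryocyte = sample(4:8, 1),
             not_applicable = 1L)
    } else as.integer(lobe_count)
    dens <- if (is.null(granule_density)) {
      base <- switch(category,
                     granulocyte = BASE_GRANULE_DENSITY *
                       DG_DENSITY_FACTOR[dg_grade + 1L],
                     not_applicable = 0.5 * BASE_GRANULE_DENSITY,
                     0)
      base * stats::runif(1, 0.9, 1.1)
    } else granule_density
    list(r = r, lb = lb, dens = dens)
  })
  if (fill$lb < 1L) stop("lobe_count must be >= 1", call. = FALSE)
  rng <- CATEGORY_RADIUS[[category]]
  if (is.null(cell_radius) == FALSE &&
      (cell_radius < 2 || cell_radius > 2 * rng[2])) {
    stop("cell_radius ", cell_radius, " outside configured bounds for ",
         category, call. = FALSE)
  }
  if (!is.null(crop_size) && 2 * ceiling(fill$r) + 5 > crop_size) {
    stop("cell radius ", round(fill$r, 1), " too large for crop size ",
         crop_size, call. = FALSE)
  }
  structure(list(category = category, dg_grade = dg_grade,
                 lobe_count = fill$lb, cell_radius = fill$r,
                 granule_density = fill$dens, stain_noise = stain_noise,
                 seed = as.integer(seed), target_label = target_label,
                 target_grade = target_grade, crop_size = crop_size),
            class = "cell_params")
}

# Linear-interpolation matrix upscaling `from` coarse samples to `to`
# fine positions (coarse samples at the bin centres).
interp_matrix <- function(to, from) {
  U <- matrix(0, to, from)
  pos <- (seq_len(to) - 0.5) / to * from + 0.5  # in coarse-index units
  for (i in seq_len(to)) {
    j <- floor(pos[i])
    frac <- pos[i] - j
    j0 <- min(max(j, 1L), from); j1 <- min(j + 1L, from)
    U[i, j0] <- U[i, j0] + (1 - frac)
    U[i, j1] <- U[i, j1] + frac
  }
  U
}

# Pale smear-like background: light grey plus low-frequency mottle, so a
# detector cannot trivially threshold at pure white.
render_background <- function(h, w, noise_sd = 0.015) {
  base <- PALETTE$background
  ch <- max(2L, ceiling(h / 16)); cw <- max(2L, ceiling(w / 16))
  coarse <- matrix(stats::rnorm(ch * cw, 0, 0.02), ch, cw)
  low <- interp_matrix(h, ch) %*% coarse %*% t(interp_matrix(w, cw))
  out <- array(0, c(h, w, 3))
  for (k in 1:3) out[, , k] <- base[k] + low
  out
}

# Snap to the 8-bit RGB grid PNG stores, so datasets round-trip the disk
# bit-exactly.
quantize_raster <- function(x) {
  x[x < 0] <- 0; x[x > 1] <- 1
  round(x * 255) / 255
}

blend <- function(canvas, colour, alpha) {
  for (k in 1:3) {
    canvas[, , k] <- canvas[, , k] * (1 - alpha) + colour[k] * alpha
  }
  canvas
}

#' Render one synthetic single-cell crop
#'
#' Deterministic for a fixed seed. Granulocyte-lineage cells receive
#' Poisson-scattered granule dots with expected count
#' `granule_density * cytoplasm area`; the returned target grade vector
#' carries the planted DG grade (and HS grade 2 when the nucleus is
#' unlobed in a granulocyte).
#'
#' @param p a [cell_params()].
#' @param schema label schema for the target vector.
#' @param id item identifier.
#' @return a [labelled_image()]; the realised granule count is attached as
#'   attribute `n_granules`.
#' @export
render_cell <- function(p, schema = default_schema(),
                        id = sprintf("cell-%d", p$seed)) {
  stopifnot(inherits(p, "cell_params"))
  r <- p$cell_radius
  s <- if (is.null(p$crop_size)) 2L * as.integer(ceiling(r)) + 5L else
    as.integer(p$crop_size)
  if (2 * ceiling(r) + 5 > s) {
    stop("cell radius ", round(r, 1), " too large for crop size ", s,
         call. = FALSE)
  }
  res <- with_seed(p$seed + 1L, {
    canvas <- render_background(s, s)
    cx <- (s + 1) / 2; cy <- (s + 1) / 2
    xx <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    yy <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    dist <- sqrt((xx - cx)^2 + (yy - cy)^2)

    cyto_alpha <- pmin(pmax(r - dist + 0.5, 0), 1)
    canvas <- blend(canvas, PALETTE$cytoplasm[[p$category]], cyto_alpha)

    # nucleus: lobe_count overlapping discs on a ring (single disc if 1)
    nl <- p$lobe_count
    lobe_r <- 0.55 * r / max(1, nl)^0.4
    ring <- if (nl == 1) 0 else min(0.45 * r, 0.85 * r - lobe_r)
    phase <- stats::runif(1, 0, 2 * pi)
    nuc_dist <- matrix(Inf, s, s)
    for (j in seq_len(nl)) {
      ang <- phase + 2 * pi * (j - 1) / nl
      lx <- cx + ring * cos(ang); ly <- cy + ring * sin(ang)
      nuc_dist <- pmin(nuc_dist, sqrt((xx - lx)^2 + (yy - ly)^2))
    }
    nuc_alpha <- pmin(pmax(lobe_r - nuc_dist + 0.5, 0), 1)

    # granules scattered uniformly in cytoplasm outside the nucleus
    cyto_mask <- dist <= r - 1 & nuc_dist > lobe_r
    area <- sum(cyto_mask)
    n_gr <- if (p$granule_density > 0) stats::rpois(1, p$granule_density *
                                                      area) else 0L
    if (n_gr > 0) {
      ok <- which(cyto_mask)
      pick <- sample(ok, n_gr, replace = TRUE)
      gy <- (pick - 1) %% s + 1          # row
      gx <- (pick - 1) %/% s + 1         # column
      gr_alpha <- matrix(0, s, s)
      for (g in seq_len(n_gr)) {
        rows <- max(1, gy[g] - 2):min(s, gy[g] + 2)
        cols <- max(1, gx[g] - 2):min(s, gx[g] + 2)
        dd <- outer((rows - gy[g])^2, (cols - gx[g])^2, "+")
        gr_alpha[rows, cols] <- pmax(gr_alpha[rows, cols],
                                     0.9 * exp(-dd / (2 * 0.8^2)))
      }
      canvas <- blend(canvas, PALETTE$granule, gr_alpha)
    }
    canvas <- blend(canvas, PALETTE$nucleus, nuc_alpha)
    if (p$stain_noise > 0) {
      canvas <- canvas + array(stats::rnorm(s * s * 3, 0, p$stain_noise),
                               c(s, s, 3))
    }
    canvas <- quantize_raster(canvas)
    list(canvas = canvas, n_gr = n_gr)
  })

  tl <- p$target_label; tg <- p$target_grade
  v <- stats::setNames(numeric(length(schema)),
                       schema$labels$abbreviation)
  if (is.null(tl)) {
    if (p$category == "granulocyte") {
      if (p$dg_grade > 0) v["DG"] <- p$dg_grade
      if (p$lobe_count == 1L) v["HS"] <- 2
      if (p$dg_grade == 0 && p$lobe_count > 1L) v["NN"] <- 1
    } else if (p$category == "erythrocyte") v["NE"] <- 1
    else if (p$category == "megakaryocyte") v["NM"] <- 1
    else v["IG"] <- 1
  } else {
    v[tl] <- if (is.null(tg)) 1 else tg
    if (p$category == "granulocyte" && p$dg_grade > 0) v["DG"] <- p$dg_grade
  }
  it <- labelled_image(id, res$canvas,
                       target = structure(v, class = "grade_vector"),
                       schema = schema,
                       provenance = list(smear = "synthetic", field = NA,
                                         box = NULL))
  attr(it, "cell_params") <- p
  attr(it, "n_granules") <- res$n_gr
  it
}

# Enucleate red-cell distractor blob (not a labelled cell).
render_rbc <- function(radius = 9, seed = 1L, stain_noise = 0.01) {
  s <- 2L * as.integer(ceiling(radius)) + 5L
  with_seed(seed, {
    canvas <- render_background(s, s)
    cx <- (s + 1) / 2
    xx <- matrix(rep(seq_len(s), each = s), s, s)
    yy <- matrix(rep(seq_len(s), times = s), s, s)
    dist <- sqrt((xx - cx)^2 + (yy - cx)^2)
    alpha <- pmin(pmax(radius - dist + 0.5, 0), 1)
    # central pallor of a red cell
    alpha <- alpha * (0.55 + 0.45 * pmin(dist / radius, 1))
    canvas <- blend(canvas, PALETTE$rbc, alpha)
    canvas <- canvas + array(stats::rnorm(s * s * 3, 0, stain_noise),
                             c(s, s, 3))
    canvas <- quantize_raster(canvas)
    canvas
  })
}

#' Specification of a synthetic cell population
#'
#' `label_counts` plants exact per-label grade frequencies: a length-3
#' vector for ordinal labels (counts of grades 1, 2, 3) or a single count
#' for presence labels. Cells not covered by any count are rendered as
#' normal neutrophils. The default emulates the extreme imbalance of a
#' real labelled-smear cohort (e.g. 46/77/11 DG cells among 1797, a large
#' immature-granulocyte pool, few megakaryocytes).
#'
#' @param n_cells total number of cells.
#' @param label_counts named list of planted frequencies (see above).
#' @param field_size c(height, width) of generated field images.
#' @param max_overlap maximum allowed pairwise overlap fraction of placed
#'   crop rectangles (0 = disjoint).
#' @param n_rbc number of enucleate red-cell distractor blobs per field.
#' @param max_attempts placement attempts per cell before failing.
#' @param stain_noise per-pixel noise sd passed to every cell.
#' @param seed master seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 1797L,
                            label_counts = list(
                              DG = c(46L, 77L, 11L),
                              HS = c(4L, 12L, 22L),
                              IG = 440L, NE = 392L, LYM = 78L, NM = 9L),
                            field_size = c(384L, 512L),
                            max_overlap = 0, n_rbc = 0L,
                            max_attempts = 500L, stain_noise = 0.01,
                            seed = 1L) {
  counts <- unlist(label_counts)
  if (any(counts < 0)) stop("frequencies must be non-negative",
                            call. = FALSE)
  if (sum(counts) > n_cells) {
    stop("label_counts sum to ", sum(counts), " > n_cells = ", n_cells,
         call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 label_counts = label_counts,
                 field_size = as.integer(field_size),
                 max_overlap = max_overlap, n_rbc = as.integer(n_rbc),
                 max_attempts = as.integer(max_attempts),
                 stain_noise = stain_noise, seed = as.integer(seed)),
            class = "population_spec")
}

# Expand a population spec into one (label, grade) assignment per cell,
# shuffled with the spec's seed.
population_assignments <- function(spec, schema) {
  labels <- character(0); grades <- integer(0)
  for (ab in names(spec$label_counts)) {
    idx <- schema_index(schema, ab)
    cnt <- spec$label_counts[[ab]]
    if (length(cnt) == 1L && schema$labels$max_grade[idx] == 1L) {
      labels <- c(labels, rep(ab, cnt)); grades <- c(grades, rep(1L, cnt))
    } else {
      for (g in seq_along(cnt)) {
        if (g > schema$labels$max_grade[idx]) {
          stop("grade ", g, " exceeds max_grade for label ", ab,
               call. = FALSE)
        }
        labels <- c(labels, rep(ab, cnt[g]))
        grades <- c(grades, rep(as.integer(g), cnt[g]))
      }
    }
  }
  n_rest <- spec$n_cells - length(labels)
  labels <- c(labels, rep("NN", n_rest))
  grades <- c(grades, rep(1L, n_rest))
  ord <- with_seed(spec$seed, sample.int(length(labels)))
  data.frame(label = labels[ord], grade = grades[ord],
             stringsAsFactors = FALSE)
}

params_for_assignment <- function(label, grade, schema, seed, stain_noise) {
  cat <- schema$labels$category[schema_index(schema, label)]
  if (label == "DG") {
    cell_params("granulocyte", dg_grade = grade, seed = seed,
                stain_noise = stain_noise)
  } else if (label == "HS") {
    cell_params("granulocyte", dg_grade = 0L, lobe_count = 1L, seed = seed,
                stain_noise = stain_noise, target_label = "HS",
                target_grade = grade)
  } else {
    cell_params(cat, dg_grade = 0L, seed = seed, stain_noise = stain_noise,
                target_label = label, target_grade = grade)
  }
}

#' Sample a labelled synthetic cell population
#'
#' Renders `spec$n_cells` single-cell crops whose per-label grade counts
#' equal the spec's frequencies exactly, shuffled with the spec's seed.
#'
#' @param spec a [population_spec()].
#' @param schema label schema.
#' @return a `cell_dataset`.
#' @export
sample_population <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "population_spec"))
  asg <- population_assignments(spec, schema)
  seeds <- split_seed(spec$seed, nrow(asg))
  items <- lapply(seq_len(nrow(asg)), function(i) {
    p <- params_for_assignment(asg$label[i], asg$grade[i], schema,
                               seeds[i], spec$stain_noise)
    render_cell(p, schema, id = sprintf("cell%05d", i))
  })
  cell_dataset(schema, items)
}

#' Render a synthetic field image with ground truth
#'
#' Places the spec's cells (and optional enucleate red-cell distractors) on
#' a smear background at non-overlapping positions, recording ground-truth
#' boxes. Cropping a returned box out of the field reproduces the
#' stand-alone crop pixel for pixel.
#'
#' @param spec a [population_spec()].
#' @param schema label schema.
#' @return list with `field` (a [field_image()]; cell boxes are tagged
#'   applicable, red-cell boxes not) and `dataset` (the ground-truth crops,
#'   provenance boxes filled in).
#' @export
render_field <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "population_spec"))
  h <- spec$field_size[1]; w <- spec$field_size[2]
  field <- with_seed(spec$seed + 7L, quantize_raster(render_background(h,
                                                                       w)))
  asg <- population_assignments(spec, schema)
  seeds <- split_seed(spec$seed, nrow(asg) + spec$n_rbc + 1L)
  items <- lapply(seq_len(nrow(asg)), function(i) {
    p <- params_for_assignment(asg$label[i], asg$grade[i], schema,
                               seeds[i], spec$stain_noise)
    render_cell(p, schema, id = sprintf("cell%05d", i))
  })
  rbcs <- lapply(seq_len(spec$n_rbc),
                 function(i) render_rbc(seed = seeds[nrow(asg) + i]))
  pseeds <- split_seed(seeds[length(seeds)],
                       length(items) + length(rbcs) + 1L)

  rects <- list()  # placed rectangles, 0-based (x, y, w, h)
  place <- function(ch, cw, rng_seed) {
    with_seed(rng_seed, {
      for (att in seq_len(spec$max_attempts)) {
        x <- sample.int(w - cw + 1L, 1L) - 1L
        y <- sample.int(h - ch + 1L, 1L) - 1L
        cand <- c(x, y, cw, ch)
        ok <- TRUE
        for (r2 in rects) {
          ix <- max(0, min(cand[1] + cand[3], r2[1] + r2[3]) -
                      max(cand[1], r2[1]))
          iy <- max(0, min(cand[2] + cand[4], r2[2] + r2[4]) -
                      max(cand[2], r2[2]))
          ov <- (ix * iy) / min(cand[3] * cand[4], r2[3] * r2[4])
          if (ov > spec$max_overlap) { ok <- FALSE; break }
        }
        if (ok) return(cand)
      }
      stop("could not place cell after ", spec$max_attempts,
           " attempts; reduce n_cells or enlarge the field", call. = FALSE)
    })
  }

  boxes <- list()
  for (i in seq_along(items)) {
    cr <- items[[i]]$raster
    rect <- place(raster_height(cr), raster_width(cr), pseeds[i])
    rects[[length(rects) + 1L]] <- rect
    field[rect[2] + seq_len(rect[4]), rect[1] + seq_len(rect[3]), ] <- cr
    b <- bounding_box(rect[1], rect[2], rect[3], rect[4], applicable = TRUE)
    boxes[[length(boxes) + 1L]] <- b
    items[[i]]$provenance$box <- b
    items[[i]]$provenance$field <- "synthetic-field"
  }
  for (j in seq_along(rbcs)) {
    cr <- rbcs[[j]]
    rect <- place(raster_height(cr), raster_width(cr),
                  pseeds[length(items) + j])
    rects[[length(rects) + 1L]] <- rect
    field[rect[2] + seq_len(rect[4]), rect[1] + seq_len(rect[3]), ] <- cr
    boxes[[length(boxes) + 1L]] <- bounding_box(rect[1], rect[2], rect[3],
                                                rect[4], applicable = FALSE)
  }
  list(field = field_image(field, boxes,
                           source_id = list(smear = "synthetic",
                                            field = "synthetic-field")),
       dataset = cell_dataset(schema, items))
}
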