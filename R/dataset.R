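# Datasets of labelled single-cell images, and their on-disk layout:
#   <dir>/images/<id>.png   single-cell crops (8-bit RGB PNG)
#   <dir>/grades.csv        image_id + one integer column per label
#   <dir>/boxes.json        COCO-style detection JSON (provenance boxes)
#   <dir>/schema.csv        the label vocabulary
#   <dir>/manifest.json     file listing + item count
# Missing grade columns mean grade 0 (morphologists label positively);
# unknown columns are rejected.

#' Construct a bounding box
#'
#' Boxes are 0-based, top-left origin, half-open:
#' [x, x + width) x [y, y + height), matching COCO.
#'
#' @param x,y top-left corner (pixels, 0-based).
#' @param width,height box size in pixels (> 0).
#' @param applicable is the boxed object a nucleated cell of interest?
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, width, height, applicable = TRUE) {
  if (width <= 0 || height <= 0) {
    stop("bounding box must have positive width and height", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 applicable = isTRUE(applicable)),
            class = "bounding_box")
}

box_in_bounds <- function(box, raster) {
  box$x >= 0 && box$y >= 0 &&
    box$x + box$width <= raster_width(raster) &&
    box$y + box$height <= raster_height(raster)
}

#' Construct a field image
#'
#' A full microscope photograph of a smear region plus its cell boxes.
#'
#' @param raster (h, w, 3) array in [0, 1].
#' @param boxes list of [bounding_box()].
#' @param source_id list or character identifying smear/field provenance.
#' @return object of class `field_image`.
#' @export
field_image <- function(raster, boxes = list(), source_id = list()) {
  assert_raster(raster)
  for (b in boxes) {
    if (!inherits(b, "bounding_box")) stop("boxes must be bounding_box")
    if (!box_in_bounds(b, raster)) {
      stop("bounding box (", b$x, ",", b$y, ",", b$width, ",", b$height,
           ") exceeds field bounds", call. = FALSE)
    }
  }
  structure(list(raster = raster, boxes = boxes, source_id = source_id),
            class = "field_image")
}

#' Construct a labelled image
#'
#' A single-cell crop paired with its grade vector and provenance.
#'
#' @param id unique item identifier (character).
#' @param raster (h, w, 3) single-cell crop.
#' @param target `grade_vector` (integer-valued for human labels), or NULL
#'   for unlabelled crops fresh from the detector.
#' @param schema the `label_schema` the target conforms to.
#' @param provenance list with optional `smear`, `field`, `box` entries.
#' @param revision iteration index of the last label change.
#' @param history list of prior revision records.
#' @return object of class `labelled_image`.
#' @export
labelled_image <- function(id, raster, target = NULL, schema = NULL,
                           provenance = list(), revision = 0L,
                           history = list()) {
  assert_raster(raster)
  if (!is.null(target)) {
    stopifnot(!is.null(schema))
    validate_grades(unclass(target), schema, what = paste0("item ", id))
  }
  structure(list(id = as.character(id), raster = raster, target = target,
                 provenance = provenance, revision = as.integer(revision),
                 history = history),
            class = "labelled_image")
}

#' Construct a dataset of labelled images
#'
#' @param schema a `label_schema`.
#' @param items list of [labelled_image()] with unique ids.
#' @return object of class `cell_dataset`.
#' @export
cell_dataset <- function(schema, items = list()) {
  ids <- vapply(items, function(it) it$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate item id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(items) <- ids
  for (it in items) {
    if (!is.null(it$target)) {
      validate_grades(unclass(it$target), schema,
                      what = paste0("item ", it$id))
    }
  }
  structure(list(schema = schema, items = items), class = "cell_dataset")
}

#' @export
length.cell_dataset <- function(x) length(x$items)

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset: ", length(x$items), " labelled images, schema ",
      x$schema$version, " (", length(x$schema), " labels)\n", sep = "")
  invisible(x)
}

#' Matrix of targets of a dataset
#' @param d a `cell_dataset`.
#' @return numeric matrix, items x labels, rownames = item ids.
#' @export
target_matrix <- function(d) {
  abbr <- d$schema$labels$abbreviation
  m <- t(vapply(d$items, function(it) {
    if (is.null(it$target)) rep(NA_real_, length(abbr)) else
      as.numeric(it$target)
  }, numeric(length(abbr))))
  colnames(m) <- abbr
  rownames(m) <- names(d$items)
  m
}

# COCO helpers -----------------------------------------------------------

coco_from_items <- function(items) {
  imgs <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    list(id = i, file_name = paste0(it$id, ".png"),
         width = raster_width(it$raster), height = raster_height(it$raster),
         item_id = it$id,
         smear = it$provenance$smear, field = it$provenance$field)
  })
  anns <- list()
  for (i in seq_along(items)) {
    b <- items[[i]]$provenance$box
    if (!is.null(b)) {
      anns[[length(anns) + 1L]] <- list(
        id = length(anns) + 1L, image_id = i,
        bbox = c(b$x, b$y, b$width, b$height),
        category_id = if (isTRUE(b$applicable)) 1L else 2L)
    }
  }
  list(images = imgs, annotations = anns,
       categories = list(list(id = 1L, name = "applicable"),
                         list(id = 2L, name = "not_applicable")))
}

#' Write / read boxes as COCO-style detection JSON
#'
#' @param boxes list of [bounding_box()].
#' @param path file path.
#' @param image_meta optional list describing the source image.
#' @return `read_coco_boxes` returns a list of `bounding_box`.
#' @export
write_coco_boxes <- function(boxes, path, image_meta = list(id = 1L)) {
  anns <- lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    list(id = i, image_id = image_meta$id,
         bbox = c(b$x, b$y, b$width, b$height),
         category_id = if (isTRUE(b$applicable)) 1L else 2L)
  })
  obj <- list(images = list(image_meta), annotations = anns,
              categories = list(list(id = 1L, name = "applicable"),
                                list(id = 2L, name = "not_applicable")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_boxes
#' @export
read_coco_boxes <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed COCO JSON in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  lapply(obj$annotations, function(a) {
    bb <- unlist(a$bbox)
    if (length(bb) != 4L) {
      stop("malformed bbox in ", path, " (annotation id ", a$id, ")",
           call. = FALSE)
    }
    bounding_box(bb[1], bb[2], bb[3], bb[4],
                 applicable = is.null(a$category_id) || a$category_id == 1L)
  })
}

# load / save ------------------------------------------------------------

#' Save a dataset to a directory
#'
#' Writes PNG crops, a COCO box file, a grade CSV and the schema CSV; the
#' pair [load_dataset()] / `save_dataset` round-trips bit-exactly for
#' rasters and exactly for grades and boxes.
#'
#' @param d a `cell_dataset`.
#' @param out_dir output directory (created if missing).
#' @return path to the written `manifest.json`.
#' @export
save_dataset <- function(d, out_dir) {
  stopifnot(inherits(d, "cell_dataset"))
  ids <- names(d$items)
  if (anyDuplicated(ids)) {
    stop("duplicate item id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  for (it in d$items) {
    write_raster(it$raster, file.path(out_dir, "images",
                                      paste0(it$id, ".png")))
  }
  abbr <- d$schema$labels$abbreviation
  tm <- target_matrix(d)
  grades <- data.frame(image_id = rownames(tm), check.names = FALSE)
  for (a in abbr) grades[[a]] <- tm[, a]
  utils::write.csv(grades, file.path(out_dir, "grades.csv"),
                   row.names = FALSE)
  write_schema_csv(d$schema, file.path(out_dir, "schema.csv"))
  jsonlite::write_json(coco_from_items(d$items),
                       file.path(out_dir, "boxes.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    n_items = length(d$items),
    schema_version = d$schema$version,
    files = list(images = file.path("images", paste0(ids, ".png")),
                 grades = "grades.csv", boxes = "boxes.json",
                 schema = "schema.csv"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Load a dataset from a directory
#'
#' @param image_dir directory of PNG crops, or a dataset directory written
#'   by [save_dataset()] (then the other paths default to its layout).
#' @param annotations COCO JSON of provenance boxes (optional).
#' @param labels grade CSV with header `image_id,<abbrev>,...`; missing
#'   label columns default to grade 0.
#' @param schema a `label_schema` or path to a schema CSV.
#' @return a `cell_dataset`.
#' @export
load_dataset <- function(image_dir,
                         annotations = file.path(image_dir, "boxes.json"),
                         labels = file.path(image_dir, "grades.csv"),
                         schema = file.path(image_dir, "schema.csv")) {
  root <- image_dir
  img_dir <- if (dir.exists(file.path(root, "images")))
    file.path(root, "images") else root
  if (is.character(schema)) {
    schema <- if (file.exists(schema)) read_schema_csv(schema) else
      default_schema()
  }
  abbr <- schema$labels$abbreviation

  grades <- NULL
  if (file.exists(labels)) {
    grades <- tryCatch(
      utils::read.csv(labels, stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e) stop("malformed grade CSV ", labels, ": ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(grades) > 0 && !"image_id" %in% names(grades)) {
      stop("grade CSV ", labels, " lacks an image_id column", call. = FALSE)
    }
    unknown <- setdiff(names(grades), c("image_id", abbr))
    if (length(unknown)) {
      stop("grade CSV ", labels, " has unknown label column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  box_by_item <- list()
  if (file.exists(annotations)) {
    obj <- tryCatch(jsonlite::read_json(annotations),
                    error = function(e) stop("malformed COCO JSON ",
                                             annotations, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    img_index <- list()
    for (im in obj$images) {
      iid <- if (!is.null(im$item_id)) im$item_id else
        sub("\\.png$", "", im$file_name)
      img_index[[as.character(im$id)]] <-
        list(item_id = iid, smear = im$smear, field = im$field)
    }
    for (a in obj$annotations) {
      meta <- img_index[[as.character(a$image_id)]]
      if (is.null(meta)) next
      bb <- unlist(a$bbox)
      box_by_item[[meta$item_id]] <- list(
        box = bounding_box(bb[1], bb[2], bb[3], bb[4],
                           applicable = a$category_id == 1L),
        smear = meta$smear, field = meta$field)
    }
  }

  files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  items <- lapply(files, function(f) {
    id <- sub("\\.png$", "", basename(f))
    raster <- read_raster(f)
    v <- stats::setNames(numeric(length(abbr)), abbr)
    if (!is.null(grades) && nrow(grades) > 0) {
      row <- grades[grades$image_id == id, , drop = FALSE]
      if (nrow(row) == 1) {
        present <- intersect(names(row), abbr)
        v[present] <- as.numeric(row[1, present])
      }
    }
    validate_grades(v, schema, integer = TRUE, what = paste0("cell ", id))
    prov <- box_by_item[[id]]
    labelled_image(id, raster,
                   target = structure(v, class = "grade_vector"),
                   schema = schema,
                   provenance = list(smear = prov$smear, field = prov$field,
                                     box = prov$box))
  })
  cell_dataset(schema, items)
}

#' Per-label grade counts of a dataset
#'
#' For each label and each grade 1..max_grade, the number of items carrying
#' that integer grade, plus the per-label positive total. The total item
#' count is attached as attribute `n_items`.
#'
#' @param d a `cell_dataset`.
#' @return data.frame with columns `abbreviation`, `category`, `max_grade`,
#'   `grade1`..`gradeG`, `total`.
#' @export
summarize_dataset <- function(d) {
  stopifnot(inherits(d, "cell_dataset"))
  sch <- d$schema$labels
  gmax <- max(sch$max_grade)
  tm <- if (length(d$items)) target_matrix(d) else
    matrix(numeric(0), 0, nrow(sch), dimnames = list(NULL,
                                                     sch$abbreviation))
  out <- sch[, c("abbreviation", "category", "max_grade")]
  for (g in seq_len(gmax)) {
    out[[paste0("grade", g)]] <- vapply(seq_len(nrow(sch)), function(i) {
      if (g > sch$max_grade[i]) 0L else
        sum(tm[, i] == g, na.rm = TRUE)
    }, integer(1))
  }
  out$total <- rowSums(as.matrix(out[, paste0("grade", seq_len(gmax)),
                                     drop = FALSE]))
  attr(out, "n_items") <- length(d$items)
  out
}
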