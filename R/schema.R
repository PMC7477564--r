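# Label schema: the fixed, ordered vocabulary of morphological labels the
# regressor scores. Each label carries a lineage category and a maximum
# grade (3 for ordinal dysplasia scales, 1 for binary presence labels).
# Grade-vector index i always means label i of the schema, so the order is
# persisted with every dataset and model.

#' Lineage categories
#'
#' The four non-overlapping cell categories every label belongs to.
#' @export
CELL_CATEGORIES <- c("erythrocyte", "granulocyte", "megakaryocyte",
                     "not_applicable")

#' Construct a label schema
#'
#' @param labels data.frame with columns `abbreviation`, `name`, `category`,
#'   `max_grade`.
#' @param version free-text schema version string.
#' @return object of class `label_schema`.
#' @export
label_schema <- function(labels, version = "1.0") {
  req <- c("abbreviation", "name", "category", "max_grade")
  if (!all(req %in% names(labels))) {
    stop("schema table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  labels <- as.data.frame(labels)[, req]
  labels$abbreviation <- as.character(labels$abbreviation)
  labels$name <- as.character(labels$name)
  labels$category <- as.character(labels$category)
  labels$max_grade <- as.integer(labels$max_grade)
  if (anyDuplicated(labels$abbreviation)) {
    stop("duplicate label abbreviation: ",
         paste(unique(labels$abbreviation[duplicated(labels$abbreviation)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !labels$category %in% CELL_CATEGORIES
  if (any(bad)) {
    stop("unknown category: ", paste(unique(labels$category[bad]),
                                     collapse = ", "), call. = FALSE)
  }
  if (any(labels$max_grade < 1L)) {
    stop("max_grade must be >= 1", call. = FALSE)
  }
  structure(list(labels = labels, version = as.character(version)),
            class = "label_schema")
}

#' Default 34-label schema
#'
#' The package's standard output vocabulary: 24 ordinal dysplasia labels
#' (graded 0-3) across the erythroid, granulocytic and megakaryocytic
#' lineages, three normal-category labels, the myeloblast presence label,
#' and six not-applicable cell types (all binary). The focused label is DG
#' (decreased granules). Multinuclearity appears in two lineages and is
#' disambiguated as MNE (erythroid) / MNM (megakaryocytic). Alternate
#' vocabularies can be loaded from CSV with [read_schema_csv()].
#'
#' @return a `label_schema` with exactly 34 entries.
#' @export
default_schema <- function() {
  e <- "erythrocyte"; g <- "granulocyte"; m <- "megakaryocyte"
  na <- "not_applicable"
  tab <- rbind(
    c("NE",    "Normal erythroid cells",                     e,  1),
    c("NB",    "Nuclear budding",                            e,  3),
    c("INB",   "Internuclear bridging",                      e,  3),
    c("KR",    "Karyorrhexis",                               e,  3),
    c("MNE",   "Multinuclearity (erythroid)",                e,  3),
    c("RCACC", "Red cell abnormal chromatin clumping",       e,  3),
    c("MC",    "Megaloblastoid change",                      e,  3),
    c("GRC",   "Giant red cell",                             e,  3),
    c("VAC",   "Vacuolization",                              e,  3),
    c("HJB",   "Howell-Jolly bodies",                        e,  3),
    c("NN",    "Normal neutrophils",                         g,  1),
    c("MB",    "Myeloblasts",                                g,  1),
    c("SUL",   "Small size or unusually large size",         g,  3),
    c("HS",    "Nuclear hyposegmentation (pseudo-Pelger-Huet)", g, 3),
    c("HYPES", "Nuclear hypersegmentation",                  g,  3),
    c("DG",    "Decreased granules; agranularity",           g,  3),
    c("PCH",   "Pseudo-Chediak-Higashi granules",            g,  3),
    c("DB",    "Dohle bodies",                               g,  3),
    c("AR",    "Auer rods",                                  g,  3),
    c("DNP",   "Dysplastic non-pseudo-Pelger-Huet",          g,  3),
    c("NP",    "Nuclear projections",                        g,  3),
    c("ACC",   "Abnormal chromatin clumping",                g,  3),
    c("NM",    "Normal megakaryocytes",                      m,  1),
    c("MM",    "Micromegakaryocytes",                        m,  3),
    c("NH",    "Nuclear hypolobation",                       m,  3),
    c("MNM",   "Multinucleation (megakaryocytic)",           m,  3),
    c("LM",    "Large megakaryocyte, hyperlobulated nucleus", m, 3),
    c("MCA",   "Megakaryocyte with cytoplasmic abnormality", m,  3),
    c("RBC",   "Red blood cells",                            na, 1),
    c("IG",    "Immature granulocytes",                      na, 1),
    c("EOS",   "Eosinophils",                                na, 1),
    c("LYM",   "Lymphocytes",                                na, 1),
    c("PC",    "Plasma cells",                               na, 1),
    c("PLT",   "Platelets",                                  na, 1)
  )
  df <- data.frame(abbreviation = tab[, 1], name = tab[, 2],
                   category = tab[, 3], max_grade = as.integer(tab[, 4]),
                   stringsAsFactors = FALSE)
  label_schema(df, version = "default-34")
}

#' @export
length.label_schema <- function(x) nrow(x$labels)

#' @export
print.label_schema <- function(x, ...) {
  cat("label_schema (", x$version, "): ", nrow(x$labels), " labels\n",
      sep = "")
  print(table(x$labels$category))
  invisible(x)
}

#' Position of a label within a schema
#' @param schema a `label_schema`.
#' @param abbreviation label short code, e.g. "DG".
#' @return integer index.
#' @export
schema_index <- function(schema, abbreviation) {
  i <- match(abbreviation, schema$labels$abbreviation)
  if (anyNA(i)) {
    stop("unknown label abbreviation: ",
         paste(abbreviation[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

#' Read / write a schema as CSV
#'
#' CSV columns: `abbreviation,name,category,max_grade`.
#' @param path file path.
#' @param version version string for the loaded schema.
#' @return `read_schema_csv` returns a `label_schema`.
#' @export
read_schema_csv <- function(path, version = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_schema(df, version = version)
}

#' @rdname read_schema_csv
#' @param schema a `label_schema`.
#' @export
write_schema_csv <- function(schema, path) {
  utils::write.csv(schema$labels, path, row.names = FALSE)
  invisible(path)
}

# grade vectors ----------------------------------------------------------

#' Construct a grade vector
#'
#' A grade vector holds one score per schema label, each within
#' [0, max_grade] for its label. Human labels are integers; model outputs
#' are continuous.
#'
#' @param schema a `label_schema`.
#' @param ... named grades, e.g. `DG = 2`; unnamed labels default to 0.
#' @param .values alternatively, a full named or unnamed numeric vector.
#' @param integer require integer grades (human labelling).
#' @return named numeric vector of length `length(schema)` with class
#'   `grade_vector`.
#' @export
grade_vector <- function(schema, ..., .values = NULL, integer = FALSE) {
  abbr <- schema$labels$abbreviation
  if (is.null(.values)) {
    v <- stats::setNames(numeric(length(abbr)), abbr)
    dots <- list(...)
    if (length(dots)) {
      idx <- schema_index(schema, names(dots))
      v[idx] <- unlist(dots)
    }
  } else {
    v <- .values
    if (is.null(names(v))) {
      if (length(v) != length(abbr)) {
        stop("grade vector length ", length(v), " != schema size ",
             length(abbr), call. = FALSE)
      }
      names(v) <- abbr
    } else {
      full <- stats::setNames(numeric(length(abbr)), abbr)
      full[names(v)] <- v  # unknown names caught below
      if (!all(names(v) %in% abbr)) {
        stop("unknown label abbreviation: ",
             paste(setdiff(names(v), abbr), collapse = ", "), call. = FALSE)
      }
      v <- full
    }
  }
  validate_grades(v, schema, integer = integer)
  structure(v, class = "grade_vector")
}

#' Validate grades against a schema
#'
#' @param v named numeric vector over the schema's labels.
#' @param schema a `label_schema`.
#' @param integer require whole-number grades.
#' @param what context string used in error messages (e.g. a cell id).
#' @return `v`, invisibly, if valid; otherwise an error naming the
#'   offending cell and label.
#' @export
validate_grades <- function(v, schema, integer = FALSE, what = "grades") {
  abbr <- schema$labels$abbreviation
  if (length(v) != length(abbr) || !identical(names(v), abbr)) {
    stop(what, ": grade vector does not match schema labels", call. = FALSE)
  }
  mg <- schema$labels$max_grade
  bad <- which(is.na(v) | v < 0 | v > mg)
  if (length(bad)) {
    stop(what, ": grade out of range for label ", abbr[bad[1]], " (value ",
         v[bad[1]], ", max ", mg[bad[1]], ")", call. = FALSE)
  }
  if (integer) {
    ni <- which(v != floor(v))
    if (length(ni)) {
      stop(what, ": non-integer grade for label ", abbr[ni[1]],
           call. = FALSE)
    }
  }
  invisible(v)
}

#' Category of each schema label
#' @param schema a `label_schema`.
#' @return character vector aligned with the schema order.
#' @export
schema_categories <- function(schema) schema$labels$category

#' Maximum grade of each schema label
#' @param schema a `label_schema`.
#' @return integer vector aligned with the schema order.
#' @export
schema_max_grades <- function(schema) schema$labels$max_grade
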