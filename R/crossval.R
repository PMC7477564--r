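# Iterative multi-label stratified k-fold assignment and the
# cross-validation driver. Stratification distributes items so that each
# fold holds approximately the same number of cells of each dysplasia
# type; with labels as rare as a dozen positives this matters -- plain
# random folds routinely leave a fold with none.

#' Iterative multi-label stratified folds
#'
#' Greedy iterative stratification: repeatedly take the label with the
#' fewest remaining unassigned items; hand its items one at a time to the
#' fold with the greatest remaining demand for that label, breaking ties
#' by greatest total remaining demand and then by seeded random draw.
#' Items with no positive label are distributed last by total demand.
#'
#' @param d a `cell_dataset`, or a logical/0-1 membership matrix
#'   (items x labels, rownames = item ids).
#' @param k number of folds (>= 2).
#' @param seed RNG seed driving all tie-breaks and item orderings.
#' @param by_grade stratify on (label, grade) pairs instead of binary
#'   "has label at grade >= 1".
#' @return object of class `fold_assignment`: a named integer vector of
#'   fold indices 0..k-1.
#' @export
iterative_stratified_folds <- function(d, k = 5L, seed = 1L,
                                       by_grade = FALSE) {
  M <- if (inherits(d, "cell_dataset")) {
    tm <- target_matrix(d)
    if (by_grade) {
      cols <- list()
      for (j in seq_len(ncol(tm))) {
        gmax <- max(tm[, j], 0, na.rm = TRUE)
        for (g in seq_len(max(1, floor(gmax)))) {
          cols[[paste0(colnames(tm)[j], ":", g)]] <- as.integer(
            tm[, j] == g)
        }
      }
      mm <- do.call(cbind, cols)
      rownames(mm) <- rownames(tm)
      mm
    } else {
      (tm >= 1) * 1L
    }
  } else {
    as.matrix(d) * 1L
  }
  n <- nrow(M)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("cannot split ", n, " items into ", k, " folds",
                  call. = FALSE)
  M <- M[, colSums(M) > 0, drop = FALSE]
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  fold <- rep(NA_integer_, n)
  # fractional desired counts per fold, decremented as items land
  demand_label <- matrix(rep(colSums(M) / k, each = k), k, ncol(M))
  demand_size <- rep(n / k, k)

  assignment <- with_seed(seed, {
    repeat {
      remaining <- is.na(fold)
      if (!any(remaining)) break
      counts <- colSums(M[remaining, , drop = FALSE])
      if (ncol(M) == 0 || all(counts == 0)) {
        # label-free leftovers: place by total demand
        rem <- which(remaining)
        for (i in rem[sample.int(length(rem))]) {
          best <- which(demand_size == max(demand_size))
          f <- best[sample.int(length(best), 1)]
          fold[i] <- f
          demand_size[f] <- demand_size[f] - 1
        }
        break
      }
      pos <- which(counts > 0)
      l <- pos[counts[pos] == min(counts[pos])]
      if (length(l) > 1) l <- l[sample.int(length(l), 1)]
      items <- which(remaining & M[, l] == 1)
      for (i in items[sample.int(length(items))]) {
        dl <- demand_label[, l]
        best <- which(dl == max(dl))
        if (length(best) > 1) {
          ds <- demand_size[best]
          best <- best[ds == max(ds)]
        }
        f <- best[sample.int(length(best), 1)]
        fold[i] <- f
        pos <- which(M[i, ] == 1)
        demand_label[f, pos] <- demand_label[f, pos] - 1
        demand_size[f] <- demand_size[f] - 1
      }
    }
    fold
  })
  structure(stats::setNames(as.integer(assignment - 1L), ids),
            class = "fold_assignment", k = k)
}

#' Write / read a fold assignment as CSV
#' @param folds a `fold_assignment`.
#' @param path CSV path (columns `image_id,fold`).
#' @return `read_fold_csv` returns a `fold_assignment`.
#' @export
write_fold_csv <- function(folds, path) {
  utils::write.csv(data.frame(image_id = names(folds),
                              fold = as.integer(folds)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_csv
#' @export
read_fold_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(stats::setNames(as.integer(df$fold), df$image_id),
            class = "fold_assignment",
            k = length(unique(df$fold)))
}

#' Per-label fold count table
#' @param d dataset or membership matrix as in
#'   [iterative_stratified_folds()].
#' @param folds a `fold_assignment`.
#' @return matrix folds x labels of positive counts.
#' @export
fold_label_counts <- function(d, folds) {
  M <- if (inherits(d, "cell_dataset")) (target_matrix(d) >= 1) * 1L else
    as.matrix(d) * 1L
  k <- attr(folds, "k")
  t(vapply(seq_len(k) - 1L, function(f) {
    colSums(M[names(folds)[folds == f], , drop = FALSE])
  }, numeric(ncol(M))))
}

#' Cross-validate the grading pipeline
#'
#' Stratified folds; for each fold, a model is trained on the remaining
#' folds and predicts the held-out cells through the rotation ensemble, so
#' every item is predicted exactly once by a model that never saw it.
#'
#' @param d a labelled `cell_dataset`.
#' @param k number of folds.
#' @param mc,tc,ac,ec model / training / augmentation / ensemble configs.
#' @param w loss weights.
#' @param seed seed for stratification; per-fold training seeds derive
#'   from it.
#' @param verbose print fold progress.
#' @return list with `predictions` (data.frame: item_id, fold, true_dg,
#'   dg_score_raw, dg_score, category, final_grade), `folds`, and
#'   `models` (one per fold).
#' @export
run_cross_validation <- function(d, k = 5L, mc = model_config(),
                                 tc = train_config(),
                                 ac = augment_config(),
                                 ec = ensemble_config(),
                                 w = loss_weights(mc$schema),
                                 seed = 1L, verbose = FALSE) {
  stopifnot(inherits(d, "cell_dataset"))
  folds <- iterative_stratified_folds(d, k = k, seed = seed)
  fseeds <- split_seed(seed, k)
  schema <- d$schema
  dg_true <- target_matrix(d)[, "DG"]
  models <- vector("list", k)
  rows <- list()
  for (f in seq_len(k) - 1L) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    if (length(test_ids) == 0 || length(train_ids) == 0) {
      stop("fold ", f, " is empty", call. = FALSE)
    }
    if (verbose) message("fold ", f, ": training on ", length(train_ids),
                         ", predicting ", length(test_ids))
    dtr <- cell_dataset(schema, unname(d$items[train_ids]))
    tcf <- tc; tcf$seed <- fseeds[f + 1L]
    fit <- train_model(dtr, mc, tcf, ac, w = w)
    models[[f + 1L]] <- fit$model
    for (id in test_ids) {
      pr <- predict_cell(fit$model, d$items[[id]]$raster, ac, ec)
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = id, fold = f, true_dg = as.integer(dg_true[id]),
        dg_score_raw = pr$dg_score_raw, dg_score = pr$dg_score,
        category = pr$category, final_grade = pr$final_grade,
        stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, rows)
  rownames(preds) <- NULL
  list(predictions = preds, folds = folds, models = models)
}
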