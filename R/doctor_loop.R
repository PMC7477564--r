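# Doctor-in-the-loop label revision. The model's disagreements with the
# human labels are queued for expert review together with the raw ensemble
# scores; the experts adjudicate each one (ai_wrong / human_wrong), their
# corrections overwrite the dataset labels with full append-only history,
# and the model is retrained on the improved labels in the next iteration.

#' Build the audit queue of model-label disagreements
#'
#' One record per cell whose final predicted DG grade differs from its
#' labelled grade, sorted by descending |difference| so the severest
#' disagreements are reviewed first.
#'
#' @param d a labelled `cell_dataset`.
#' @param predictions pooled prediction data.frame
#'   (from [run_cross_validation()]).
#' @return data.frame of class `audit_queue` with columns `item_id`,
#'   `true_dg`, `final_grade`, `diff`, `dg_score_raw`, `category`.
#' @export
build_audit_queue <- function(d, predictions) {
  stopifnot(inherits(d, "cell_dataset"))
  q <- predictions[predictions$final_grade != predictions$true_dg,
                   c("item_id", "true_dg", "final_grade", "dg_score_raw",
                     "category"), drop = FALSE]
  q$diff <- abs(q$true_dg - q$final_grade)
  q <- q[order(-q$diff), c("item_id", "true_dg", "final_grade", "diff",
                           "dg_score_raw", "category")]
  rownames(q) <- NULL
  class(q) <- c("audit_queue", "data.frame")
  q
}

#' Write an audit queue as CSV for visual review
#' @param q an `audit_queue`.
#' @param path CSV path.
#' @param image_dir optional directory prefix recorded as image paths.
#' @export
write_audit_csv <- function(q, path, image_dir = "images") {
  out <- as.data.frame(q)
  out$image_path <- file.path(image_dir, paste0(out$item_id, ".png"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Apply expert revisions to a dataset
#'
#' Completed audit records carry a human verdict per disagreement:
#' `ai_wrong` upholds the label, `human_wrong` replaces it. Revisions
#' overwrite the named label's grade, bump the item's revision index and
#' append to its history, so any prior labelling state is reconstructible
#' ([revert_revisions()]). Re-applying the same records is a no-op.
#'
#' @param d a `cell_dataset`.
#' @param records data.frame with columns `item_id`, `label`, `new_grade`,
#'   `verdict` (one of "ai_wrong", "human_wrong").
#' @return list with `dataset` (new version; attribute `iteration`
#'   incremented) and `stats` (`n_audited`, `n_revised`,
#'   `fraction_revised` among audited items).
#' @export
apply_revisions <- function(d, records) {
  stopifnot(inherits(d, "cell_dataset"))
  req <- c("item_id", "label", "new_grade", "verdict")
  if (!all(req %in% names(records))) {
    stop("revision records need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad_v <- setdiff(unique(records$verdict), c("ai_wrong", "human_wrong"))
  if (length(bad_v)) stop("unknown verdict: ", bad_v[1], call. = FALSE)
  unknown <- setdiff(records$item_id, names(d$items))
  if (length(unknown)) {
    stop("revision references unknown item: ", unknown[1], call. = FALSE)
  }
  iteration <- (attr(d, "iteration") %||% 0L) + 1L
  revised_items <- character(0)
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (rec$verdict != "human_wrong") next
    it <- d$items[[rec$item_id]]
    idx <- schema_index(d$schema, rec$label)
    old <- as.numeric(it$target)[idx]
    v <- unclass(it$target)
    v[idx] <- rec$new_grade
    validate_grades(v, d$schema, integer = TRUE,
                    what = paste0("revision of item ", rec$item_id))
    if (old == rec$new_grade) next
    it$target <- structure(v, class = "grade_vector")
    it$revision <- it$revision + 1L
    it$history[[length(it$history) + 1L]] <-
      list(iteration = iteration, label = rec$label, old_grade = old,
           new_grade = rec$new_grade)
    d$items[[rec$item_id]] <- it
    revised_items <- union(revised_items, rec$item_id)
  }
  attr(d, "iteration") <- iteration
  n_aud <- length(unique(records$item_id))
  list(dataset = d,
       stats = list(n_audited = n_aud,
                    n_revised = length(revised_items),
                    fraction_revised = if (n_aud) length(revised_items) /
                      n_aud else NA_real_))
}

#' Reconstruct the unrevised labels of a dataset
#'
#' Unwinds every item's revision history back to the original grades,
#' demonstrating that dataset versions form a reconstructible append-only
#' chain.
#'
#' @param d a `cell_dataset` that went through [apply_revisions()].
#' @return the dataset with original grades, empty histories, revision 0.
#' @export
revert_revisions <- function(d) {
  for (id in names(d$items)) {
    it <- d$items[[id]]
    if (!length(it$history)) next
    v <- unclass(it$target)
    for (h in rev(it$history)) {
      v[schema_index(d$schema, h$label)] <- h$old_grade
    }
    it$target <- structure(v, class = "grade_vector")
    it$revision <- 0L
    it$history <- list()
    d$items[[id]] <- it
  }
  attr(d, "iteration") <- NULL
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
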