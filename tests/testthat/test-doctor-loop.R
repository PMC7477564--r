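loop_fixture <- function() {
  sch <- default_schema()
  spec <- population_spec(n_cells = 20,
                          label_counts = list(DG = c(3, 3, 2)), seed = 23)
  d <- sample_population(spec, sch)
  true_dg <- as.integer(target_matrix(d)[, "DG"])
  # synthetic pooled predictions: 3 planted disagreements
  preds <- data.frame(item_id = names(d$items), fold = 0L,
                      true_dg = true_dg,
                      dg_score_raw = true_dg + 0.1,
                      dg_score = true_dg + 0.1,
                      category = "granulocyte",
                      final_grade = true_dg,
                      stringsAsFactors = FALSE)
  for (i in c(2L, 5L, 9L)) {
    preds$final_grade[i] <- (preds$true_dg[i] + 2L) %% 4L
  }
  disag <- which(preds$final_grade != preds$true_dg)
  list(d = d, preds = preds, disag = disag)
}

test_that("the audit queue holds exactly the disagreements, severest first", {
  fx <- loop_fixture()
  q <- build_audit_queue(fx$d, fx$preds)
  expect_equal(nrow(q), length(fx$disag))
  expect_setequal(q$item_id, fx$preds$item_id[fx$disag])
  expect_true(all(q$final_grade != q$true_dg))
  expect_true(all(diff(q$diff) <= 0))
  # raw continuous scores ride along for the reviewer
  expect_true("dg_score_raw" %in% names(q))
  # perfect agreement produces an empty queue
  agree <- fx$preds; agree$final_grade <- agree$true_dg
  expect_equal(nrow(build_audit_queue(fx$d, agree)), 0L)
})

test_that("revisions overwrite grades with history; upheld labels stay put", {
  fx <- loop_fixture()
  ids <- fx$preds$item_id[fx$disag]
  old_g <- as.integer(target_matrix(fx$d)[ids, "DG"])
  verdicts <- c("human_wrong", "ai_wrong", "human_wrong")
  records <- data.frame(
    item_id = ids,
    label = "DG",
    new_grade = ifelse(verdicts == "human_wrong", (old_g + 1L) %% 4L,
                       old_g),
    verdict = verdicts,
    stringsAsFactors = FALSE)
  out <- apply_revisions(fx$d, records)
  d2 <- out$dataset
  expect_equal(out$stats$n_audited, 3L)
  # ai_wrong verdicts leave the dataset unchanged for that item
  expect_equal(target_matrix(d2)[ids[2], "DG"],
               target_matrix(fx$d)[ids[2], "DG"])
  expect_equal(d2$items[[ids[2]]]$revision, 0L)
  # human_wrong verdicts overwrite and bump the revision index
  expect_equal(unname(target_matrix(d2)[ids[1], "DG"]),
               (old_g[1] + 1) %% 4)
  expect_equal(d2$items[[ids[1]]]$revision, 1L)
  expect_equal(d2$items[[ids[1]]]$history[[1]]$old_grade, old_g[1])
  # item membership is invariant
  expect_equal(names(d2$items), names(fx$d$items))
  expect_equal(out$stats$n_revised, 2L)
  expect_equal(out$stats$fraction_revised, 2 / 3)
  # re-applying the same records is a no-op on the grades
  out2 <- apply_revisions(d2, records)
  expect_identical(target_matrix(out2$dataset), target_matrix(d2))
  expect_equal(out2$stats$n_revised, 0L)
  # iteration counter increments per call
  expect_equal(attr(out2$dataset, "iteration"), 2L)
})

test_that("all-upheld audits revise nothing", {
  fx <- loop_fixture()
  ids <- fx$preds$item_id[fx$disag]
  records <- data.frame(item_id = ids, label = "DG", new_grade = 0L,
                        verdict = "ai_wrong", stringsAsFactors = FALSE)
  out <- apply_revisions(fx$d, records)
  expect_identical(target_matrix(out$dataset), target_matrix(fx$d))
  expect_equal(out$stats$fraction_revised, 0)
})

test_that("the revision chain reconstructs any prior labelling state", {
  fx <- loop_fixture()
  ids <- fx$preds$item_id[fx$disag]
  old1 <- as.integer(target_matrix(fx$d)[ids[1], "DG"])
  r1 <- data.frame(item_id = ids[1], label = "DG",
                   new_grade = (old1 + 1L) %% 4L,
                   verdict = "human_wrong", stringsAsFactors = FALSE)
  r2 <- data.frame(item_id = ids[1], label = "DG",
                   new_grade = (old1 + 2L) %% 4L,
                   verdict = "human_wrong", stringsAsFactors = FALSE)
  d1 <- apply_revisions(fx$d, r1)$dataset
  d2 <- apply_revisions(d1, r2)$dataset
  expect_equal(d2$items[[ids[1]]]$revision, 2L)
  d0 <- revert_revisions(d2)
  expect_identical(target_matrix(d0), target_matrix(fx$d))
  expect_equal(d0$items[[ids[1]]]$revision, 0L)
})

test_that("invalid revisions are rejected", {
  fx <- loop_fixture()
  bad_grade <- data.frame(item_id = fx$preds$item_id[1], label = "DG",
                          new_grade = 9L, verdict = "human_wrong")
  expect_error(apply_revisions(fx$d, bad_grade), "out of range")
  bad_item <- data.frame(item_id = "nope", label = "DG", new_grade = 1L,
                         verdict = "human_wrong")
  expect_error(apply_revisions(fx$d, bad_item), "unknown item")
  bad_verdict <- data.frame(item_id = fx$preds$item_id[1], label = "DG",
                            new_grade = 1L, verdict = "dunno")
  expect_error(apply_revisions(fx$d, bad_verdict), "verdict")
})
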