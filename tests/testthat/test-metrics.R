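test_that("confusion matrix is row-normalized with hand-checked entries", {
  ph <- gait_phases()
  # perfect predictions -> identity
  truth <- rep(ph, times = c(3, 4, 2, 1))
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(cm$C), diag(4))

  # 2-of-4 example: true=[P1,P1,P2,P2], pred=[P1,P2,P2,P2]
  tr <- ph[c(1, 1, 2, 2)]
  pr <- ph[c(1, 2, 2, 2)]
  cm <- confusion_matrix(tr, pr)
  expect_equal(cm$C[1, 1], 0.5)
  expect_equal(cm$C[1, 2], 0.5)
  expect_equal(cm$C[2, 2], 1.0)
  # rows with support sum to 1; columns need not
  expect_equal(unname(rowSums(cm$C)[1:2]), c(1, 1))
  expect_gt(sum(cm$C[, 2]), 1)
  # empty classes flagged, all-zero rows
  expect_identical(cm$empty_rows, ph[3:4])
  expect_true(all(cm$C[3:4, ] == 0))

  expect_error(confusion_matrix(tr, pr[-1]), "length")
})

test_that("accuracy is correct/total and matches the confusion diagonal", {
  ph <- gait_phases()
  set.seed(7)
  tr <- sample(ph, 10, replace = TRUE)
  pr <- tr
  pr[c(2, 5)] <- ph[(match(pr[c(2, 5)], ph)) %% 4 + 1]
  expect_equal(accuracy(tr, pr)$overall, 0.8)
  expect_equal(accuracy(tr, tr)$overall, 1.0)
  expect_error(accuracy(character(0), character(0)), "empty")

  # overall accuracy == sum_i n_i c_ii / sum_i n_i, on random label sets
  for (k in 1:20) {
    tr <- sample(ph, 60, replace = TRUE)
    pr <- sample(ph, 60, replace = TRUE)
    cm <- confusion_matrix(tr, pr)
    expect_equal(accuracy(tr, pr)$overall,
                 sum(cm$support * diag(cm$C)) / sum(cm$support))
  }
})

test_that("macro metrics follow the harmonic-of-macro-means definition", {
  ph <- gait_phases()
  perfect <- macro_metrics(rep(ph, 5), rep(ph, 5))
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
  expect_equal(perfect$macro_f1, 1)

  # two-class worked example, verified with the brute-force oracle
  tr <- c("P1", "P1", "P2", "P2")
  pr <- c("P1", "P2", "P2", "P2")
  mm <- macro_metrics(tr, pr, levels = c("P1", "P2"))
  orc <- oracle_macro(tr, pr, c("P1", "P2"))
  expect_equal(mm$macro_precision, (1 + 2 / 3) / 2)
  expect_equal(mm$macro_recall, 0.75)
  expect_equal(mm$macro_f1, 2 * (5 / 6) * 0.75 / ((5 / 6) + 0.75))
  expect_equal(mm$macro_f1, orc$macro_f1)
  # the harmonic-of-means aggregate differs from the mean of per-class F1s
  expect_false(isTRUE(all.equal(mm$macro_f1, mm$mean_class_f1)))
})

test_that("a class never predicted gets precision 0 with a warning", {
  ph <- gait_phases()
  tr <- ph[c(1, 2, 3, 4)]
  pr <- ph[c(1, 2, 3, 1)]  # SW-R never predicted
  expect_warning(mm <- macro_metrics(tr, pr), "precision")
  expect_equal(unname(mm$precision["SW-R"]), 0)
})

test_that("metrics agree with brute-force oracles on random label vectors", {
  ph <- gait_phases()
  set.seed(123)
  for (k in 1:50) {
    n <- sample(5:80, 1)
    tr <- sample(ph, n, replace = TRUE)
    pr <- sample(ph, n, replace = TRUE)
    mm <- suppressWarnings(macro_metrics(tr, pr))
    orc <- oracle_macro(tr, pr, ph)
    expect_equal(mm$macro_precision, orc$macro_precision, tolerance = 1e-12)
    expect_equal(mm$macro_recall, orc$macro_recall, tolerance = 1e-12)
    expect_equal(mm$macro_f1, orc$macro_f1, tolerance = 1e-12)
    cm <- confusion_matrix(tr, pr)
    expect_equal(cm$C, oracle_confusion(tr, pr, ph)$C, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("metrics are invariant to joint permutation and to relabeling", {
  ph <- gait_phases()
  set.seed(9)
  tr <- sample(ph, 100, replace = TRUE)
  pr <- sample(ph, 100, replace = TRUE)
  idx <- sample(100)
  a <- suppressWarnings(metrics_report(tr, pr))
  b <- suppressWarnings(metrics_report(tr[idx], pr[idx]))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$macro_f1, b$macro_f1)
  expect_equal(a$confusion, b$confusion)

  # accuracy invariant under a fixed bijection of the class labels
  relab <- setNames(ph[c(3, 1, 4, 2)], ph)
  expect_equal(accuracy(relab[tr], relab[pr])$overall,
               accuracy(tr, pr)$overall)
})

test_that("reports serialize to JSON and CSV", {
  ph <- gait_phases()
  rep <- metrics_report(rep(ph, 4), rep(ph, 4))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rep, js, confusion_csv = cs)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got$accuracy, 1)
  expect_equal(got$macro_f1, 1)
  expect_true(file.exists(cs))
})
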