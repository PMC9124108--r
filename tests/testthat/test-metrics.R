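test_that("confusion matrices tally actual/predicted pairs", {
  cm <- confusion_matrix(c(0, 1), c(0, 1))
  expect_identical(unname(unclass(cm)), matrix(c(1L, 0L, 0L, 1L), 2))
  cm2 <- confusion_matrix(c(0, 1), c(0, 0))
  expect_identical(cm2["1", "0"], 1L)
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 2), c(0, 1)), "\\{0, 1\\}")
  expect_error(confusion2x2(-1, 0, 0, 1), "non-negative")
})

test_that("per-class metrics reproduce the published benchmark rows", {
  # Leukemia, class 0 positive: 83.33 / 100.00 / 50.00 / 88.89 / 89.44
  m <- class_metrics(confusion2x2(8, 0, 2, 2), k = 0)
  expect_equal(100 * m$accuracy, 83.33, tolerance = 0.005)
  expect_equal(100 * m$recall, 100)
  expect_equal(100 * m$specificity, 50)
  expect_equal(100 * m$f_score, 88.89, tolerance = 0.005)
  expect_equal(100 * m$g_measure, 89.44, tolerance = 0.005)
  # Stanford, class 0 positive: F 50.00, G 57.74
  s <- class_metrics(confusion2x2(2, 4, 0, 9), k = 0)
  expect_equal(100 * s$f_score, 50)
  expect_equal(100 * s$g_measure, 57.74, tolerance = 0.005)
  # perfect diagonal: everything 100%
  p <- class_metrics(confusion2x2(5, 0, 0, 7), k = 1)
  expect_true(all(unlist(p[c("accuracy", "recall", "specificity",
                              "precision", "f_score", "g_measure")]) == 1))
  # no predicted positives: precision flagged, reported as 0
  u <- class_metrics(confusion2x2(0, 3, 0, 4), k = 0)
  expect_true(u$precision_undefined)
  expect_equal(u$precision, 0)
  expect_error(class_metrics(confusion2x2(0, 0, 1, 1), k = 0), "recall")
})

test_that("macro averages match the published summary lines", {
  lk <- macro_metrics(confusion2x2(8, 0, 2, 2))
  expect_equal(round(100 * unname(lk$macro[c("accuracy", "recall",
                                             "specificity", "f_score",
                                             "g_measure")]), 2),
               c(83.33, 75, 75, 77.78, 80.08), tolerance = 0.005)
  cl <- macro_metrics(confusion2x2(12, 1, 1, 5))
  expect_equal(round(100 * unname(cl$macro[c("accuracy", "recall",
                                             "specificity", "f_score",
                                             "g_measure")]), 2),
               c(89.47, 87.82, 87.82, 87.82, 87.82), tolerance = 0.005)
  # symmetric matrix: per-class metrics coincide with the macro average
  sy <- macro_metrics(confusion2x2(5, 1, 1, 5))
  expect_equal(unlist(sy$per_class["class_0", ]),
               unlist(sy$per_class["class_1", ]))
  expect_equal(unname(unlist(sy$per_class["class_0", ])),
               unname(sy$macro))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(14)
  for (i in 1:40) {
    cm <- confusion2x2(sample(1:30, 1), sample(0:30, 1),
                       sample(0:30, 1), sample(1:30, 1))
    m0 <- class_metrics(cm, 0); m1 <- class_metrics(cm, 1)
    # specificity duality and shared accuracy
    expect_equal(m0$specificity, m1$recall)
    expect_equal(m1$specificity, m0$recall)
    expect_equal(m0$accuracy, m1$accuracy)
    # AM-GM ordering when both precision and recall are positive
    for (m in list(m0, m1)) if (m$precision > 0 && m$recall > 0) {
      expect_lte(m$f_score, m$g_measure + 1e-12)
      expect_lte(m$g_measure, (m$precision + m$recall) / 2 + 1e-12)
    }
    # relabeling both classes swaps the per-class rows
    sw <- confusion2x2(cm["1", "1"], cm["1", "0"], cm["0", "1"], cm["0", "0"])
    expect_equal(class_metrics(sw, 1), class_metrics(cm, 0))
  }
})

test_that("stratified folds partition the samples with balanced classes", {
  y <- rep(c(0, 1), 10)
  folds <- stratified_kfold(y, 10, seed = 2)
  expect_length(folds, 10L)
  for (f in folds) expect_identical(as.vector(table(y[f])), c(1L, 1L))
  expect_identical(sort(unlist(folds)), 1:20)
  expect_identical(folds, stratified_kfold(y, 10, seed = 2))
  expect_false(identical(folds, stratified_kfold(y, 10, seed = 3)))
  # per-fold counts deviate from proportionality by at most one
  y2 <- c(rep(0, 23), rep(1, 11))
  folds2 <- stratified_kfold(y2, 5, seed = 1)
  expect_identical(sort(unlist(folds2)), seq_along(y2))
  for (f in folds2) {
    expect_lte(abs(sum(y2[f] == 0) - 23 / 5), 1)
    expect_lte(abs(sum(y2[f] == 1) - 11 / 5), 1)
  }
  expect_error(stratified_kfold(y, 25), "k must")
  expect_warning(stratified_kfold(c(0, 0, 0, 1, 1, 1, 1, 1), 4),
                 "best-effort")
})

test_that("stratified holdout splits preserve both classes", {
  y <- rep(c(0, 1), c(30, 12))
  sp <- stratified_holdout(y, test_fraction = 0.3, seed = 4)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_identical(sum(y[sp$test] == 0), 9L)
  expect_identical(sum(y[sp$test] == 1), 4L)
  expect_error(stratified_holdout(y, 0), "fraction")
})

test_that("reports render the percent table with half-up rounding", {
  tab <- report_table(macro_metrics(confusion2x2(8, 0, 2, 2)))
  expect_identical(tab["average", "g_measure"], 80.08)  # mean of 89.44, 70.71
  expect_identical(tab["class_0", "f_score"], 88.89)
  f <- tempfile()
  write_metrics_report(macro_metrics(confusion2x2(8, 0, 2, 2)), f)
  expect_true(file.exists(paste0(f, ".txt")))
  j <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(j$macro$accuracy, 10 / 12)
})
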