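test_that("stratified folds partition the cohort and preserve proportions", {
  labels <- rep(0:1, each = 50)
  fs <- stratified_folds(labels, k = 5, seed = 2)
  for (f in 1:5) {
    val <- fs$folds[[f]]$val
    expect_identical(unname(c(table(labels[val]))), c(10L, 10L))
    expect_identical(sort(c(val, fs$folds[[f]]$train)), seq_along(labels))
  }
  expect_identical(sort(unlist(lapply(fs$folds, `[[`, "val"))),
                   seq_along(labels))
  fs2 <- stratified_folds(labels, k = 5, seed = 2)
  expect_identical(fs$assignments, fs2$assignments)
  expect_error(stratified_folds(c(rep(0, 20), rep(3, 2)), k = 5), "class 3")

  # randomized cohorts: every fold's class count within 1 of n_c / k
  set.seed(77)
  for (i in 1:10) {
    lab <- sample(0:5, 120, replace = TRUE, prob = runif(6, 0.2, 1))
    lab <- c(lab, 0:5)  # ensure every class present at least k=3 times
    lab <- c(lab, 0:5, 0:5)
    fs <- stratified_folds(lab, k = 3, seed = i)
    for (cl in 0:5) {
      per_fold <- table(factor(fs$assignments[lab == cl], levels = 1:3))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
})

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_identical(unclass(cm)[1, ], c(`0` = 1L, `1` = 1L))
  expect_identical(unclass(cm)[2, ], c(`0` = 0L, `1` = 2L))
  expect_identical(sum(cm), 4L)

  perfect <- confusion(rep(0:2, times = c(3, 4, 5)), rep(0:2, times = c(3, 4, 5)))
  expect_identical(diag(unclass(perfect)), c(`0` = 3L, `1` = 4L, `2` = 5L))
  expect_identical(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  expect_error(confusion(c(0, 1), c(0)), "equal length")
  expect_error(confusion(c(0, 7), c(0, 0), levels = 0:5), "levels")
})

test_that("class-wise metrics match the hand-computed example", {
  cm <- structure(matrix(c(8L, 1L, 2L, 9L), 2, 2), class = "confusion_matrix",
                  levels = 0:1)
  r <- classwise_metrics(cm)
  expect_equal(r$sensitivity[1], 0.8)
  expect_equal(r$specificity[1], 0.9)
  expect_equal(r$precision[1], 8 / 9)
  expect_equal(r$accuracy[1], 0.85)
  expect_equal(r$f_measure[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(r$f_measure[1], 0.8421, tolerance = 1e-4)

  perfect <- confusion(rep(0:2, 5), rep(0:2, 5))
  rp <- classwise_metrics(perfect)
  expect_true(all(as.matrix(rp[, 2:6]) == 1))
})

test_that("metrics agree with brute-force enumeration on random inputs", {
  set.seed(11)
  for (i in 1:40) {
    K <- sample(2:6, 1)
    n <- sample(10:80, 1)
    y <- sample(0:(K - 1), n, replace = TRUE)
    p <- sample(0:(K - 1), n, replace = TRUE)
    got <- suppressWarnings(classwise_metrics(confusion(y, p, levels = 0:(K - 1))))
    want <- oracle_classwise(y, p, 0:(K - 1))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$precision, want$precision)
    expect_equal(got$f_measure, want$f_measure)
    # micro identities: sum of per-class supports is N, and micro-averaged
    # sensitivity (pooled TP / N) equals overall accuracy
    cm <- unclass(confusion(y, p, levels = 0:(K - 1)))
    expect_identical(sum(cm), as.integer(n))
    expect_equal(sum(diag(cm)) / n, mean(y == p))
  }
})

test_that("undefined classes are excluded from macro averages with a warning", {
  cm <- confusion(c(0, 0, 1), c(0, 0, 1), levels = 0:2)
  expect_warning(r <- classwise_metrics(cm), "excluded")
  expect_false(r$defined[3])
  mac <- macro_average(r)
  expect_equal(mac[["sensitivity"]], 1)

  # degenerate one-class report: macro equals that class's metrics
  one <- suppressWarnings(classwise_metrics(confusion(rep(0, 6), rep(0, 6),
                                                      levels = 0:1)))
  expect_equal(macro_average(one)[["sensitivity"]], one$sensitivity[1])

  # identical metrics across classes: macro equals them
  bal <- classwise_metrics(confusion(rep(0:1, each = 10),
                                     c(rep(0, 9), 1, rep(1, 9), 0)))
  expect_equal(macro_average(bal)[["sensitivity"]], bal$sensitivity[1])
})
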