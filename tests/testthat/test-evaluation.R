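test_that("confusion counting enumerates pixels correctly", {
  set.seed(3)
  truth <- randomMask(10, 10)
  k <- sum(truth)
  c1 <- confusionCounts(truth, truth)
  expect_equal(c(c1@tp, c1@tn, c1@fp, c1@fn), c(k, 100 - k, 0, 0))
  c2 <- confusionCounts(1L - truth, truth)
  expect_equal(c(c2@tp, c2@tn), c(0, 0))
  c3 <- confusionCounts(matrix(c(1L, 1L, 0L, 0L), 1), matrix(c(1L, 0L, 1L, 0L), 1))
  expect_equal(c(c3@tp, c3@fp, c3@fn, c3@tn), c(1, 1, 1, 1))
  expect_error(confusionCounts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "identical shapes")
  expect_error(confusionCounts(matrix(2L, 2, 2), matrix(0L, 2, 2)), "binary")
})

test_that("the five metrics evaluate their formulas exactly", {
  r <- computeMetrics(new("ConfusionCounts", tp = 50, fp = 10, fn = 10,
                          tn = 30))
  expect_equal(r@precision, 50 / 60)
  expect_equal(r@recall, 50 / 60)
  expect_equal(r@f1, 50 / 60)
  expect_equal(r@accuracy, 0.8)
  expect_equal(r@iou, 50 / 70)

  perfect <- computeMetrics(new("ConfusionCounts", tp = 7, fp = 0, fn = 0,
                                tn = 3))
  for (nm in c("accuracy", "recall", "precision", "f1", "iou"))
    expect_equal(slot(perfect, nm), 1)
})

test_that("zero denominators are undefined markers, never silent 0 or 1", {
  r <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 5, tn = 5))
  expect_true(is.na(r@precision))
  expect_equal(r@recall, 0)
  expect_equal(r@iou, 0)
  expect_true(is.na(r@f1))
  allNeg <- computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 0,
                               tn = 9))
  expect_true(is.na(allNeg@precision))
  expect_true(is.na(allNeg@recall))
  expect_true(is.na(allNeg@iou))
  expect_equal(allNeg@accuracy, 1)
  expect_error(computeMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 0,
                                  tn = 0)), "zero")
})

test_that("metrics agree with an independent per-pixel recount", {
  set.seed(9)
  for (i in 1:50) {
    pred <- randomMask(16, 16, runif(1, 0.1, 0.9))
    truth <- randomMask(16, 16, runif(1, 0.1, 0.9))
    mine <- computeMetrics(confusionCounts(pred, truth))
    oracle <- oracleMetrics(pred, truth)
    for (nm in c("accuracy", "recall", "precision", "f1", "iou")) {
      expect_identical(is.na(slot(mine, nm)), is.na(oracle[[nm]]))
      if (!is.na(oracle[[nm]])) expect_equal(slot(mine, nm), oracle[[nm]])
    }
  }
})

test_that("F1 and IoU satisfy their algebraic identity", {
  set.seed(4)
  for (i in 1:200) {
    cc <- new("ConfusionCounts", tp = rpois(1, 20), fp = rpois(1, 10),
              fn = rpois(1, 10), tn = rpois(1, 40))
    if (cc@tp + cc@fp + cc@fn + cc@tn == 0) next
    r <- computeMetrics(cc)
    if (!is.na(r@f1) && !is.na(r@iou))
      expect_equal(r@f1, 2 * r@iou / (1 + r@iou), tolerance = 1e-12)
  }
})

test_that("metric symmetries hold", {
  set.seed(6)
  pred <- randomMask(12, 12)
  truth <- randomMask(12, 12)
  a <- computeMetrics(confusionCounts(pred, truth))
  flip <- computeMetrics(confusionCounts(1L - pred, 1L - truth))
  expect_equal(a@accuracy, flip@accuracy)
  swapped <- computeMetrics(confusionCounts(truth, pred))
  expect_equal(a@precision, swapped@recall)
  expect_equal(a@recall, swapped@precision)
})

test_that("dataset evaluation aggregates per-image and pooled consistently", {
  set.seed(8)
  pred <- randomMask(8, 8)
  truth <- randomMask(8, 8)
  one <- evaluateDataset(list(pred), list(truth))
  pooled <- evaluateDataset(list(pred), list(truth), mode = "pooled")
  for (nm in c("accuracy", "recall", "precision", "f1", "iou"))
    expect_equal(slot(one$aggregate, nm), slot(pooled$aggregate, nm))

  twoSame <- evaluateDataset(list(pred, pred), list(truth, truth),
                             mode = "pooled")
  expect_equal(twoSame$aggregate@iou, pooled$aggregate@iou)

  # pooled counts add before the formulas apply
  predA <- matrix(c(1L, 0L, 0L, 0L), 2)   # vs truth A: TP=1, FN=1, TN=2
  truthA <- matrix(c(1L, 1L, 0L, 0L), 2)
  predB <- matrix(1L, 2, 2)               # vs truth B: TP=2, FP=2
  truthB <- matrix(c(1L, 1L, 0L, 0L), 2)
  res <- evaluateDataset(list(predA, predB), list(truthA, truthB),
                         mode = "pooled")
  expect_equal(res$aggregate@precision, 3 / 5)
  expect_equal(res$aggregate@recall, 3 / 4)

  expect_error(evaluateDataset(list(pred), list(truth, truth)), "1 predictions")
})

test_that("reports serialize with one row per image plus an aggregate", {
  dir <- withr::local_tempdir()
  set.seed(10)
  preds <- lapply(1:3, function(i) randomMask(6, 6))
  truths <- lapply(1:3, function(i) randomMask(6, 6))
  res <- evaluateDataset(preds, truths, ids = c("a", "b", "c"))
  df <- writeReport(res, csvPath = file.path(dir, "r.csv"),
                    jsonPath = file.path(dir, "r.json"))
  expect_equal(nrow(df), 4)
  expect_identical(df$imageId, c("a", "b", "c", "aggregate"))
  back <- read.csv(file.path(dir, "r.csv"))
  expect_equal(nrow(back), 4)
  expect_equal(back$iou[1:3], vapply(res$reports, slot, numeric(1), "iou"))
  js <- jsonlite::read_json(file.path(dir, "r.json"), simplifyVector = TRUE)
  expect_equal(nrow(js), 4)
})
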