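test_that("pixel-wise softmax normalizes, matches closed forms and shifts", {
  a <- array(0, dim = c(2, 2, 2))
  expect_true(all(pixelSoftmax(a) == 0.5))
  b <- array(c(1, 0), dim = c(1, 1, 2))
  p <- pixelSoftmax(b)
  expect_equal(p[1, 1, 1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(p[1, 1, 2], 1 / (exp(1) + 1), tolerance = 1e-12)
  set.seed(2)
  acts <- array(rnorm(16 * 16 * 3, sd = 4), dim = c(16, 16, 3))
  sm <- pixelSoftmax(acts)
  expect_true(all(abs(apply(sm, c(1, 2), sum) - 1) < 1e-6))
  expect_true(all(sm >= 0 & sm <= 1))
  # shift invariance: adding a constant to every channel changes nothing
  expect_equal(pixelSoftmax(acts + 7.3), sm, tolerance = 1e-12)
  expect_error(pixelSoftmax(array(c(Inf, 0), dim = c(1, 1, 2))), "finite")
  expect_error(pixelSoftmax(array(0, dim = c(2, 2, 1))), "K >= 2")
})

test_that("U-Net output honors the probability-map contract", {
  spec <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 2,
                         inputSize = 16)
  model <- buildUNet(spec, initSeed = 4)
  A <- matrix(runif(16 * 16 * 2 * 3), 16 * 16 * 2, 3)
  fw <- nucseg:::segForward(model, A, 2L, training = FALSE)
  probs <- nucseg:::softmaxRows(fw$logits)
  expect_identical(dim(probs), c(16L * 16L * 2L, 2L))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # one skip concatenation per level
  expect_length(model@params$dec, spec@depth)
  for (d in model@params$dec)
    expect_equal(nrow(d$convs[[1]]$conv$W) / 9,
                 2 * length(d$up$b))  # first conv sees up + skip channels
})

test_that("extra convolutions per block add parameters (improved vs classic)", {
  s2 <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 2,
                       inputSize = 16)
  s3 <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 3,
                       inputSize = 16)
  expect_gt(countParams(buildUNet(s3)), countParams(buildUNet(s2)))
})

test_that("the FCN has no skip connections but the same output contract", {
  spec <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 2,
                         inputSize = 16)
  model <- buildFCN(spec, initSeed = 4)
  expect_false("dec" %in% names(model@params))  # encoder-decoder, no concat
  expect_length(model@params$ups, spec@depth)
  A <- matrix(runif(16 * 16 * 3), 16 * 16, 3)
  fw <- nucseg:::segForward(model, A, 1L, training = FALSE)
  probs <- nucseg:::softmaxRows(fw$logits)
  expect_identical(dim(probs), c(16L * 16L, 2L))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})

test_that("segmentation training reduces cross-entropy and validates input", {
  params <- tinyParams(h = 16, w = 16, n = 2, radius = c(3, 5), noise = 0.02)
  tiles <- generateDataset(8, params)
  spec <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 2,
                         inputSize = 16)
  fit <- trainSegmenter(buildUNet(spec, initSeed = 6), tiles, epochs = 5,
                        batchSize = 4, seed = 6)
  h <- historyLoss(fit$history)
  expect_length(h, 5)
  expect_true(all(h >= 0))
  expect_lt(h[5], h[1])
  expect_length(historyAccuracy(fit$history), 5)
  # reruns with the same seed are bit-identical
  fit2 <- trainSegmenter(buildUNet(spec, initSeed = 6), tiles, epochs = 5,
                         batchSize = 4, seed = 6)
  expect_identical(historyLoss(fit2$history), h)

  expect_error(trainSegmenter(buildUNet(spec), list(), epochs = 1),
               "non-empty")
  bad <- list(list(image = getImage(tiles[[1]]),
                   mask = matrix(2L, 16, 16)))
  expect_error(trainSegmenter(buildUNet(spec), bad, epochs = 1), "0 or 1")
})

test_that("training toward all-background drives foreground away", {
  imgs <- generateDataset(6, tinyParams(h = 16, w = 16, n = 2, noise = 0.02))
  blank <- lapply(imgs, function(im)
    list(image = getImage(im), mask = matrix(0L, 16, 16)))
  spec <- segNetworkSpec(depth = 2, baseFilters = 4, convsPerBlock = 2,
                         inputSize = 16)
  fit <- trainSegmenter(buildUNet(spec, initSeed = 7), blank, epochs = 8,
                        batchSize = 3, seed = 7)
  pred <- predictMask(fit$model, getImage(imgs[[1]]))
  expect_lt(mean(pred), 0.1)
})

test_that("mask prediction is deterministic, binary and tile-consistent", {
  model <- forcedSegModel(c(0, 10))
  img <- array(runif(40 * 24 * 3), dim = c(40, 24, 3))
  pred <- predictMask(model, img)
  expect_identical(dim(pred), c(40L, 24L))
  expect_true(all(pred == 1L))  # forced argmax toward class 1
  expect_identical(predictMask(model, img), pred)

  # constant-probability model: overlapping and disjoint tiling agree
  dense <- predictMask(model, img, stride = 8)
  expect_identical(dense, pred)

  zeroModel <- forcedSegModel(c(10, 0))
  expect_true(all(predictMask(zeroModel, img) == 0L))
  # exact 0.5 ties go to foreground
  tieModel <- forcedSegModel(c(0, 0))
  expect_true(all(predictMask(tieModel, img) == 1L))

  untrained <- buildUNet(segNetworkSpec(depth = 2, baseFilters = 4,
                                        convsPerBlock = 2, inputSize = 16))
  expect_error(predictMask(untrained, img), "untrained")
})
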