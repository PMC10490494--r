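# The autoencoder/clustering tests run tiny networks (8x8 inputs, few
# filters) so each block stays in the seconds range.

tinySpec <- function() networkSpec(depth = 2, baseFilters = 4, latentDim = 6,
                                   inputSize = 8)

tinyPatchSet <- function(n = 24, seed = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- if (i %% 2 == 0) 0.2 else 0.8
    array(pmin(pmax(base + runif(8 * 8 * 3, -0.05, 0.05), 0), 1),
          dim = c(8, 8, 3))
  })
}

test_that("autoencoder geometry follows the (N, C, Z) contract", {
  spec <- networkSpec(depth = 2, baseFilters = 8, latentDim = 16,
                      inputSize = 32)
  model <- buildCAE(spec)
  patches <- lapply(1:5, function(i) array(runif(32 * 32 * 3),
                                           dim = c(32, 32, 3)))
  codes <- encodePatches(model, patches)
  expect_identical(dim(codes), c(5L, 16L))
  # reconstruction has the input geometry and sigmoid range
  A <- nucseg:::patchesToMatrix(patches)
  fw <- nucseg:::caeForward(model@params, spec, A, 5L, model@state, FALSE)
  expect_identical(dim(fw$recon), dim(A))
  expect_true(all(fw$recon >= 0 & fw$recon <= 1))
  # pooling halves the spatial extent at every level: 32 -> 16
  expect_equal(nrow(fw$caches$enc[[1]]$conv$cols), 32 * 32 * 5)
  expect_equal(nrow(fw$caches$enc[[2]]$conv$cols), 16 * 16 * 5)
  expect_error(networkSpec(depth = 2, inputSize = 30), "divisible")
})

test_that("reconstruction training reduces the loss and is reproducible", {
  patches <- rep(list(array(0.7, dim = c(8, 8, 3))), 30)
  model <- buildCAE(tinySpec(), initSeed = 1)
  fit <- trainCAE(model, patches, epochs = 6, batchSize = 8, seed = 1)
  h <- historyLoss(fit$history)
  expect_length(h, 6)
  expect_true(all(h >= 0))
  expect_lt(h[6], h[1])
  expect_true(fit$model@trained)
  # identical build + data + seed reproduce the history bitwise
  fit2 <- trainCAE(buildCAE(tinySpec(), initSeed = 1), patches,
                   epochs = 6, batchSize = 8, seed = 1)
  expect_identical(historyLoss(fit2$history), h)
  # single-epoch history has length one
  one <- trainCAE(buildCAE(tinySpec()), patches[1:4], epochs = 1, seed = 0)
  expect_length(historyLoss(one$history), 1)
  expect_error(trainCAE(model, list(), epochs = 1), "at least one patch")
  expect_error(trainCAE(model, patches, epochs = 0), "epochs")
})

test_that("encoding is deterministic and separates opposite patches", {
  patches <- c(rep(list(array(0, dim = c(8, 8, 3))), 10),
               rep(list(array(1, dim = c(8, 8, 3))), 10))
  fit <- trainCAE(buildCAE(tinySpec(), initSeed = 2), patches,
                  epochs = 8, batchSize = 4, seed = 2)
  codes <- encodePatches(fit$model, patches[c(1, 2, 11)])
  expect_identical(codes[1, ], codes[2, ])  # identical inputs, identical codes
  expect_identical(codes, encodePatches(fit$model, patches[c(1, 2, 11)]))
  expect_gt(sqrt(sum((codes[1, ] - codes[3, ])^2)), 0)
  expect_error(encodePatches(fit$model, list(array(0, dim = c(4, 4, 3)))),
               "match the network input")
})

test_that("2-means matches the exhaustive optimum on separable blobs", {
  set.seed(5)
  x <- rbind(matrix(rnorm(8, mean = 0, sd = 0.1), 4, 2),
             matrix(rnorm(8, mean = 5, sd = 0.1), 4, 2))
  cm <- fitKmeans2(x, seed = 5)
  expect_equal(clusterInertia(cm), bruteForce2PartitionSSE(x),
               tolerance = 1e-10)
  asg <- nucseg:::assignClusters(x, centroids(cm))
  expect_length(unique(asg[1:4]), 1)
  expect_length(unique(asg[5:8]), 1)
  expect_false(asg[1] == asg[5])
  expect_true(all(is.na(classMap(cm))))
})

test_that("2-means handles the degenerate and minimal cases", {
  two <- rbind(c(0, 0), c(3, 4))
  cm <- fitKmeans2(two, seed = 1)
  expect_equal(clusterInertia(cm), 0)
  expect_error(fitKmeans2(matrix(1, 5, 3), seed = 1), "degenerate")
  expect_error(fitKmeans2(matrix(1, 1, 3), seed = 1), "at least two")
})

test_that("cluster-to-class mapping maximizes reference accuracy", {
  ps <- lapply(1:8, function(i) array(0.5, dim = c(4, 4, 3)))
  asg <- rep(c(1L, 2L), each = 4)
  # cluster 2's patches are mostly foreground -> cluster 2 must be tumor
  refs <- c(rep(list(matrix(0L, 4, 4)), 4), rep(list(matrix(1L, 4, 4)), 4))
  cm <- new("ClusterModel", centroids = matrix(0, 2, 3), inertia = 0,
            classOfCluster = c(NA_integer_, NA_integer_))
  expect_identical(classMap(mapClustersToClasses(cm, asg, ps, refs)),
                   c(0L, 1L))
  # and the flipped references flip the mapping
  expect_identical(classMap(mapClustersToClasses(cm, asg, ps, rev(refs))),
                   c(1L, 0L))
  # symmetric accuracies fall back to cluster 1 = non-tumor
  half <- lapply(1:8, function(i) {
    m <- matrix(0L, 4, 4); m[1:8] <- 1L; m
  })
  expect_identical(classMap(mapClustersToClasses(cm, asg, ps, half)),
                   c(0L, 1L))
})

test_that("without references the darker cluster is called tumor", {
  dark <- lapply(1:5, function(i) array(0.2, dim = c(4, 4, 3)))
  light <- lapply(1:5, function(i) array(0.9, dim = c(4, 4, 3)))
  cm <- new("ClusterModel", centroids = matrix(0, 2, 3), inertia = 0,
            classOfCluster = c(NA_integer_, NA_integer_))
  m1 <- mapClustersToClasses(cm, rep(c(1L, 2L), each = 5), c(dark, light))
  expect_identical(classMap(m1), c(1L, 0L))
  m2 <- mapClustersToClasses(cm, rep(c(2L, 1L), each = 5), c(dark, light))
  expect_identical(classMap(m2), c(0L, 1L))
})

test_that("unsupervised segmentation keeps the pixel contract end to end", {
  params <- tinyParams(h = 32, w = 32, n = 3, noise = 0.01, seed = 8,
                       radius = c(4, 7))
  imgs <- generateDataset(6, params)
  patches <- unlist(lapply(imgs, function(im)
    getPatches(extractPatches(getImage(im), 8))), recursive = FALSE)
  maskPatches <- unlist(lapply(imgs, function(im)
    getPatches(extractMaskPatches(getMask(im), 8))), recursive = FALSE)
  fit <- trainCAE(buildCAE(tinySpec(), initSeed = 8), patches,
                  epochs = 6, batchSize = 16, seed = 8)
  codes <- encodePatches(fit$model, patches)
  cm <- fitKmeans2(codes, seed = 8)
  asg <- nucseg:::assignClusters(codes, centroids(cm))
  cm <- mapClustersToClasses(cm, asg, patches, maskPatches)

  out <- segmentUnsupervised(getImage(imgs[[1]]), fit$model, cm)
  expect_identical(dim(out), c(32L, 32L))
  expect_true(all(out %in% c(0L, 1L)))

  # label-permutation invariance: swapping clusters and the mapping
  # leaves the segmentation unchanged
  flipped <- new("ClusterModel",
                 centroids = centroids(cm)[2:1, ],
                 inertia = clusterInertia(cm),
                 classOfCluster = classMap(cm)[2:1])
  expect_identical(segmentUnsupervised(getImage(imgs[[1]]), fit$model, flipped),
                   out)

  # a pure-background image segments to an all-zero mask
  bg <- generateImage(tinyParams(h = 32, w = 32, n = 0, noise = 0.01, seed = 9))
  expect_true(all(segmentUnsupervised(getImage(bg), fit$model, cm) == 0L))

  unmapped <- fitKmeans2(codes, seed = 8)
  expect_error(segmentUnsupervised(getImage(imgs[[1]]), fit$model, unmapped),
               "mapping unset")
})
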