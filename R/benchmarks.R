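# Reproducible synthetic benchmarks. These bundle the package's reference
# study conditions — the easy synthetic sets, network sizes and training
# budgets used throughout the documentation — so that the same experiment
# can be re-run from tests, scripts or an interactive session with one
# call and one seed. All randomness derives from the single seed
# argument, so repeated calls are bit-identical.

benchSeed <- function(seed, salt) as.integer((as.numeric(seed) * 131071 +
                                                salt) %% 2147483629)

#' Autoencoder reconstruction benchmark
#'
#' Trains the default convolutional autoencoder (depth 3, 16 base
#' filters, 64 latent units, 32x32 input) on `nPatches` synthetic H&E-like
#' 32x32 patches and reports the per-epoch reconstruction loss and the
#' final/initial loss ratio.
#'
#' @param nPatches number of training patches.
#' @param epochs training epochs.
#' @param seed master seed; fixes data, initialization and shuffling.
#' @return list with `history` ([TrainingHistory-class]), `lossRatio`
#'   (final epoch loss / first epoch loss) and the trained `model`.
#' @export
benchmarkCAE <- function(nPatches = 200L, epochs = 20L, seed = 1L) {
  params <- syntheticParams(imageHeight = 128L, imageWidth = 128L,
                            nNuclei = 8L, noiseSd = 0.02,
                            seed = benchSeed(seed, 1L))
  imgs <- generateDataset(ceiling(nPatches / 16), params)
  patches <- unlist(lapply(imgs, function(im)
    getPatches(extractPatches(getImage(im), 32L))),
    recursive = FALSE)[seq_len(nPatches)]
  model <- buildCAE(networkSpec(), initSeed = benchSeed(seed, 2L))
  fit <- trainCAE(model, patches, epochs = epochs,
                  seed = benchSeed(seed, 3L))
  h <- historyLoss(fit$history)
  list(history = fit$history, lossRatio = h[epochs] / h[1],
       model = fit$model)
}

#' End-to-end unsupervised segmentation benchmark
#'
#' Generates an easy high-contrast synthetic set (default 20 images of
#' 128x128, noise 0.02), trains a small autoencoder on non-overlapping
#' 8x8 patches, clusters the latent codes with 2-means, resolves the
#' cluster-to-class mapping against the training masks, then segments
#' every image with an overlapping stride (8x8 patches, stride 4) and
#' scores IoU against the pixel-exact ground truth.
#'
#' @param nImages images in the set.
#' @param epochs autoencoder training epochs.
#' @param seed master seed.
#' @param stride segmentation stride in pixels.
#' @return list with `meanIoU`, per-image `ious`, predicted `masks`, the
#'   `dataset`, the training `history` and the fitted models.
#' @export
benchmarkUnsupervised <- function(nImages = 20L, epochs = 8L, seed = 1L,
                                  stride = 4L) {
  params <- syntheticParams(imageHeight = 128L, imageWidth = 128L,
                            nNuclei = 8L, noiseSd = 0.02,
                            seed = benchSeed(seed, 11L))
  imgs <- generateDataset(nImages, params)
  ps <- 8L
  patches <- list()
  maskPatches <- list()
  for (im in imgs) {
    patches <- c(patches, getPatches(extractPatches(getImage(im), ps)))
    maskPatches <- c(maskPatches,
                     getPatches(extractMaskPatches(getMask(im), ps)))
  }
  spec <- networkSpec(depth = 2L, baseFilters = 8L, latentDim = 16L,
                      inputSize = ps)
  fit <- trainCAE(buildCAE(spec, initSeed = benchSeed(seed, 12L)), patches,
                  epochs = epochs, batchSize = 128L,
                  seed = benchSeed(seed, 13L))
  codes <- encodePatches(fit$model, patches)
  cm <- fitKmeans2(codes, seed = benchSeed(seed, 14L))
  asg <- assignClusters(codes, cm@centroids)
  cm <- mapClustersToClasses(cm, asg, patches, maskPatches)
  masks <- lapply(imgs, function(im)
    segmentUnsupervised(getImage(im), fit$model, cm, patchSize = ps,
                        stride = stride))
  ious <- vapply(seq_along(imgs), function(i)
    computeMetrics(confusionCounts(masks[[i]], getMask(imgs[[i]])))@iou,
    numeric(1))
  list(meanIoU = mean(ious), ious = ious, masks = masks, dataset = imgs,
       history = fit$history, model = fit$model, clusterModel = cm)
}

#' Supervised segmentation benchmark: improved U-Net vs FCN
#'
#' Generates a synthetic training set and a held-out test set (64x64
#' tiles), trains the improved U-Net (depth 3, 8 base filters, 3 convs
#' per block) and the FCN baseline with identical data, budgets and
#' seeds, and reports held-out mean IoU for both.
#'
#' @param nTrain,nTest training and held-out image counts.
#' @param epochs training epochs for each network.
#' @param seed master seed.
#' @param runFCN also train the FCN baseline (set `FALSE` to skip).
#' @return list with `unetIoU`, `fcnIoU` (`NA` when skipped), per-network
#'   histories, predicted masks on the test set and the test dataset.
#' @export
benchmarkSupervised <- function(nTrain = 64L, nTest = 16L, epochs = 30L,
                                seed = 1L, runFCN = TRUE) {
  params <- syntheticParams(imageHeight = 64L, imageWidth = 64L,
                            nNuclei = 3L, radiusRange = c(6, 12),
                            noiseSd = 0.02, seed = benchSeed(seed, 21L))
  all <- generateDataset(nTrain + nTest, params)
  train <- all[seq_len(nTrain)]
  test <- all[nTrain + seq_len(nTest)]
  spec <- segNetworkSpec(depth = 3L, baseFilters = 8L, convsPerBlock = 3L,
                         inputSize = 64L)
  runOne <- function(build) {
    fit <- trainSegmenter(build(spec, initSeed = benchSeed(seed, 22L)),
                          train, epochs = epochs, batchSize = 8L,
                          seed = benchSeed(seed, 23L))
    masks <- lapply(test, function(im) predictMask(fit$model, getImage(im)))
    ious <- vapply(seq_along(test), function(i)
      computeMetrics(confusionCounts(masks[[i]], getMask(test[[i]])))@iou,
      numeric(1))
    list(iou = mean(ious), ious = ious, masks = masks,
         history = fit$history, model = fit$model)
  }
  unet <- runOne(buildUNet)
  fcn <- if (runFCN) runOne(buildFCN) else NULL
  list(unetIoU = unet$iou, fcnIoU = if (runFCN) fcn$iou else NA_real_,
       unet = unet, fcn = fcn, test = test)
}
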