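# User-facing constructors and show/accessor methods.

#' Create synthetic-generator parameters
#'
#' Defaults render dark bluish-purple elliptical nuclei, RGB
#' (0.35, 0.25, 0.55), on a pinkish eosin-like background,
#' RGB (0.90, 0.75, 0.80) — the luminance contrast the unsupervised
#' cluster-to-class heuristic relies on.
#'
#' @param imageHeight,imageWidth canvas size in pixels.
#' @param nNuclei number of nuclei.
#' @param radiusRange `(min, max)` semi-major axis in pixels.
#' @param eccentricityRange `(min, max)` in `[0, 1)`.
#' @param nucleusColor,backgroundColor RGB triples in `[0, 1]`.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param allowOverlap may nuclei overlap? Overlaps union into one mask.
#' @param seed integer seed.
#' @return a [SyntheticParams-class] object.
#' @examples
#' p <- syntheticParams(imageHeight = 64, imageWidth = 64, nNuclei = 3)
#' @export
syntheticParams <- function(imageHeight = 512L, imageWidth = 512L,
                            nNuclei = 30L, radiusRange = c(8, 18),
                            eccentricityRange = c(0, 0.8),
                            nucleusColor = c(0.35, 0.25, 0.55),
                            backgroundColor = c(0.90, 0.75, 0.80),
                            noiseSd = 0.02, allowOverlap = TRUE,
                            seed = 1L) {
  new("SyntheticParams",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      nNuclei = as.integer(nNuclei), radiusRange = as.numeric(radiusRange),
      eccentricityRange = as.numeric(eccentricityRange),
      nucleusColor = as.numeric(nucleusColor),
      backgroundColor = as.numeric(backgroundColor),
      noiseSd = as.numeric(noiseSd), allowOverlap = isTRUE(allowOverlap),
      seed = as.integer(seed))
}

#' Create an autoencoder network specification
#'
#' Defaults (`depth = 3`, `baseFilters = 16`, `latentDim = 64`,
#' `inputSize = 32`) give a bottleneck of 64 units against a 32x32x3 =
#' 3072-value input, and 32 / 2^3 = 4 keeps the pooled extent integral.
#'
#' @param depth encoder levels (N).
#' @param baseFilters first-level filter count (C); doubled per level.
#' @param latentDim latent dimensionality (Z).
#' @param inputSize square input patch edge, divisible by `2^depth`.
#' @return a [NetworkSpec-class] object.
#' @export
networkSpec <- function(depth = 3L, baseFilters = 16L, latentDim = 64L,
                        inputSize = 32L) {
  new("NetworkSpec", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      latentDim = as.integer(latentDim), inputSize = as.integer(inputSize))
}

#' Create a segmentation network specification
#'
#' @param depth encoder levels.
#' @param baseFilters first-block filter count; doubled per level.
#' @param convsPerBlock convolutions per encoder/decoder block; 3 is the
#'   improved U-Net, 2 the classic one.
#' @param nClasses number of output classes.
#' @param inputSize square tile edge, divisible by `2^depth`.
#' @return a [SegNetworkSpec-class] object.
#' @export
segNetworkSpec <- function(depth = 3L, baseFilters = 16L, convsPerBlock = 3L,
                           nClasses = 2L, inputSize = 32L) {
  new("SegNetworkSpec", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters),
      convsPerBlock = as.integer(convsPerBlock),
      nClasses = as.integer(nClasses), inputSize = as.integer(inputSize))
}

#' Bundle an image, an optional mask and an id
#'
#' @param image `height x width x 3` numeric array in `[0, 1]`.
#' @param mask binary matrix of matching extent, or `NULL`.
#' @param imageId character id.
#' @return a [LabeledImage-class] object.
#' @export
labeledImage <- function(image, mask = NULL, imageId = "img") {
  if (!is.null(mask)) {
    mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  }
  new("LabeledImage", image = image, mask = mask, imageId = as.character(imageId))
}

#' @describeIn LabeledImage-class the image array.
#' @param x,object a `LabeledImage`.
#' @export
getImage <- function(x) x@image

#' @describeIn LabeledImage-class the mask matrix or `NULL`.
#' @export
getMask <- function(x) x@mask

#' @describeIn LabeledImage-class the image id.
#' @export
imageId <- function(x) x@imageId

#' @describeIn PatchGrid-class number of patches in the grid.
#' @param x a `PatchGrid`.
#' @export
patchCount <- function(x) length(x@patches)

#' @describeIn PatchGrid-class list of patch arrays.
#' @export
getPatches <- function(x) x@patches

#' @describeIn PatchGrid-class 0-based top-left `(row, col)` coordinates.
#' @export
patchCoords <- function(x) x@coords

#' @describeIn ClusterModel-class the `2 x latentDim` centroid matrix.
#' @param x a `ClusterModel`.
#' @export
centroids <- function(x) x@centroids

#' @describeIn ClusterModel-class total within-cluster sum of squares.
#' @export
clusterInertia <- function(x) x@inertia

#' @describeIn ClusterModel-class the cluster-to-class mapping (`NA` until
#'   set by [mapClustersToClasses()]).
#' @export
classMap <- function(x) x@classOfCluster

#' @describeIn TrainingHistory-class per-epoch mean loss.
#' @param x a `TrainingHistory`.
#' @export
historyLoss <- function(x) x@loss

#' @describeIn TrainingHistory-class per-epoch pixel accuracy (`NA` for
#'   autoencoder training).
#' @export
historyAccuracy <- function(x) x@accuracy

#' Turn metric reports into a data frame
#'
#' @param reports a single [MetricReport-class] or a list of them.
#' @return a data frame with columns `imageId`, `accuracy`, `recall`,
#'   `precision`, `f1`, `iou` (one row per report; `NA` marks metrics that
#'   were undefined because of a zero denominator).
#' @export
metricsTable <- function(reports) {
  if (is(reports, "MetricReport")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(imageId = r@imageId, accuracy = r@accuracy, recall = r@recall,
               precision = r@precision, f1 = r@f1, iou = r@iou,
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "SyntheticParams", function(object) {
  cat(sprintf("SyntheticParams: %d x %d canvas, %d nuclei, radius [%g, %g], noiseSd %g, seed %d\n",
              object@imageHeight, object@imageWidth, object@nNuclei,
              object@radiusRange[1], object@radiusRange[2], object@noiseSd,
              object@seed))
})

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledImage '%s': %d x %d RGB, mask %s\n", object@imageId,
              d[1], d[2],
              if (is.null(object@mask)) "absent"
              else sprintf("present (%.1f%% foreground)",
                           100 * mean(object@mask))))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %d x %d (stride %d) from %d x %d (padded %d x %d)\n",
              patchCount(object), object@patchSize, object@patchSize,
              object@stride, object@sourceDim[1], object@sourceDim[2],
              object@paddedDim[1], object@paddedDim[2]))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec(N = %d, C = %d, Z = %d, input %d x %d)\n",
              object@depth, object@baseFilters, object@latentDim,
              object@inputSize, object@inputSize))
})

setMethod("show", "SegNetworkSpec", function(object) {
  cat(sprintf("SegNetworkSpec: depth %d, base %d filters, %d convs/block, %d classes, input %d\n",
              object@depth, object@baseFilters, object@convsPerBlock,
              object@nClasses, object@inputSize))
})

setMethod("show", "CAEModel", function(object) {
  cat(sprintf("CAEModel (%s): ", if (object@trained) "trained" else "untrained"))
  show(object@spec)
})

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel [%s] (%s): ", object@arch,
              if (object@trained) "trained" else "untrained"))
  show(object@spec)
})

setMethod("show", "ClusterModel", function(object) {
  m <- object@classOfCluster
  cat(sprintf("ClusterModel: 2 centroids in %d-d latent space, inertia %.4g, mapping %s\n",
              ncol(object@centroids), object@inertia,
              if (any(is.na(m))) "unset"
              else sprintf("cluster1->%d, cluster2->%d", m[1], m[2])))
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: %d epochs, loss %.5g -> %.5g (seed %d)\n",
              object@epochs, object@loss[1], object@loss[object@epochs],
              object@seed))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %g, FP %g, FN %g, TN %g\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "MetricReport", function(object) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("MetricReport [%s]: accuracy %s, recall %s, precision %s, F1 %s, IoU %s\n",
              object@imageId, fmt(object@accuracy), fmt(object@recall),
              fmt(object@precision), fmt(object@f1), fmt(object@iou)))
})
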