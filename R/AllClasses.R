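#' @import methods
NULL

setClassUnion("matrixOrNULL", members = c("matrix", "NULL"))

#' Parameters of the synthetic H&E-like image generator
#'
#' Describes one synthetic histology tile: canvas size, the number of
#' elliptical nuclei to render, their size and shape ranges, the two stain
#' colors, the additive noise level and the random seed. Defaults mimic a
#' hematoxylin-and-eosin tile: dark bluish-purple nuclei on a pink
#' eosin-like background.
#'
#' @slot imageHeight,imageWidth canvas size in pixels.
#' @slot nNuclei number of nuclei to draw.
#' @slot radiusRange min/max semi-major axis in pixels.
#' @slot eccentricityRange min/max eccentricity in `[0, 1)`; 0 gives circles.
#' @slot nucleusColor,backgroundColor RGB triples in `[0, 1]`.
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise.
#' @slot allowOverlap if `FALSE`, nuclei are rejection-sampled so that no
#'   two ellipses can intersect.
#' @slot seed integer seed; identical parameters give bit-identical output.
#' @seealso [syntheticParams()], [generateImage()], [generateDataset()]
#' @exportClass SyntheticParams
setClass("SyntheticParams",
  representation(
    imageHeight = "integer", imageWidth = "integer", nNuclei = "integer",
    radiusRange = "numeric", eccentricityRange = "numeric",
    nucleusColor = "numeric", backgroundColor = "numeric",
    noiseSd = "numeric", allowOverlap = "logical", seed = "integer"
  )
)

setValidity("SyntheticParams", function(object) {
  msg <- character()
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@nNuclei < 0L) msg <- c(msg, "nNuclei must be >= 0")
  if (length(object@radiusRange) != 2L ||
      object@radiusRange[1] > object@radiusRange[2] ||
      object@radiusRange[1] <= 0)
    msg <- c(msg, "radiusRange must be positive with min <= max")
  if (length(object@eccentricityRange) != 2L ||
      any(object@eccentricityRange < 0) || any(object@eccentricityRange >= 1) ||
      object@eccentricityRange[1] > object@eccentricityRange[2])
    msg <- c(msg, "eccentricityRange must lie in [0, 1) with min <= max")
  for (nm in c("nucleusColor", "backgroundColor")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(v < 0) || any(v > 1))
      msg <- c(msg, sprintf("%s must be an RGB triple in [0, 1]", nm))
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' An image paired with its (optional) ground-truth nuclei mask
#'
#' The basic unit every pipeline stage consumes: an RGB image with
#' intensities in `[0, 1]` (`height x width x 3` array), an optional binary
#' mask of identical extent (1 = nucleus/tumor foreground) and an id used
#' to pair files on disk.
#'
#' @slot image `height x width x 3` numeric array in `[0, 1]`.
#' @slot mask binary integer matrix of the same height/width, or `NULL`
#'   for unannotated images (the unsupervised branch needs no masks).
#' @slot imageId character scalar.
#' @seealso [generateImage()], [loadDataset()]
#' @exportClass LabeledImage
setClass("LabeledImage",
  representation(image = "array", mask = "matrixOrNULL", imageId = "character")
)

setValidity("LabeledImage", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    return("image must be a height x width x 3 array")
  if (min(object@image) < 0 || max(object@image) > 1)
    return("image intensities must lie in [0, 1]")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), d[1:2]))
      return("mask dimensions must match the image")
    if (!all(object@mask %in% c(0L, 1L)))
      return("mask values must be 0 or 1")
  }
  if (length(object@imageId) != 1L) return("imageId must be a single string")
  TRUE
})

#' A grid of patches cut from one image
#'
#' Holds the patches produced by [extractPatches()] together with the
#' geometry needed to reassemble them exactly: top-left coordinates on the
#' (reflect-padded) canvas, the patch size and stride, and the original and
#' padded extents. Coordinates are 0-based, row-major, origin top-left.
#'
#' @slot patches list of `patchSize x patchSize (x 3)` arrays.
#' @slot coords integer matrix with columns `row`, `col` (0-based top-left
#'   positions on the padded canvas), one row per patch, ordered
#'   left-to-right then top-to-bottom.
#' @slot patchSize,stride pixels.
#' @slot sourceDim,paddedDim `(height, width)` of the original image and of
#'   the padded canvas the grid tiles exactly.
#' @slot channels 3 for image grids, 1 for mask grids.
#' @seealso [extractPatches()], [assembleMask()]
#' @exportClass PatchGrid
setClass("PatchGrid",
  representation(
    patches = "list", coords = "matrix", patchSize = "integer",
    stride = "integer", sourceDim = "integer", paddedDim = "integer",
    channels = "integer"
  )
)

setValidity("PatchGrid", function(object) {
  if (nrow(object@coords) != length(object@patches))
    return("coords must have one row per patch")
  if (object@patchSize < 1L) return("patchSize must be >= 1")
  if (object@stride < 1L || object@stride > object@patchSize)
    return("stride must satisfy 1 <= stride <= patchSize")
  TRUE
})

#' Hyperparameters of the convolutional autoencoder
#'
#' The `(N, C, Z)` triple of the autoencoder plus the square input patch
#' edge: `depth` encoder levels each halve the spatial extent (2x2 max
#' pooling), so `inputSize` must be divisible by `2^depth`; filters double
#' at each level starting from `baseFilters`; the information bottleneck
#' (latent space) has `latentDim` units.
#'
#' @slot depth number of encoder levels (N).
#' @slot baseFilters filters of the first convolution (C).
#' @slot latentDim latent dimensionality (Z).
#' @slot inputSize square patch edge in pixels.
#' @seealso [networkSpec()], [buildCAE()]
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(depth = "integer", baseFilters = "integer",
                 latentDim = "integer", inputSize = "integer")
)

setValidity("NetworkSpec", function(object) {
  if (object@depth < 1L || object@baseFilters < 1L || object@latentDim < 1L)
    return("depth, baseFilters and latentDim must all be >= 1")
  if (object@inputSize %% (2L^object@depth) != 0L)
    return(sprintf("inputSize (%d) must be divisible by 2^depth (%d)",
                   object@inputSize, 2L^object@depth))
  TRUE
})

#' Hyperparameters of the supervised segmentation networks
#'
#' Shared by the improved U-Net and the FCN baseline. `convsPerBlock`
#' controls the extra convolution layers per encoder/decoder block that
#' constitute the "improved" U-Net (3 by default; 2 recovers the classic
#' architecture).
#'
#' @slot depth encoder levels (each followed by 2x2 max pooling).
#' @slot baseFilters filters of the first block; doubled per level.
#' @slot convsPerBlock convolutions per block (>= 1).
#' @slot nClasses output classes (2: tumor / non-tumor).
#' @slot inputSize square tile edge; divisible by `2^depth`.
#' @seealso [segNetworkSpec()], [buildUNet()], [buildFCN()]
#' @exportClass SegNetworkSpec
setClass("SegNetworkSpec",
  representation(depth = "integer", baseFilters = "integer",
                 convsPerBlock = "integer", nClasses = "integer",
                 inputSize = "integer")
)

setValidity("SegNetworkSpec", function(object) {
  if (object@depth < 1L || object@baseFilters < 1L)
    return("depth and baseFilters must be >= 1")
  if (object@convsPerBlock < 1L) return("convsPerBlock must be >= 1")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@inputSize %% (2L^object@depth) != 0L)
    return(sprintf("inputSize (%d) must be divisible by 2^depth (%d)",
                   object@inputSize, 2L^object@depth))
  TRUE
})

#' Fitted convolutional autoencoder
#'
#' @slot spec the [NetworkSpec-class] the model was built from.
#' @slot params named list of weight matrices and vectors.
#' @slot state batch-norm running statistics used at inference time.
#' @slot trained `TRUE` once [trainCAE()] has run.
#' @seealso [buildCAE()], [trainCAE()], [encodePatches()]
#' @exportClass CAEModel
setClass("CAEModel",
  representation(spec = "NetworkSpec", params = "list", state = "list",
                 trained = "logical")
)

#' Fitted segmentation network (improved U-Net or FCN baseline)
#'
#' @slot arch `"unet"` or `"fcn"`.
#' @slot spec the [SegNetworkSpec-class] the model was built from.
#' @slot params named list of weight matrices and vectors.
#' @slot state batch-norm running statistics used at inference time.
#' @slot trained `TRUE` once [trainSegmenter()] has run.
#' @seealso [buildUNet()], [buildFCN()], [predictMask()]
#' @exportClass SegModel
setClass("SegModel",
  representation(arch = "character", spec = "SegNetworkSpec",
                 params = "list", state = "list", trained = "logical")
)

#' Two-cluster model over latent codes
#'
#' The result of 2-means on autoencoder latent codes: the two centroids,
#' the within-cluster sum of squares (inertia) and, once
#' [mapClustersToClasses()] has run, the bijection from anonymous cluster
#' indices to semantic classes (1 = tumor/nuclei, 0 = background).
#'
#' @slot centroids `2 x latentDim` matrix.
#' @slot inertia total within-cluster sum of squared distances.
#' @slot classOfCluster integer vector of length 2 mapping cluster 1 and 2
#'   to class 0/1; `NA` until the cluster-to-class correspondence is set.
#' @seealso [fitKmeans2()], [mapClustersToClasses()]
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(centroids = "matrix", inertia = "numeric",
                 classOfCluster = "integer")
)

setValidity("ClusterModel", function(object) {
  if (nrow(object@centroids) != 2L) return("exactly 2 centroids required")
  if (length(object@inertia) != 1L || object@inertia < 0)
    return("inertia must be a single non-negative number")
  m <- object@classOfCluster
  if (length(m) != 2L) return("classOfCluster must have length 2")
  if (!any(is.na(m)) && !setequal(m, c(0L, 1L)))
    return("classOfCluster must be a bijection onto {0, 1}")
  TRUE
})

#' Per-epoch training record
#'
#' @slot loss mean loss per epoch (reconstruction MSE for the autoencoder,
#'   pixel-wise cross-entropy for the segmenters).
#' @slot accuracy mean pixel accuracy per epoch (`NA` for the autoencoder).
#' @slot epochs number of epochs run.
#' @slot seed the seed that fixed initialization and shuffling.
#' @exportClass TrainingHistory
setClass("TrainingHistory",
  representation(loss = "numeric", accuracy = "numeric", epochs = "integer",
                 seed = "integer")
)

setValidity("TrainingHistory", function(object) {
  if (length(object@loss) != object@epochs)
    return("loss must have one entry per epoch")
  if (any(object@loss < 0)) return("losses must be non-negative")
  TRUE
})

#' Pixel-level confusion counts
#'
#' @slot tp,fp,fn,tn true/false positive/negative pixel counts
#'   (foreground = positive).
#' @seealso [confusionCounts()], [computeMetrics()]
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})

#' The five segmentation metrics
#'
#' Accuracy, recall, precision, F1 and IoU computed from pixel confusion
#' counts. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0 or 1.
#'
#' @slot accuracy,recall,precision,f1,iou numeric in `[0, 1]` or `NA`.
#' @slot imageId id of the evaluated image, or `"aggregate"`/`"pooled"`.
#' @seealso [computeMetrics()], [evaluateDataset()]
#' @exportClass MetricReport
setClass("MetricReport",
  representation(accuracy = "numeric", recall = "numeric",
                 precision = "numeric", f1 = "numeric", iou = "numeric",
                 imageId = "character")
)

setValidity("MetricReport", function(object) {
  for (nm in c("accuracy", "recall", "precision", "f1", "iou")) {
    v <- slot(object, nm)
    if (length(v) != 1L) return(sprintf("%s must be a scalar", nm))
    if (!is.na(v) && (v < 0 || v > 1))
      return(sprintf("%s must lie in [0, 1] when defined", nm))
  }
  TRUE
})
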