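# 2-means over latent codes plus the cluster-to-class correspondence.
# Lloyd iterations come from stats::kmeans; the k-means++ seeding, the
# multi-restart selection by inertia and the deterministic assignment
# tie rule (nearest centroid, ties -> lower index) are implemented here.

kmeansPlusPlusInit <- function(x) {
  n <- nrow(x)
  i1 <- sample.int(n, 1L)
  d2 <- rowSums((x - rep(x[i1, ], each = n))^2)
  if (sum(d2) == 0) stop("degenerate input", call. = FALSE)
  i2 <- sample.int(n, 1L, prob = d2)
  x[c(i1, i2), , drop = FALSE]
}

# Nearest-centroid assignment; ties go to the lower centroid index.
assignClusters <- function(codes, centroids) {
  n <- nrow(codes)
  d1 <- rowSums((codes - rep(centroids[1, ], each = n))^2)
  d2 <- rowSums((codes - rep(centroids[2, ], each = n))^2)
  ifelse(d1 <= d2, 1L, 2L)
}

clusterInertiaOf <- function(codes, centroids, assignment) {
  n <- nrow(codes)
  d1 <- rowSums((codes - rep(centroids[1, ], each = n))^2)
  d2 <- rowSums((codes - rep(centroids[2, ], each = n))^2)
  sum(ifelse(assignment == 1L, d1, d2))
}

#' Fit a 2-cluster K-means model to latent codes
#'
#' Lloyd iterations with k-means++ initialization, repeated `nRestarts`
#' times; on small inputs (up to 24 points) every distinct pair of points
#' is additionally tried as a deterministic seeding, which in practice
#' pins the global optimum on instances small enough to verify by
#' exhaustive enumeration. The solution with the smallest within-cluster
#' sum of squares (inertia) wins. Point assignment is nearest-centroid
#' with ties broken toward the lower centroid index.
#'
#' @param latents `n x latentDim` matrix of latent codes (n >= 2, at
#'   least two distinct rows; all-identical codes raise a degenerate-input
#'   error rather than returning an empty cluster).
#' @param nRestarts number of k-means++ restarts.
#' @param seed seed controlling initialization.
#' @return a [ClusterModel-class] with the class mapping unset.
#' @seealso [mapClustersToClasses()] to set the cluster-to-class mapping.
#' @export
fitKmeans2 <- function(latents, nRestarts = 10L, seed = 0L) {
  latents <- as.matrix(latents)
  if (nrow(latents) < 2L)
    stop("at least two latent codes are required", call. = FALSE)
  if (all(abs(sweep(latents, 2L, latents[1L, ])) < 1e-12))
    stop("degenerate input: all latent codes are identical, no 2-partition exists",
         call. = FALSE)
  # restart pool: nRestarts k-means++ seedings, plus (on small inputs)
  # every distinct pair of points as deterministic extra seedings, so
  # that tiny instances reliably reach the global optimum.
  starts <- vector("list", nRestarts)
  if (nrow(latents) <= 24L) {
    n <- nrow(latents)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (any(latents[i, ] != latents[j, ]))
          starts[[length(starts) + 1L]] <- latents[c(i, j), , drop = FALSE]
      }
    }
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_along(starts)) {
      centers0 <- if (is.null(starts[[r]])) kmeansPlusPlusInit(latents)
                  else starts[[r]]
      km <- tryCatch(
        suppressWarnings(
          stats::kmeans(latents, centers = centers0, iter.max = 100L,
                        algorithm = "Lloyd")
        ),
        error = function(e) list(centers = centers0)
      )
      assignment <- assignClusters(latents, km$centers)
      inertia <- clusterInertiaOf(latents, km$centers, assignment)
      if (is.null(best) || inertia < best$inertia)
        best <- list(centers = km$centers, inertia = inertia)
    }
  })
  new("ClusterModel", centroids = unname(best$centers),
      inertia = best$inertia, classOfCluster = c(NA_integer_, NA_integer_))
}

#' Resolve the cluster-to-class correspondence
#'
#' Clustering leaves the two clusters anonymous; this sets the bijection
#' onto \{tumor = 1, non-tumor = 0\}. With reference masks (evaluation
#' mode) the bijection maximizing pixel accuracy against the references is
#' chosen, ties going to "cluster 1 = non-tumor". Without references
#' (deployment mode) the cluster whose member patches are darker (lower
#' mean Rec.-601 luminance) is labeled tumor — the hematoxylin-dark
#' heuristic.
#'
#' @param clusterModel a [ClusterModel-class] from [fitKmeans2()].
#' @param assignments integer vector of cluster ids (1/2), one per patch.
#' @param patches the image patches the assignments refer to.
#' @param referenceMasks optional list of binary mask patches aligned with
#'   `patches`.
#' @return the [ClusterModel-class] with `classOfCluster` set.
#' @export
mapClustersToClasses <- function(clusterModel, assignments, patches,
                                 referenceMasks = NULL) {
  stopifnot(is(clusterModel, "ClusterModel"))
  if (is(patches, "PatchGrid")) patches <- patches@patches
  if (length(assignments) != length(patches))
    stop("assignments and patches must align", call. = FALSE)
  if (!is.null(referenceMasks)) {
    if (is(referenceMasks, "PatchGrid")) referenceMasks <- referenceMasks@patches
    if (length(referenceMasks) != length(patches))
      stop("referenceMasks and patches must align", call. = FALSE)
    fg <- vapply(referenceMasks, function(m) sum(m == 1L), numeric(1))
    tot <- vapply(referenceMasks, length, numeric(1))
    accOf <- function(mapping) {
      lab <- mapping[assignments]
      sum(ifelse(lab == 1L, fg, tot - fg)) / sum(tot)
    }
    m1 <- c(0L, 1L)  # cluster 1 -> non-tumor
    m2 <- c(1L, 0L)
    mapping <- if (accOf(m1) >= accOf(m2)) m1 else m2
  } else {
    lum <- vapply(patches, function(p) {
      luminance(c(mean(p[, , 1]), mean(p[, , 2]), mean(p[, , 3])))
    }, numeric(1))
    meanLum <- vapply(1:2, function(k) {
      if (any(assignments == k)) mean(lum[assignments == k]) else Inf
    }, numeric(1))
    # darker cluster = nuclei; an empty cluster counts as light background
    mapping <- if (meanLum[1] < meanLum[2]) c(1L, 0L) else c(0L, 1L)
  }
  clusterModel@classOfCluster <- mapping
  clusterModel
}

#' Segment an image with the unsupervised pipeline
#'
#' Patches the image (reflect padding as in [extractPatches()]), encodes
#' every patch with the trained autoencoder, assigns each latent code to
#' its nearest cluster centroid, maps clusters to classes and broadcasts
#' each patch's class to its pixels via [assembleMask()] — with an
#' overlapping stride each pixel takes the majority over covering patches.
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param caeModel a trained [CAEModel-class].
#' @param clusterModel a [ClusterModel-class] with the class mapping set.
#' @param patchSize patch edge; defaults to the autoencoder input size.
#' @param stride patch stride; values below `patchSize` refine the
#'   segmentation granularity by per-pixel voting.
#' @return binary mask matrix of the image's extent.
#' @export
segmentUnsupervised <- function(image, caeModel, clusterModel,
                                patchSize = caeModel@spec@inputSize,
                                stride = patchSize) {
  stopifnot(is(caeModel, "CAEModel"), is(clusterModel, "ClusterModel"))
  if (any(is.na(clusterModel@classOfCluster)))
    stop("cluster-to-class mapping unset; run mapClustersToClasses() first",
         call. = FALSE)
  if (patchSize != caeModel@spec@inputSize)
    stop("patchSize must equal the autoencoder input size", call. = FALSE)
  grid <- extractPatches(image, patchSize, stride)
  codes <- encodePatches(caeModel, grid)
  assignment <- assignClusters(codes, clusterModel@centroids)
  labels <- clusterModel@classOfCluster[assignment]
  assembleMask(as.list(labels), grid)
}
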