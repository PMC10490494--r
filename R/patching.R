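# Patch extraction / reassembly and rotation augmentation. All grids are
# regular, row-major, 0-based, origin top-left. When the image extent is
# not covered exactly, the bottom/right are reflect-padded (mirror
# without repeating the edge row/column) to the smallest covered size.

paddedExtent <- function(size, patchSize, stride) {
  nSteps <- if (size <= patchSize) 1L
            else as.integer(ceiling((size - patchSize) / stride)) + 1L
  c(steps = nSteps, padded = patchSize + (nSteps - 1L) * stride)
}

reflectPad <- function(px, targetH, targetW) {
  H <- dim(px)[1] %||% nrow(px)
  W <- dim(px)[2] %||% ncol(px)
  ri <- reflectIndex(seq_len(targetH), H)
  ci <- reflectIndex(seq_len(targetW), W)
  if (length(dim(px)) == 3L) px[ri, ci, , drop = FALSE] else px[ri, ci, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extractGrid <- function(px, patchSize, stride) {
  if (patchSize < 1L) stop("patchSize must be >= 1", call. = FALSE)
  if (stride < 1L || stride > patchSize)
    stop("stride must satisfy 1 <= stride <= patchSize", call. = FALSE)
  is3d <- length(dim(px)) == 3L
  H <- dim(px)[1]
  W <- dim(px)[2]
  eh <- paddedExtent(H, patchSize, stride)
  ew <- paddedExtent(W, patchSize, stride)
  padded <- reflectPad(px, eh["padded"], ew["padded"])
  patches <- vector("list", eh["steps"] * ew["steps"])
  coords <- matrix(0L, length(patches), 2L,
                   dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (gr in seq_len(eh["steps"]) - 1L) {       # top-to-bottom
    for (gc in seq_len(ew["steps"]) - 1L) {     # left-to-right
      k <- k + 1L
      r0 <- gr * stride
      c0 <- gc * stride
      coords[k, ] <- c(r0, c0)
      patches[[k]] <- if (is3d)
        padded[r0 + seq_len(patchSize), c0 + seq_len(patchSize), , drop = FALSE]
      else
        padded[r0 + seq_len(patchSize), c0 + seq_len(patchSize), drop = FALSE]
    }
  }
  new("PatchGrid", patches = patches, coords = coords,
      patchSize = as.integer(patchSize), stride = as.integer(stride),
      sourceDim = c(H, W), paddedDim = as.integer(c(eh["padded"], ew["padded"])),
      channels = if (is3d) 3L else 1L)
}

#' Cut an RGB image into square patches
#'
#' Covers the image left-to-right, top-to-bottom with `patchSize` x
#' `patchSize` patches at the given stride; if a dimension is not covered
#' exactly the image is reflect-padded on the bottom/right first, and the
#' padded extent is recorded so [assembleMask()] can crop it away again.
#'
#' @param image `height x width x 3` array.
#' @param patchSize patch edge in pixels (default 32).
#' @param stride step between patch origins, `1 <= stride <= patchSize`;
#'   the default `stride = patchSize` gives non-overlapping tiles.
#' @return a [PatchGrid-class].
#' @examples
#' img <- getImage(generateImage(syntheticParams(64, 64, nNuclei = 2)))
#' patchCount(extractPatches(img, 32))  # 4 patches on a 2 x 2 grid
#' @export
extractPatches <- function(image, patchSize = 32L, stride = patchSize) {
  if (length(dim(image)) != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  extractGrid(image, as.integer(patchSize), as.integer(stride))
}

#' Cut a binary mask into patches on the same geometry as [extractPatches()]
#'
#' @param mask binary matrix.
#' @inheritParams extractPatches
#' @return a [PatchGrid-class] of single-channel binary patches.
#' @export
extractMaskPatches <- function(mask, patchSize = 32L, stride = patchSize) {
  mask <- asBinaryMatrix(mask)
  extractGrid(mask, as.integer(patchSize), as.integer(stride))
}

#' Label one mask patch as tumor or non-tumor
#'
#' A patch is labeled positive (1 = cancer/tumor) iff its foreground
#' fraction reaches `positiveFraction`; the default 0.5 is a majority
#' rule.
#'
#' @param maskPatch binary matrix.
#' @param positiveFraction proportion in `(0, 1]`.
#' @return integer 0 or 1.
#' @export
labelPatch <- function(maskPatch, positiveFraction = 0.5) {
  if (length(maskPatch) == 0L)
    stop("maskPatch must be non-empty", call. = FALSE)
  maskPatch <- asBinaryMatrix(maskPatch, "maskPatch")
  as.integer(mean(maskPatch) >= positiveFraction)
}

#' Reassemble per-patch labels or mask patches into a pixel mask
#'
#' Scalar labels are broadcast to every pixel of their patch; mask patches
#' are placed at their grid coordinates. With an overlapping grid
#' (`stride < patchSize`) each pixel takes the majority vote over all
#' covering patches, with ties resolved to foreground (favoring nuclei
#' recall). The padded border is cropped so the output matches the source
#' image exactly.
#'
#' @param labels either a vector/list of per-patch 0/1 labels, a list of
#'   binary patch matrices, or a [PatchGrid-class] of mask patches.
#' @param grid the [PatchGrid-class] the labels refer to.
#' @return binary integer matrix of the grid's source extent.
#' @export
assembleMask <- function(labels, grid) {
  if (is(labels, "PatchGrid")) labels <- labels@patches
  if (!is.list(labels)) labels <- as.list(labels)
  if (length(labels) != patchCount(grid))
    stop(sprintf("got %d labels for %d grid cells", length(labels),
                 patchCount(grid)), call. = FALSE)
  ph <- grid@paddedDim[1]
  pw <- grid@paddedDim[2]
  votes <- matrix(0, ph, pw)
  count <- matrix(0, ph, pw)
  ps <- grid@patchSize
  for (k in seq_along(labels)) {
    v <- labels[[k]]
    if (length(v) != 1L && length(v) != ps * ps)
      stop("each label must be a scalar or a patchSize x patchSize mask",
           call. = FALSE)
    rows <- grid@coords[k, 1] + seq_len(ps)
    cols <- grid@coords[k, 2] + seq_len(ps)
    votes[rows, cols] <- votes[rows, cols] + as.numeric(v)
    count[rows, cols] <- count[rows, cols] + 1
  }
  out <- matrix(as.integer(2 * votes >= count), ph, pw)
  out[seq_len(grid@sourceDim[1]), seq_len(grid@sourceDim[2]), drop = FALSE]
}

# Exact counterclockwise right-angle rotation (array coordinates).
rot90ccw <- function(m) {
  if (length(dim(m)) == 3L) {
    out <- array(0, dim = c(dim(m)[2], dim(m)[1], dim(m)[3]))
    for (ch in seq_len(dim(m)[3])) out[, , ch] <- rot90ccw(m[, , ch])
    return(out)
  }
  t(m[, ncol(m):1, drop = FALSE])
}

rotateRightAngle <- function(px, k) {
  k <- k %% 4L
  while (k > 0L) {
    px <- rot90ccw(px)
    k <- k - 1L
  }
  px
}

# Arbitrary-angle rotation about the center: inverse mapping with
# reflect fill; bilinear resampling for images, nearest for masks (so
# masks stay binary). Canvas kept at the original size.
rotateResample <- function(px, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  is3d <- length(dim(px)) == 3L
  H <- dim(px)[1]
  W <- dim(px)[2]
  a <- angle * pi / 180
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  yd <- matrix(seq_len(H) - cy, H, W)
  xd <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  ys <- -xd * sin(a) + yd * cos(a) + cy
  xs <- xd * cos(a) + yd * sin(a) + cx
  sampleOne <- function(plane) {
    if (interp == "nearest") {
      ri <- reflectIndex(as.integer(round(ys)), H)
      ci <- reflectIndex(as.integer(round(xs)), W)
      return(matrix(plane[cbind(as.vector(ri), as.vector(ci))], H, W))
    }
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0;   fx <- xs - x0
    g <- function(r, c) plane[cbind(as.vector(reflectIndex(as.integer(r), H)),
                                    as.vector(reflectIndex(as.integer(c), W)))]
    v <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
         fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
    matrix(v, H, W)
  }
  if (!is3d) return(sampleOne(px))
  out <- array(0, dim = dim(px))
  for (ch in seq_len(dim(px)[3])) out[, , ch] <- sampleOne(px[, , ch])
  out
}

rotatePixels <- function(px, angle, interp) {
  angle <- angle %% 360
  if (angle %% 90 == 0) rotateRightAngle(px, as.integer(angle %/% 90))
  else rotateResample(px, angle, interp)
}

#' Augment a dataset by rotation
#'
#' Rotates image and mask identically for every requested angle.
#' Multiples of 90 degrees are exact (lossless, pixel permutations);
#' other angles use bilinear resampling for the image and
#' nearest-neighbor for the mask, with reflect fill on the original
#' canvas, so masks stay strictly binary. Angle 0 returns the item
#' unchanged; rotated copies get ids suffixed `_rot<angle>`.
#'
#' @param dataset list of [LabeledImage-class].
#' @param angles non-empty numeric vector of degrees; default
#'   `c(0, 90, 180, 270)`.
#' @return list of `length(dataset) * length(angles)` items.
#' @export
augmentRotations <- function(dataset, angles = c(0, 90, 180, 270)) {
  if (length(angles) == 0L)
    stop("angles must be non-empty", call. = FALSE)
  out <- vector("list", length(dataset) * length(angles))
  k <- 0L
  for (item in dataset) {
    for (ang in angles) {
      k <- k + 1L
      if (ang %% 360 == 0) {
        out[[k]] <- item
        next
      }
      img <- clip01(rotatePixels(item@image, ang, "bilinear"))
      mask <- if (is.null(item@mask)) NULL
              else rotatePixels(item@mask, ang, "nearest")
      out[[k]] <- labeledImage(img, mask, paste0(item@imageId, "_rot", ang))
    }
  }
  out
}
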