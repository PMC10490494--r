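# Synthetic H&E-like tile generator: elliptical "nuclei" in a
# hematoxylin-like color on an eosin-like background, with a pixel-exact
# binary ground-truth mask. Noise perturbs the image only, never the mask.

#' Generate one synthetic H&E-like image with its ground-truth mask
#'
#' Renders `nNuclei` filled ellipses with random center, orientation,
#' semi-major axis drawn from `radiusRange` and eccentricity from
#' `eccentricityRange`, clipped to the canvas. Overlapping ellipses union
#' into one mask. The mask marks exactly the rendered foreground; additive
#' Gaussian noise (clipped to `[0, 1]`) is applied to the image afterwards
#' and never touches the mask. Identical parameters (including the seed)
#' give bit-identical output.
#'
#' @param params a [SyntheticParams-class] object.
#' @return a [LabeledImage-class] with a pixel-exact mask.
#' @examples
#' img <- generateImage(syntheticParams(imageHeight = 64, imageWidth = 64,
#'                                      nNuclei = 3, seed = 7))
#' mean(getMask(img))  # foreground fraction
#' @export
generateImage <- function(params) {
  validObject(params)
  H <- params@imageHeight
  W <- params@imageWidth
  withSeed(params@seed, {
    mask <- matrix(0L, H, W)
    placed <- matrix(numeric(0), 0, 3)  # cy, cx, a of accepted nuclei
    n <- params@nNuclei
    i <- 0L
    while (i < n) {
      tries <- 0L
      repeat {
        cy <- runif(1, 1, H)
        cx <- runif(1, 1, W)
        a <- runif(1, params@radiusRange[1], params@radiusRange[2])
        ecc <- runif(1, params@eccentricityRange[1], params@eccentricityRange[2])
        theta <- runif(1, 0, pi)
        if (params@allowOverlap || nrow(placed) == 0L ||
            all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                placed[, 3] + a)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not place non-overlapping nuclei; reduce nNuclei or radiusRange",
               call. = FALSE)
      }
      b <- a * sqrt(1 - ecc^2)
      rows <- max(1L, floor(cy - a)):min(H, ceiling(cy + a))
      cols <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
      dy <- rows - cy
      dx <- cols - cx
      u <- outer(dy, dx, function(y, x) x * cos(theta) + y * sin(theta))
      v <- outer(dy, dx, function(y, x) -x * sin(theta) + y * cos(theta))
      inside <- (u / a)^2 + (v / b)^2 <= 1
      sub <- mask[rows, cols, drop = FALSE]
      sub[inside] <- 1L
      mask[rows, cols] <- sub
      placed <- rbind(placed, c(cy, cx, a))
      i <- i + 1L
    }
    img <- array(0, dim = c(H, W, 3))
    fg <- mask == 1L
    for (ch in 1:3) {
      plane <- matrix(params@backgroundColor[ch], H, W)
      plane[fg] <- params@nucleusColor[ch]
      img[, , ch] <- plane
    }
    if (params@noiseSd > 0) {
      img <- clip01(img + array(rnorm(length(img), 0, params@noiseSd), dim(img)))
    }
    labeledImage(img, mask, sprintf("synth%010d", params@seed))
  })
}

#' Generate a deterministic synthetic dataset
#'
#' Per-image seeds are derived deterministically from `params@seed`, so two
#' calls with identical arguments return elementwise identical datasets.
#'
#' @param nImages number of images (>= 0).
#' @param params a [SyntheticParams-class]; its seed anchors the dataset.
#' @return list of [LabeledImage-class] with distinct ids `img001`, ...
#' @export
generateDataset <- function(nImages, params) {
  if (length(nImages) != 1L || is.na(nImages) || nImages < 0)
    stop("nImages must be a single non-negative integer", call. = FALSE)
  validObject(params)
  nImages <- as.integer(nImages)
  lapply(seq_len(nImages), function(i) {
    p <- params
    p@seed <- as.integer((as.numeric(params@seed) * 10007 + i * 7919) %%
                           2147483629)
    out <- generateImage(p)
    out@imageId <- sprintf("img%03d", i)
    out
  })
}

#' Write a dataset to disk as paired PNG files
#'
#' Each item becomes `<id>.png` (RGB image) and, when a mask is present,
#' `<id>_mask.png` (8-bit single channel, 0/255) — the layout
#' [loadDataset()] reads back.
#'
#' @param dataset list of [LabeledImage-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the image file paths.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(dataset, function(item) {
    path <- file.path(dir, paste0(item@imageId, ".png"))
    writeImage(item@image, path)
    if (!is.null(item@mask))
      writeMask(item@mask, file.path(dir, paste0(item@imageId, "_mask.png")))
    path
  }, character(1))
  invisible(paths)
}
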