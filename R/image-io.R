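# Reading and writing images/masks (PNG and TIFF) and loading a dataset
# directory in the <id>.png / <id>_mask.png pairing convention.

readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  # both readers scale 8/16-bit samples to [0, 1]
  px
}

#' Read an RGB image
#'
#' PNG or TIFF, 8- or 16-bit; intensities are scaled to `[0, 1]`.
#' Grayscale inputs are replicated to 3 channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path file path.
#' @return `height x width x 3` numeric array in `[0, 1]`.
#' @export
readImage <- function(path) {
  px <- readRaster(path)
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 1L) px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Read a binary ground-truth mask
#'
#' Uses the first channel of the file and thresholds the `[0, 1]`-scaled
#' intensity: a pixel is foreground iff its intensity exceeds `threshold`,
#' so an 8-bit 0/255 mask decodes to 0/1 exactly.
#'
#' @param path file path.
#' @param threshold intensity cut in `[0, 1)`; default 0.5.
#' @return binary integer matrix (1 = nucleus).
#' @export
readMask <- function(path, threshold = 0.5) {
  px <- readRaster(path)
  if (!is.matrix(px)) px <- px[, , 1]
  matrix(as.integer(px > threshold), nrow(px), ncol(px))
}

#' Write an RGB image as PNG or TIFF
#'
#' @param image `height x width x 3` array in `[0, 1]` (clipped on write).
#' @param path destination; extension selects the format.
#' @return invisibly, `path`.
#' @export
writeImage <- function(image, path) {
  px <- clip01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0 -> 0, 1 -> 255)
#'
#' `readMask(writeMask(m))` is the identity.
#'
#' @param mask binary matrix.
#' @param path destination `.png` path.
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  mask <- asBinaryMatrix(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Load a dataset directory of images with optional paired masks
#'
#' Picks up every `<id>.png`/`<id>.tif`/`<id>.tiff` that is not itself a
#' mask file and pairs it with `<id>_mask.png` when present; images
#' without a mask get `mask = NULL` and remain usable by the unsupervised
#' branch. An empty directory yields an empty list.
#'
#' @param dir directory path.
#' @param maskSuffix suffix identifying mask files (default `"_mask"`).
#' @return list of [LabeledImage-class].
#' @export
loadDataset <- function(dir, maskSuffix = "_mask") {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  ids <- tools::file_path_sans_ext(files)
  keep <- !endsWith(ids, maskSuffix)
  files <- files[keep]
  ids <- ids[keep]
  ord <- order(ids)
  mapply(function(f, id) {
    img <- readImage(file.path(dir, f))
    maskPath <- file.path(dir, paste0(id, maskSuffix, ".png"))
    mask <- NULL
    if (file.exists(maskPath)) {
      mask <- readMask(maskPath)
      if (!identical(dim(mask), dim(img)[1:2]))
        stop(sprintf("mask size (%d x %d) does not match image '%s' (%d x %d)",
                     nrow(mask), ncol(mask), id, dim(img)[1], dim(img)[2]),
             call. = FALSE)
    }
    labeledImage(img, mask, id)
  }, files[ord], ids[ord], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
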