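# Shared fixtures and independent oracles used across test files.

# Small easy-contrast synthetic tile parameters.
tinyParams <- function(h = 48, w = 48, n = 3, seed = 5, noise = 0,
                       overlap = TRUE, radius = c(5, 9), ecc = c(0, 0.8)) {
  syntheticParams(imageHeight = h, imageWidth = w, nNuclei = n,
                  radiusRange = radius, eccentricityRange = ecc,
                  noiseSd = noise, allowOverlap = overlap, seed = seed)
}

randomMask <- function(h, w, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Independent metric oracle: cross-tabulate pixels, then apply the metric
# definitions directly. Shares no code with the package path.
oracleMetrics <- function(pred, truth) {
  tab <- table(factor(as.vector(pred), levels = c(0, 1)),
               factor(as.vector(truth), levels = c(0, 1)))
  tp <- tab["1", "1"]; fp <- tab["1", "0"]
  fn <- tab["0", "1"]; tn <- tab["0", "0"]
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = prec, recall = rec,
       f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
            else 2 * rec * prec / (rec + prec),
       iou = div(tp, tp + fp + fn))
}

# Exhaustive optimal 2-partition sum of squared distances (the K-means
# oracle): enumerate every non-trivial bipartition of <= 10 points.
bruteForce2PartitionSSE <- function(x) {
  n <- nrow(x)
  stopifnot(n <= 12)
  best <- Inf
  sseOf <- function(rows) {
    if (length(rows) == 0L) return(0)
    mu <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2L, mu)^2)
  }
  for (code in 0:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    best <- min(best, sseOf(which(inA)) + sseOf(which(!inA)))
  }
  best
}

# A tiny trained U-Net/FCN is expensive; build a "constant head" model
# whose logits are fixed, for contract tests that need a trained model.
forcedSegModel <- function(activations = c(0, 10), inputSize = 16L) {
  spec <- segNetworkSpec(depth = 2L, baseFilters = 4L, convsPerBlock = 2L,
                         inputSize = inputSize)
  model <- buildUNet(spec, initSeed = 1L)
  model@params$head$W <- matrix(0, nrow(model@params$head$W), 2L)
  model@params$head$b <- activations
  model@trained <- TRUE
  model
}
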