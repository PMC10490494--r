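# Supervised segmentation networks. The improved U-Net: encoder blocks of
# convsPerBlock x [3x3 conv -> BN -> ReLU] followed by 2x2 max pooling, a
# bottom block, and a symmetric decoder of 2x2 up-convolutions with
# concatenation of the matching encoder map at every level; head = 1x1
# conv to nClasses + pixel-wise softmax. convsPerBlock = 2 recovers the
# classic U-Net; >= 3 is the improved variant. The FCN baseline: an
# AlexNet-style encoder (7x7 first conv, no skip connections), a 1x1
# classifier at coarse resolution and transposed-convolution upsampling
# back to the input size.

unetFilters <- function(spec) spec@baseFilters * 2L^(0:spec@depth)

#' Pixel-wise softmax over an activation map
#'
#' Channel-normalized exponential at each pixel:
#' `p_k(x) = exp(a_k(x)) / sum_k' exp(a_k'(x))`, numerically stabilized by
#' subtracting the per-pixel maximum (the result is invariant to adding a
#' constant to all channels of a pixel).
#'
#' @param activations `height x width x K` array of finite reals, K >= 2.
#' @return array of the same shape; per-pixel channel sums are 1.
#' @examples
#' a <- array(c(1, 0), dim = c(1, 1, 2))
#' pixelSoftmax(a)[1, 1, ]  # exp(1)/(exp(1)+1), 1/(exp(1)+1)
#' @export
pixelSoftmax <- function(activations) {
  d <- dim(activations)
  if (length(d) != 3L || d[3] < 2L)
    stop("activations must be a height x width x K array with K >= 2",
         call. = FALSE)
  if (!all(is.finite(activations)))
    stop("activations must be finite", call. = FALSE)
  logits <- matrix(activations, d[1] * d[2], d[3])
  array(softmaxRows(logits), dim = d)
}

#' Build the improved U-Net
#'
#' @param spec a [SegNetworkSpec-class].
#' @param initSeed seed for weight initialization.
#' @return an untrained [SegModel-class] with `arch = "unet"`.
#' @export
buildUNet <- function(spec, initSeed = 0L) {
  validObject(spec)
  withSeed(initSeed, {
    g <- unetFilters(spec)
    cpb <- spec@convsPerBlock
    encBlock <- function(cin, f) {
      lapply(seq_len(cpb), function(j) {
        list(conv = newConv(3L, if (j == 1L) cin else f, f), bn = newBN(f))
      })
    }
    enc <- lapply(seq_len(spec@depth), function(l) {
      encBlock(if (l == 1L) 3L else g[l - 1L], g[l])
    })
    bottom <- encBlock(g[spec@depth], g[spec@depth + 1L])
    dec <- lapply(rev(seq_len(spec@depth)), function(l) {
      list(up = newUpconv(g[l + 1L], g[l]),
           convs = encBlock(2L * g[l], g[l]))
    })
    params <- list(enc = enc, bottom = bottom, dec = dec,
                   head = newConv(1L, g[1L], spec@nClasses))
    new("SegModel", arch = "unet", spec = spec, params = params,
        state = list(), trained = FALSE)
  })
}

#' Build the FCN baseline
#'
#' AlexNet-style convolutional encoder (large 7x7 first kernel, 5x5
#' second, 3x3 after; no skip connections), fully connected layers recast
#' as convolutions, a 1x1 classifier at the coarse resolution and `depth`
#' 2x2 transposed convolutions back to full resolution. Shares the
#' [SegNetworkSpec-class], the output contract and [trainSegmenter()]
#' with the U-Net.
#'
#' @inheritParams buildUNet
#' @return an untrained [SegModel-class] with `arch = "fcn"`.
#' @export
buildFCN <- function(spec, initSeed = 0L) {
  validObject(spec)
  withSeed(initSeed, {
    kOf <- function(l) if (l == 1L) 7L else if (l == 2L) 5L else 3L
    fOf <- function(l) spec@baseFilters * 2L^min(l, 3L)
    levels <- lapply(seq_len(spec@depth), function(l) {
      cin <- if (l == 1L) 3L else fOf(l - 1L)
      list(conv = newConv(kOf(l), cin, fOf(l)), bn = newBN(fOf(l)))
    })
    fc <- list(conv = newConv(3L, fOf(spec@depth), spec@baseFilters * 8L),
               bn = newBN(spec@baseFilters * 8L))
    # upsampling stages start as exact nearest-neighbor interpolation of
    # the class scores (the standard FCN deconv initialization), so the
    # coarse classifier is usable from the first epoch
    interpUp <- function(K) {
      W <- matrix(0, K, 4L * K)
      for (f in seq_len(K)) W[f, f + K * (0:3)] <- 1
      list(W = W, b = numeric(K))
    }
    params <- list(
      levels = levels, fc = fc,
      cls = newConv(1L, spec@baseFilters * 8L, spec@nClasses),
      ups = lapply(seq_len(spec@depth), function(i)
        interpUp(spec@nClasses))
    )
    new("SegModel", arch = "fcn", spec = spec, params = params,
        state = list(), trained = FALSE)
  })
}

# ---- U-Net forward/backward ---------------------------------------------

unetForward <- function(params, spec, A, N, state, training) {
  g <- unetFilters(spec)
  cpb <- spec@convsPerBlock
  sz <- spec@inputSize
  runBlock <- function(A, block, sz, keyBase) {
    caches <- vector("list", length(block))
    for (j in seq_along(block)) {
      cv <- convFwd(A, sz, sz, N, block[[j]]$conv)
      bn <- bnFwd(cv$out, block[[j]]$bn, state, paste0(keyBase, "_", j),
                  training)
      state <<- bn$state
      A <- reluFwd(bn$out)
      caches[[j]] <- list(conv = cv, bn = bn$cache, pre = bn$out)
    }
    list(A = A, caches = caches)
  }
  caches <- list(enc = vector("list", spec@depth),
                 dec = vector("list", spec@depth))
  skips <- vector("list", spec@depth)
  for (l in seq_len(spec@depth)) {
    rb <- runBlock(A, params$enc[[l]], sz, paste0("enc", l))
    skips[[l]] <- rb$A
    pl <- maxpool2_fwd(rb$A, sz, sz, N)
    caches$enc[[l]] <- list(block = rb$caches, pool = pl$idx,
                            rowsIn = nrow(rb$A), size = sz)
    A <- pl$out
    sz <- sz %/% 2L
  }
  rb <- runBlock(A, params$bottom, sz, "bottom")
  caches$bottom <- list(block = rb$caches, size = sz)
  A <- rb$A
  for (i in seq_len(spec@depth)) {
    l <- spec@depth - i + 1L
    up <- upconvFwd(A, sz, sz, N, params$dec[[i]]$up)
    sz <- sz * 2L
    A <- cbind(up$out, skips[[l]])
    rb <- runBlock(A, params$dec[[i]]$convs, sz, paste0("dec", l))
    caches$dec[[i]] <- list(up = up, block = rb$caches, size = sz,
                            gl = g[l])
    A <- rb$A
  }
  hd <- convFwd(A, sz, sz, N, params$head)
  caches$head <- hd
  list(logits = hd$out, caches = caches, state = state)
}

unetBackward <- function(params, spec, caches, dLogits, N) {
  g <- unetFilters(spec)
  S <- spec@inputSize
  blockBwd <- function(dA, block, blockCaches, sz, cin) {
    grads <- vector("list", length(block))
    for (j in rev(seq_along(block))) {
      cc <- blockCaches[[j]]
      dPre <- reluBwd(dA, cc$pre)
      bb <- bnBwd(dPre, cc$bn, block[[j]]$bn)
      cinj <- if (j == 1L) cin else length(block[[j]]$conv$b)
      cb <- convBwd(bb$dA, cc$conv, block[[j]]$conv, sz, sz, N, cinj)
      grads[[j]] <- list(conv = list(W = cb$dW, b = cb$db),
                         bn = list(gamma = bb$dgamma, beta = bb$dbeta))
      dA <- cb$dA
    }
    list(dA = dA, grads = grads)
  }
  grads <- list(enc = vector("list", spec@depth),
                dec = vector("list", spec@depth))
  hb <- convBwd(dLogits, caches$head, params$head, S, S, N, g[1L])
  grads$head <- list(W = hb$dW, b = hb$db)
  dA <- hb$dA
  dSkips <- vector("list", spec@depth)
  for (i in rev(seq_len(spec@depth))) {
    l <- spec@depth - i + 1L
    cc <- caches$dec[[i]]
    bw <- blockBwd(dA, params$dec[[i]]$convs, cc$block, cc$size, 2L * cc$gl)
    grads$dec[[i]] <- list(convs = bw$grads)
    dUp <- bw$dA[, seq_len(cc$gl), drop = FALSE]
    dSkips[[l]] <- bw$dA[, cc$gl + seq_len(cc$gl), drop = FALSE]
    ub <- upconvBwd(dUp, cc$up, params$dec[[i]]$up,
                    cc$size %/% 2L, cc$size %/% 2L, N)
    grads$dec[[i]]$up <- list(W = ub$dW, b = ub$db)
    dA <- ub$dA
  }
  bw <- blockBwd(dA, params$bottom, caches$bottom$block, caches$bottom$size,
                 g[spec@depth])
  grads$bottom <- bw$grads
  dA <- bw$dA
  for (l in rev(seq_len(spec@depth))) {
    cc <- caches$enc[[l]]
    dA <- maxpool2_bwd(dA, cc$pool, cc$rowsIn) + dSkips[[l]]
    cin <- if (l == 1L) 3L else g[l - 1L]
    bw <- blockBwd(dA, params$enc[[l]], cc$block, cc$size, cin)
    grads$enc[[l]] <- bw$grads
    dA <- bw$dA
  }
  grads
}

# ---- FCN forward/backward -----------------------------------------------

fcnForward <- function(params, spec, A, N, state, training) {
  sz <- spec@inputSize
  caches <- list(levels = vector("list", spec@depth))
  for (l in seq_len(spec@depth)) {
    cv <- convFwd(A, sz, sz, N, params$levels[[l]]$conv)
    bn <- bnFwd(cv$out, params$levels[[l]]$bn, state, paste0("lvl", l),
                training)
    state <- bn$state
    rl <- reluFwd(bn$out)
    pl <- maxpool2_fwd(rl, sz, sz, N)
    caches$levels[[l]] <- list(conv = cv, bn = bn$cache, pre = bn$out,
                               pool = pl$idx, rowsIn = nrow(rl), size = sz)
    A <- pl$out
    sz <- sz %/% 2L
  }
  cv <- convFwd(A, sz, sz, N, params$fc$conv)
  bn <- bnFwd(cv$out, params$fc$bn, state, "fc", training)
  state <- bn$state
  A <- reluFwd(bn$out)
  caches$fc <- list(conv = cv, bn = bn$cache, pre = bn$out, size = sz)
  cl <- convFwd(A, sz, sz, N, params$cls)
  caches$cls <- cl
  A <- cl$out
  caches$ups <- vector("list", spec@depth)
  for (i in seq_len(spec@depth)) {
    up <- upconvFwd(A, sz, sz, N, params$ups[[i]])
    caches$ups[[i]] <- list(up = up, size = sz)
    A <- up$out
    sz <- sz * 2L
  }
  list(logits = A, caches = caches, state = state)
}

fcnBackward <- function(params, spec, caches, dLogits, N) {
  grads <- list(levels = vector("list", spec@depth),
                ups = vector("list", spec@depth))
  dA <- dLogits
  for (i in rev(seq_len(spec@depth))) {
    cc <- caches$ups[[i]]
    ub <- upconvBwd(dA, cc$up, params$ups[[i]], cc$size, cc$size, N)
    grads$ups[[i]] <- list(W = ub$dW, b = ub$db)
    dA <- ub$dA
  }
  szc <- caches$cls
  cb <- convBwd(dA, szc, params$cls, caches$fc$size, caches$fc$size, N,
                spec@baseFilters * 8L)
  grads$cls <- list(W = cb$dW, b = cb$db)
  dA <- cb$dA
  cc <- caches$fc
  dPre <- reluBwd(dA, cc$pre)
  bb <- bnBwd(dPre, cc$bn, params$fc$bn)
  fOf <- function(l) spec@baseFilters * 2L^min(l, 3L)
  cb <- convBwd(bb$dA, cc$conv, params$fc$conv, cc$size, cc$size, N,
                fOf(spec@depth))
  grads$fc <- list(conv = list(W = cb$dW, b = cb$db),
                   bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  dA <- cb$dA
  for (l in rev(seq_len(spec@depth))) {
    cc <- caches$levels[[l]]
    dA <- maxpool2_bwd(dA, cc$pool, cc$rowsIn)
    dPre <- reluBwd(dA, cc$pre)
    bb <- bnBwd(dPre, cc$bn, params$levels[[l]]$bn)
    cin <- if (l == 1L) 3L else fOf(l - 1L)
    cb <- convBwd(bb$dA, cc$conv, params$levels[[l]]$conv, cc$size, cc$size,
                  N, cin)
    grads$levels[[l]] <- list(conv = list(W = cb$dW, b = cb$db),
                              bn = list(gamma = bb$dgamma, beta = bb$dbeta))
    dA <- cb$dA
  }
  grads
}

segForward <- function(model, A, N, training) {
  if (model@arch == "unet")
    unetForward(model@params, model@spec, A, N, model@state, training)
  else
    fcnForward(model@params, model@spec, A, N, model@state, training)
}

segBackward <- function(model, caches, dLogits, N) {
  if (model@arch == "unet")
    unetBackward(model@params, model@spec, caches, dLogits, N)
  else
    fcnBackward(model@params, model@spec, caches, dLogits, N)
}

#' Count the trainable parameters of a model
#'
#' @param model a [SegModel-class] or [CAEModel-class].
#' @return total number of trainable scalars.
#' @export
countParams <- function(model) {
  walk <- function(p) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      return(sum(vapply(keys, function(k) {
        if (identical(k, "k")) 0 else walk(p[[k]])
      }, numeric(1))))
    }
    length(p)
  }
  walk(model@params)
}

# ---- training and prediction --------------------------------------------

segDatasetToMatrices <- function(dataset, S) {
  if (length(dataset) == 0L)
    stop("dataset must be non-empty", call. = FALSE)
  lapply(dataset, function(item) {
    if (is(item, "LabeledImage")) item <- list(image = item@image,
                                               mask = item@mask)
    img <- item$image
    mask <- item$mask
    if (is.null(mask)) stop("every training item needs a mask", call. = FALSE)
    if (!all(mask %in% c(0L, 1L)))
      stop("mask values must be 0 or 1", call. = FALSE)
    d <- dim(img)
    if (d[1] != S || d[2] != S)
      stop(sprintf("training tiles must be %d x %d to match the network", S, S),
           call. = FALSE)
    list(X = matrix(img, S * S, 3L), y = as.integer(mask))
  })
}

#' Train a segmentation network
#'
#' Minimizes the pixel-wise softmax cross-entropy against the one-hot
#' ground truth with Adam; records per-epoch mean loss and pixel
#' accuracy. The seed fixes shuffling, so identical inputs reproduce the
#' history exactly. Works for both U-Net and FCN models.
#'
#' @param model an untrained or pre-trained [SegModel-class].
#' @param dataset list of training tiles: [LabeledImage-class] objects or
#'   `list(image =, mask =)` pairs, each `inputSize x inputSize`.
#' @param epochs passes over the data.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size (tiles per step).
#' @param seed seed for shuffling.
#' @return list with elements `model` and `history`
#'   (a [TrainingHistory-class] with loss and pixel accuracy).
#' @export
trainSegmenter <- function(model, dataset, epochs = 20L, learningRate = 1e-3,
                           batchSize = 8L, seed = 0L) {
  stopifnot(is(model, "SegModel"))
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  S <- model@spec@inputSize
  items <- segDatasetToMatrices(dataset, S)
  n <- length(items)
  params <- model@params
  state <- model@state
  opt <- adamInit(params)
  losses <- numeric(epochs)
  accs <- numeric(epochs)
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      bl <- numeric(0)
      ba <- numeric(0)
      for (start in seq(1L, n, by = batchSize)) {
        sel <- ord[start:min(start + batchSize - 1L, n)]
        A <- do.call(rbind, lapply(items[sel], `[[`, "X"))
        y <- unlist(lapply(items[sel], `[[`, "y"))
        model@params <- params
        model@state <- state
        fw <- segForward(model, A, length(sel), training = TRUE)
        state <- fw$state
        ls <- softmaxCELoss(fw$logits, y)
        bl <- c(bl, ls$loss)
        ba <- c(ba, mean(max.col(ls$probs, ties.method = "last") - 1L == y))
        grads <- segBackward(model, fw$caches, ls$dLogits, length(sel))
        upd <- adamStep(params, grads, opt, lr = learningRate)
        params <- upd$params
        opt <- upd$opt
      }
      losses[ep] <- mean(bl)
      accs[ep] <- mean(ba)
    }
  })
  model@params <- params
  model@state <- state
  model@trained <- TRUE
  history <- new("TrainingHistory", loss = losses, accuracy = accs,
                 epochs = as.integer(epochs), seed = as.integer(seed))
  list(model = model, history = history)
}

#' Predict a binary mask for an image
#'
#' Tiles the image (reflect padding as in [extractPatches()]), forwards
#' every tile in inference mode, averages the per-pixel class
#' probabilities over all covering tiles and takes the per-pixel argmax;
#' a foreground probability of exactly 0.5 goes to class 1 (foreground).
#'
#' @param model a trained [SegModel-class].
#' @param image `height x width x 3` array.
#' @param patchSize tile edge; defaults to the network input size.
#' @param stride tile stride; below `patchSize` yields overlapping tiles
#'   whose probabilities are averaged.
#' @param chunkSize tiles per forward pass.
#' @return binary mask matrix of the image's extent.
#' @export
predictMask <- function(model, image, patchSize = model@spec@inputSize,
                        stride = patchSize, chunkSize = 64L) {
  stopifnot(is(model, "SegModel"))
  if (!model@trained)
    stop("model is untrained; run trainSegmenter() first", call. = FALSE)
  if (patchSize != model@spec@inputSize)
    stop("patchSize must equal the network input size", call. = FALSE)
  grid <- extractPatches(image, patchSize, stride)
  K <- model@spec@nClasses
  ph <- grid@paddedDim[1]
  pw <- grid@paddedDim[2]
  ps <- grid@patchSize
  probSum <- array(0, dim = c(ph, pw, K))
  count <- matrix(0, ph, pw)
  nPatch <- patchCount(grid)
  for (start in seq(1L, nPatch, by = chunkSize)) {
    sel <- start:min(start + chunkSize - 1L, nPatch)
    A <- patchesToMatrix(grid@patches[sel])
    fw <- segForward(model, A, length(sel), training = FALSE)
    probs <- softmaxRows(fw$logits)
    for (j in seq_along(sel)) {
      k <- sel[j]
      rows <- grid@coords[k, 1] + seq_len(ps)
      cols <- grid@coords[k, 2] + seq_len(ps)
      block <- (j - 1L) * ps * ps + seq_len(ps * ps)
      for (cl in seq_len(K)) {
        probSum[rows, cols, cl] <- probSum[rows, cols, cl] +
          matrix(probs[block, cl], ps, ps)
      }
      count[rows, cols] <- count[rows, cols] + 1
    }
  }
  flat <- matrix(probSum, ph * pw, K) / as.vector(count)
  cls <- max.col(flat, ties.method = "last") - 1L
  out <- matrix(as.integer(cls >= 1L), ph, pw)
  out[seq_len(grid@sourceDim[1]), seq_len(grid@sourceDim[2]), drop = FALSE]
}
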