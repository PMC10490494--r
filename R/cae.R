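# Convolutional autoencoder: encoder of `depth` levels, each
# [3x3 conv -> batch norm -> ReLU -> 2x2 max pool] with filters doubling
# from baseFilters, a dense bottleneck of latentDim units, and a mirrored
# decoder (2x2 transposed conv -> 3x3 conv -> BN -> ReLU per level) with
# a sigmoid head so reconstructions lie in [0, 1].

caeFilters <- function(spec) spec@baseFilters * 2L^(seq_len(spec@depth) - 1L)

#' Build a convolutional autoencoder
#'
#' @param spec a [NetworkSpec-class]; `inputSize` must be divisible by
#'   `2^depth`.
#' @param initSeed seed for the weight initialization, so that identical
#'   calls build identical models.
#' @return an untrained [CAEModel-class].
#' @examples
#' m <- buildCAE(networkSpec(depth = 2, baseFilters = 8, latentDim = 16))
#' @export
buildCAE <- function(spec, initSeed = 0L) {
  validObject(spec)
  withSeed(initSeed, {
    f <- caeFilters(spec)
    s <- spec@inputSize %/% 2L^spec@depth
    D <- s * s * f[spec@depth]
    enc <- lapply(seq_len(spec@depth), function(l) {
      cin <- if (l == 1L) 3L else f[l - 1L]
      list(conv = newConv(3L, cin, f[l]), bn = newBN(f[l]))
    })
    dec <- lapply(rev(seq_len(spec@depth)), function(l) {
      fout <- if (l == 1L) spec@baseFilters else f[l - 1L]
      list(up = newUpconv(f[l], fout), conv = newConv(3L, fout, fout),
           bn = newBN(fout))
    })
    params <- list(
      enc = enc,
      toZ = newDense(D, spec@latentDim),
      fromZ = newDense(spec@latentDim, D),
      dec = dec,
      head = newConv(3L, spec@baseFilters, 3L)
    )
    new("CAEModel", spec = spec, params = params, state = list(),
        trained = FALSE)
  })
}

# Full forward pass. Returns reconstruction, latent codes, per-layer
# caches (for backprop) and the updated batch-norm state.
caeForward <- function(params, spec, A, N, state, training) {
  S <- spec@inputSize
  f <- caeFilters(spec)
  caches <- list(enc = vector("list", spec@depth),
                 dec = vector("list", spec@depth))
  sz <- S
  for (l in seq_len(spec@depth)) {
    cv <- convFwd(A, sz, sz, N, params$enc[[l]]$conv)
    bn <- bnFwd(cv$out, params$enc[[l]]$bn, state, paste0("enc", l), training)
    state <- bn$state
    rl <- reluFwd(bn$out)
    pl <- maxpool2_fwd(rl, sz, sz, N)
    caches$enc[[l]] <- list(conv = cv, bn = bn$cache, pre = bn$out,
                            pool = pl$idx, rowsIn = nrow(rl), size = sz)
    A <- pl$out
    sz <- sz %/% 2L
  }
  s2 <- sz * sz
  X <- flattenActs(A, s2, N)
  codes <- denseFwd(X, params$toZ)
  Xd <- denseFwd(codes, params$fromZ)
  Xr <- reluFwd(Xd)
  caches$bottleneck <- list(X = X, codes = codes, Xd = Xd, s2 = s2,
                            cbot = f[spec@depth])
  A <- unflattenActs(Xr, s2, f[spec@depth])
  for (i in seq_len(spec@depth)) {
    l <- spec@depth - i + 1L
    up <- upconvFwd(A, sz, sz, N, params$dec[[i]]$up)
    sz <- sz * 2L
    cv <- convFwd(up$out, sz, sz, N, params$dec[[i]]$conv)
    bn <- bnFwd(cv$out, params$dec[[i]]$bn, state, paste0("dec", l), training)
    state <- bn$state
    A <- reluFwd(bn$out)
    caches$dec[[i]] <- list(up = up, conv = cv, bn = bn$cache, pre = bn$out,
                            cin = ncol(up$A), size = sz)
  }
  hd <- convFwd(A, S, S, N, params$head)
  recon <- sigmoidFwd(hd$out)
  caches$head <- hd
  caches$lastA <- A
  list(recon = recon, codes = codes, caches = caches, state = state)
}

caeBackward <- function(params, spec, caches, dRecon, recon, N) {
  S <- spec@inputSize
  f <- caeFilters(spec)
  grads <- list(enc = vector("list", spec@depth),
                dec = vector("list", spec@depth))
  dLogits <- dRecon * recon * (1 - recon)
  hb <- convBwd(dLogits, caches$head, params$head, S, S, N, spec@baseFilters)
  grads$head <- list(W = hb$dW, b = hb$db)
  dA <- hb$dA
  sz <- S
  for (i in rev(seq_len(spec@depth))) {
    cc <- caches$dec[[i]]
    dPre <- reluBwd(dA, cc$pre)
    bb <- bnBwd(dPre, cc$bn, params$dec[[i]]$bn)
    cb <- convBwd(bb$dA, cc$conv, params$dec[[i]]$conv, cc$size, cc$size, N,
                  length(params$dec[[i]]$up$b))
    ub <- upconvBwd(cb$dA, cc$up, params$dec[[i]]$up,
                    cc$size %/% 2L, cc$size %/% 2L, N)
    grads$dec[[i]] <- list(up = list(W = ub$dW, b = ub$db),
                           conv = list(W = cb$dW, b = cb$db),
                           bn = list(gamma = bb$dgamma, beta = bb$dbeta))
    dA <- ub$dA
    sz <- cc$size %/% 2L
  }
  bt <- caches$bottleneck
  dXr <- flattenActs(dA, bt$s2, N)
  dXd <- reluBwd(dXr, bt$Xd)
  grads$fromZ <- list(W = crossprod(bt$codes, dXd), b = colSums(dXd))
  dCodes <- dXd %*% t(params$fromZ$W)
  grads$toZ <- list(W = crossprod(bt$X, dCodes), b = colSums(dCodes))
  dX <- dCodes %*% t(params$toZ$W)
  dA <- unflattenActs(dX, bt$s2, bt$cbot)
  for (l in rev(seq_len(spec@depth))) {
    cc <- caches$enc[[l]]
    dPooled <- maxpool2_bwd(dA, cc$pool, cc$rowsIn)
    dPre <- reluBwd(dPooled, cc$pre)
    bb <- bnBwd(dPre, cc$bn, params$enc[[l]]$bn)
    cin <- if (l == 1L) 3L else f[l - 1L]
    cb <- convBwd(bb$dA, cc$conv, params$enc[[l]]$conv, cc$size, cc$size, N,
                  cin)
    grads$enc[[l]] <- list(conv = list(W = cb$dW, b = cb$db),
                           bn = list(gamma = bb$dgamma, beta = bb$dbeta))
    dA <- cb$dA
  }
  grads
}

asPatchList <- function(patches, inputSize, channels = 3L) {
  if (is(patches, "PatchGrid")) patches <- patches@patches
  if (!is.list(patches) || length(patches) == 0L)
    stop("at least one patch is required", call. = FALSE)
  for (p in patches) {
    d <- dim(p)
    if (d[1] != inputSize || d[2] != inputSize)
      stop(sprintf("patches must be %d x %d to match the network input",
                   inputSize, inputSize), call. = FALSE)
  }
  patches
}

#' Train a convolutional autoencoder by reconstruction
#'
#' Minimizes the per-pixel mean squared reconstruction error with Adam.
#' The seed fixes the shuffling, so the same model, data and seed
#' reproduce the loss history exactly.
#'
#' @param model an untrained or pre-trained [CAEModel-class].
#' @param patches list of `inputSize x inputSize x 3` arrays (or a
#'   [PatchGrid-class]).
#' @param epochs number of passes over the data (>= 1).
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param seed seed for shuffling.
#' @return list with elements `model` (trained [CAEModel-class]) and
#'   `history` (a [TrainingHistory-class] of per-epoch mean loss).
#' @export
trainCAE <- function(model, patches, epochs = 20L, learningRate = 1e-3,
                     batchSize = 32L, seed = 0L) {
  stopifnot(is(model, "CAEModel"))
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  patches <- asPatchList(patches, model@spec@inputSize)
  pm <- lapply(patches, function(p) matrix(p, prod(dim(p)[1:2]), 3L))
  n <- length(pm)
  params <- model@params
  state <- model@state
  opt <- adamInit(params)
  losses <- numeric(epochs)
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      bl <- numeric(0)
      for (start in seq(1L, n, by = batchSize)) {
        sel <- ord[start:min(start + batchSize - 1L, n)]
        A <- do.call(rbind, pm[sel])
        fw <- caeForward(params, model@spec, A, length(sel), state,
                         training = TRUE)
        state <- fw$state
        ls <- mseLoss(fw$recon, A)
        bl <- c(bl, ls$loss)
        grads <- caeBackward(params, model@spec, fw$caches, ls$grad,
                             fw$recon, length(sel))
        upd <- adamStep(params, grads, opt, lr = learningRate)
        params <- upd$params
        opt <- upd$opt
      }
      losses[ep] <- mean(bl)
    }
  })
  model@params <- params
  model@state <- state
  model@trained <- TRUE
  history <- new("TrainingHistory", loss = losses,
                 accuracy = rep(NA_real_, epochs),
                 epochs = as.integer(epochs), seed = as.integer(seed))
  list(model = model, history = history)
}

#' Encode patches into the latent space
#'
#' Runs the encoder (inference mode: batch norm uses running statistics)
#' and returns one latent vector per patch. Deterministic for fixed
#' weights.
#'
#' @param model a [CAEModel-class].
#' @param patches list of patch arrays or a [PatchGrid-class]; rows of the
#'   result align with the patch order.
#' @param chunkSize number of patches encoded per forward pass.
#' @return `n_patches x latentDim` numeric matrix.
#' @export
encodePatches <- function(model, patches, chunkSize = 512L) {
  stopifnot(is(model, "CAEModel"))
  patches <- asPatchList(patches, model@spec@inputSize)
  pm <- lapply(patches, function(p) matrix(p, prod(dim(p)[1:2]), 3L))
  n <- length(pm)
  out <- matrix(0, n, model@spec@latentDim)
  for (start in seq(1L, n, by = chunkSize)) {
    sel <- start:min(start + chunkSize - 1L, n)
    A <- do.call(rbind, pm[sel])
    fw <- caeForward(model@params, model@spec, A, length(sel), model@state,
                     training = FALSE)
    out[sel, ] <- fw$codes
  }
  out
}
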