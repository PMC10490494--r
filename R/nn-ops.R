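# Network engine primitives. A batch of N maps of size H x W with C
# channels is a (H*W*N) x C matrix, row index h + H*w + H*W*n (0-based);
# convolution is one GEMM against the im2col patch matrix, batch norm and
# activations are column operations. Gradients mirror each forward op.

heInit <- function(nrow, ncol, fanIn) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fanIn)), nrow, ncol)
}

newConv <- function(k, cin, f) {
  list(W = heInit(k * k * cin, f, k * k * cin), b = numeric(f), k = k)
}

newBN <- function(f) list(gamma = rep(1, f), beta = numeric(f))

newUpconv <- function(cin, f) {
  list(W = heInit(cin, 4 * f, cin), b = numeric(f))
}

newDense <- function(din, dout) {
  list(W = heInit(din, dout, din), b = numeric(dout))
}

convFwd <- function(A, H, W, N, layer) {
  cols <- im2col_nchw(A, H, W, N, layer$k)
  out <- cols %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, cols = cols)
}

convBwd <- function(dY, cache, layer, H, W, N, cin) {
  list(dA = col2im_nchw(dY %*% t(layer$W), H, W, N, cin, layer$k),
       dW = crossprod(cache$cols, dY),
       db = colSums(dY))
}

# Spatial batch norm over all rows (pixels x batch). Biased variance;
# running statistics (momentum 0.9) are used at inference.
bnFwd <- function(A, layer, state, key, training, momentum = 0.9, eps = 1e-5) {
  n <- nrow(A)
  if (training) {
    mu <- colMeans(A)
    ctr <- A - rep(mu, each = n)
    v <- colMeans(ctr * ctr)
    if (is.null(state[[key]])) state[[key]] <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]]$mean <- momentum * state[[key]]$mean + (1 - momentum) * mu
    state[[key]]$var <- momentum * state[[key]]$var + (1 - momentum) * v
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(ncol(A)), var = rep(1, ncol(A)))
    mu <- st$mean
    v <- st$var
    ctr <- A - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- ctr * rep(invstd, each = n)
  out <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, n = n),
       state = state)
}

bnBwd <- function(dY, cache, layer, training = TRUE) {
  n <- cache$n
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(layer$gamma, each = n)
  if (!training) {
    dA <- dxhat * rep(cache$invstd, each = n)
    return(list(dA = dA, dgamma = dgamma, dbeta = dbeta))
  }
  sx <- colSums(dxhat)
  sxx <- colSums(dxhat * cache$xhat)
  dA <- (dxhat - rep(sx / n, each = n) -
           cache$xhat * rep(sxx / n, each = n)) * rep(cache$invstd, each = n)
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

reluFwd <- function(A) {
  out <- A
  out[out < 0] <- 0
  out
}

reluBwd <- function(dY, A) dY * (A > 0)

upconvFwd <- function(A, H, W, N, layer) {
  f <- length(layer$b)
  Y4 <- A %*% layer$W
  out <- upconv2_scatter(Y4, H, W, N, f)
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, A = A)
}

upconvBwd <- function(dY, cache, layer, H, W, N) {
  f <- length(layer$b)
  dY4 <- upconv2_gather(dY, H, W, N, f)
  list(dA = dY4 %*% t(layer$W),
       dW = crossprod(cache$A, dY4),
       db = colSums(dY))
}

denseFwd <- function(X, layer) {
  out <- X %*% layer$W
  out + rep(layer$b, each = nrow(out))
}

sigmoidFwd <- function(A) 1 / (1 + exp(-A))

# Row-wise numerically stabilized softmax (subtract the per-row max).
softmaxRows <- function(logits) {
  m <- logits[, 1]
  for (k in seq_len(ncol(logits))[-1]) m <- pmax(m, logits[, k])
  e <- exp(logits - m)
  e / rowSums(e)
}

mseLoss <- function(recon, target) {
  d <- recon - target
  list(loss = mean(d * d), grad = 2 * d / length(d))
}

# Pixel-wise softmax cross-entropy; labels are 0-based class ids per row.
# Returns the combined gradient w.r.t. the logits.
softmaxCELoss <- function(logits, labels) {
  probs <- softmaxRows(logits)
  n <- nrow(probs)
  picked <- probs[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dLogits <- probs
  dLogits[cbind(seq_len(n), labels + 1L)] <-
    dLogits[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, probs = probs, dLogits = dLogits / n)
}

# Reshape between the activation layout and per-sample flat features.
# A: (s2*N) x C  ->  N x (s2*C), feature index hw + s2*(c-1).
flattenActs <- function(A, s2, N) {
  t(matrix(aperm(array(A, dim = c(s2, N, ncol(A))), c(1, 3, 2)),
           s2 * ncol(A), N))
}

unflattenActs <- function(X, s2, C) {
  N <- nrow(X)
  matrix(aperm(array(t(X), dim = c(s2, C, N)), c(1, 3, 2)), s2 * N, C)
}

# ---- Adam over an arbitrarily nested parameter list ----------------------

adamInit <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    p * 0
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

adamStep <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        if (is.null(g[[nm]])) next  # non-trainable entries (e.g. kernel size)
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p
        out$m[[nm]] <- r$m
        out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

# Stack a list of patches (s x s x 3 arrays or s x s matrices) into the
# activation layout.
patchesToMatrix <- function(patches) {
  do.call(rbind, lapply(patches, function(p) {
    if (length(dim(p)) == 3L) matrix(p, prod(dim(p)[1:2]), dim(p)[3])
    else matrix(p, length(p), 1L)
  }))
}
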