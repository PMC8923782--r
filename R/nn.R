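## Minimal CNN engine -------------------------------------------------------
##
## Activations are stored as N x C matrices with N = B*H*W rows in
## batch-major, row-major pixel order: row index = (b-1)*H*W + (r-1)*W + c.
## Convolutions are im2col gathers followed by a BLAS matrix product;
## backward passes are hand-derived and checked against numerical gradients
## in the test suite. A "tensor" is list(x = matrix, H, W, B).

.nnCache <- new.env(parent = emptyenv())

nnTensor <- function(x, H, W, B) list(x = x, H = H, W = W, B = B)

# Gather-index matrix for an im2col convolution. Entries index rows of the
# activation matrix augmented with one trailing zero row (zero padding).
convIndex <- function(B, H, W, k, stride, pad) {
  key <- paste("ci", B, H, W, k, stride, pad, sep = "_")
  hit <- .nnCache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- (H + 2 * pad - k) %/% stride + 1L
  W2 <- (W + 2 * pad - k) %/% stride + 1L
  zrow <- B * H * W + 1L
  r2 <- rep(seq_len(H2), each = W2)       # output pixel rows, row-major
  c2 <- rep(seq_len(W2), times = H2)
  idx <- matrix(0L, H2 * W2, k * k)
  o <- 0L
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    o <- o + 1L
    r <- (r2 - 1L) * stride + dy - pad
    c <- (c2 - 1L) * stride + dx - pad
    valid <- r >= 1L & r <= H & c >= 1L & c <= W
    p <- (r - 1L) * W + c
    p[!valid] <- zrow  # marker; batch offset not applied to the zero row
    idx[, o] <- p
  }
  if (B > 1L) {
    base <- idx
    idx <- matrix(0L, B * H2 * W2, k * k)
    for (b in seq_len(B)) {
      blk <- base
      real <- base != zrow
      blk[real] <- base[real] + (b - 1L) * H * W
      idx[((b - 1L) * H2 * W2 + 1L):(b * H2 * W2), ] <- blk
    }
  }
  ivec <- as.vector(idx)
  # cached sparse scatter for col2im: row p sums all (output pixel, offset)
  # entries that read input pixel p
  scat <- Matrix::sparseMatrix(i = ivec, j = seq_along(ivec), x = 1,
                               dims = c(zrow, length(ivec)))
  out <- list(idx = idx, ivec = ivec, scat = scat,
              H2 = H2, W2 = W2, zrow = zrow)
  .nnCache[[key]] <- out
  out
}

addBias <- function(Y, b) Y + rep(b, each = nrow(Y))

convForward <- function(t, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && stride == 1L) {
    Y <- addBias(t$x %*% W, b)
    return(list(out = nnTensor(Y, t$H, t$W, t$B),
                cache = list(k = 1L, stride = 1L, X = t$x, W = W,
                             H = t$H, Wd = t$W, B = t$B)))
  }
  ci <- convIndex(t$B, t$H, t$W, k, stride, pad)
  Xz <- rbind(t$x, 0)
  C <- ncol(t$x)
  # weight rows are channel-major: row (c-1)*k^2 + o, so im2col is a single
  # gather reinterpreted as (nOut x k^2*C)
  Xcol <- Xz[ci$ivec, , drop = FALSE]
  dim(Xcol) <- c(nrow(ci$idx), k * k * C)
  Y <- addBias(Xcol %*% W, b)
  list(out = nnTensor(Y, ci$H2, ci$W2, t$B),
       cache = list(k = k, stride = stride, pad = pad, Xcol = Xcol, W = W,
                    ci = ci, C = C, N = nrow(t$x), H = t$H, Wd = t$W, B = t$B))
}

convBackward <- function(dY, cache) {
  if (cache$k == 1L && cache$stride == 1L) {
    dW <- crossprod(cache$X, dY)
    db <- colSums(dY)
    dX <- dY %*% t(cache$W)
    return(list(dX = dX, dW = dW, db = db))
  }
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(cache$W)
  C <- cache$C
  k2 <- cache$k^2
  # col2im: the channel-major layout makes the reshape to (nOut*k2 x C) a
  # dim change; rows landing on the same input pixel are then summed
  # (padding rows collapse onto the discarded zero row)
  dim(dXcol) <- c(nrow(cache$Xcol) * k2, C)
  dX <- as.matrix(cache$ci$scat %*% dXcol)
  list(dX = dX[seq_len(cache$N), , drop = FALSE], dW = dW, db = db)
}

bnForward <- function(t, gamma, beta, run, training, momentum = 0.1,
                      eps = 1e-5) {
  X <- t$x
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc * xc)
    newRun <- list(mean = (1 - momentum) * run$mean + momentum * mu,
                   var = (1 - momentum) * run$var + momentum * v)
  } else {
    mu <- run$mean; v <- run$var
    xc <- sweep(X, 2L, mu)
    newRun <- run
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = nnTensor(Y, t$H, t$W, t$B),
       cache = list(xhat = xhat, istd = istd, gamma = gamma,
                    training = training),
       run = newRun)
}

bnBackward <- function(dY, cache) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$training) {
    N <- nrow(dY)
    m1 <- colMeans(dY)
    m2 <- colSums(dY * cache$xhat) / N
    dX <- sweep(dY, 2L, m1) - sweep(cache$xhat, 2L, m2, `*`)
    dX <- sweep(dX, 2L, cache$gamma * cache$istd, `*`)
  } else {
    dX <- sweep(dY, 2L, cache$gamma * cache$istd, `*`)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(t) {
  Y <- t$x
  neg <- Y < 0
  Y[neg] <- 0
  list(out = nnTensor(Y, t$H, t$W, t$B), cache = list(neg = neg))
}

reluBackward <- function(dY, cache) {
  dY[cache$neg] <- 0
  dY
}

# 2x bilinear upsampling as a cached sparse linear map (half-pixel-aligned
# source coordinates, clamped at borders); backward is the transpose.
upsampleMatrix <- function(B, H, W) {
  key <- paste("up", B, H, W, sep = "_")
  hit <- .nnCache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- 2L * H; W2 <- 2L * W
  ro <- rep(seq_len(H2) - 1L, each = W2)
  co <- rep(seq_len(W2) - 1L, times = H2)
  ys <- clamp((ro + 0.5) / 2 - 0.5, 0, H - 1)
  xs <- clamp((co + 0.5) / 2 - 0.5, 0, W - 1)
  r0 <- floor(ys); c0 <- floor(xs)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fy <- ys - r0; fx <- xs - c0
  outPix <- seq_len(H2 * W2)
  i <- rep(outPix, 4L)
  j <- c(r0 * W + c0, r0 * W + c1, r1 * W + c0, r1 * W + c1) + 1
  w <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  S1 <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(H2 * W2, H * W))
  S <- if (B > 1L) Matrix::bdiag(rep(list(S1), B)) else S1
  .nnCache[[key]] <- S
  S
}

upsampleForward <- function(t) {
  S <- upsampleMatrix(t$B, t$H, t$W)
  Y <- as.matrix(S %*% t$x)
  list(out = nnTensor(Y, 2L * t$H, 2L * t$W, t$B),
       cache = list(S = S))
}

upsampleBackward <- function(dY, cache) {
  as.matrix(Matrix::crossprod(cache$S, dY))
}

dropoutForward <- function(t, rate, training) {
  if (!training || rate <= 0)
    return(list(out = t, cache = list(keep = NULL, rate = rate)))
  keep <- matrix(runif(length(t$x)) >= rate, nrow(t$x), ncol(t$x))
  Y <- t$x * keep / (1 - rate)
  list(out = nnTensor(Y, t$H, t$W, t$B), cache = list(keep = keep, rate = rate))
}

dropoutBackward <- function(dY, cache) {
  if (is.null(cache$keep)) return(dY)
  dY * cache$keep / (1 - cache$rate)
}

# Pixelwise softmax cross-entropy. logits: N x numClasses, labels: integer
# vector in 0..numClasses-1. Returns mean loss and d(loss)/d(logits).
softmaxCrossEntropy <- function(logits, labels) {
  mx <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) mx <- pmax(mx, logits[, j])
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  N <- nrow(logits)
  iy <- cbind(seq_len(N), labels + 1L)
  loss <- -mean(log(pmax(p[iy], 1e-300)))
  dlogits <- p
  dlogits[iy] <- dlogits[iy] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

## Adam ---------------------------------------------------------------------

adamInit <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- opt$state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    opt$state[[nm]] <- st
  }
  opt$t <- t
  list(params = params, opt = opt)
}
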