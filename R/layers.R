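# Layer primitives for the residual network. Activations are 4-D arrays
# (H, W, C, N); convolutions call the compiled im2col+GEMM kernels.

convForward <- function(x, W, b, stride = 1L, pad = 0L)
  .conv2dForward(x, W, b, as.integer(stride), as.integer(pad))

convBackward <- function(x, W, dy, stride = 1L, pad = 0L)
  .conv2dBackward(x, W, dy, as.integer(stride), as.integer(pad))

# --- batch normalization (per channel over H, W, N) ---

# per-channel reduction over (H, W, N): colMeans/colSums over the first two
# dims gives a C x N matrix, then reduce over samples
chMean <- function(x) rowMeans(colMeans(x, dims = 2))
chSum <- function(x) rowSums(colSums(x, dims = 2))

# broadcast a per-channel vector over (H, W, C, N) by recycling a
# length H*W*C vector across samples (column-major layout makes this exact)
chVec <- function(stats, d) rep(stats, each = d[1] * d[2])

bnForward <- function(x, gamma, beta, buffers, training,
                      momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (training) {
    mu <- chMean(x)
    v <- chMean(x * x) - mu^2
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var + momentum * v
  } else {
    mu <- buffers$mean
    v <- buffers$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - chVec(mu, d)) * chVec(invstd, d)
  out <- xhat * chVec(gamma, d) + chVec(beta, d)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       buffers = buffers)
}

bnBackward <- function(dy, cache) {
  xhat <- cache$xhat
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  dgamma <- chSum(dy * xhat)
  dbeta <- chSum(dy)
  dxhat <- dy * chVec(cache$gamma, d)
  sum1 <- chSum(dxhat)
  sum2 <- chSum(dxhat * xhat)
  dx <- (dxhat - chVec(sum1 / m, d) - xhat * chVec(sum2 / m, d)) *
    chVec(cache$invstd, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

reluBackward <- function(dy, mask) dy * mask

gapForward <- function(x) colMeans(x, dims = 2)   # C x N descriptor

gapBackward <- function(dpool, hwDim) {
  scale <- 1 / (hwDim[1] * hwDim[2])
  array(rep(as.vector(dpool * scale), each = hwDim[1] * hwDim[2]),
        c(hwDim[1], hwDim[2], dim(dpool)))
}

linearForward <- function(feat, W, b) {
  # feat: C x N; W: nOut x C; returns nOut x N
  W %*% feat + b
}

sigmoid <- function(z) 1 / (1 + exp(-z))
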