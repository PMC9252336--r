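#' Residual network architecture specification
#'
#' The default architecture: a 1x1 convolution stem lifting the single-channel
#' 112 x 112 image to 64 feature maps, three residual layers of two units
#' each (channels 128, 256, 512; the first unit of each layer downsamples by
#' stride 2 through a 1x1 projection shortcut, so the spatial side halves
#' three times: 112 -> 56 -> 28 -> 14), adaptive global average pooling to a
#' 512-value descriptor, and a 2-neuron linear head with elementwise sigmoid.
#' A prediction is positive when the positive neuron's output is `>= 0.5`.
#'
#' @param inputSide input image side (default 112).
#' @param stemChannels stem output channels (default 64).
#' @param layerChannels output channels of the three residual layers
#'   (default `c(128, 256, 512)`); the last entry is the descriptor length.
#' @param unitsPerLayer residual units per layer (default 2).
#' @param kernel spatial kernel of the residual weight layers (default 3).
#' @return a validated spec list.
#' @export
networkSpec <- function(inputSide = 112, stemChannels = 64,
                        layerChannels = c(128, 256, 512),
                        unitsPerLayer = 2, kernel = 3) {
  spec <- list(inputSide = as.integer(inputSide),
               inputChannels = 1L,
               stemChannels = as.integer(stemChannels),
               layerChannels = as.integer(layerChannels),
               unitsPerLayer = as.integer(unitsPerLayer),
               kernel = as.integer(kernel),
               nOutputs = 2L)
  validateNetworkSpec(spec)
  spec
}

validateNetworkSpec <- function(spec) {
  if (length(spec$layerChannels) != 3)
    stop("exactly three residual layers (three downsamplings) are required")
  if (spec$inputSide < 8)
    stop("inputSide too small for three stride-2 downsamplings")
  if (spec$unitsPerLayer < 1 || spec$kernel %% 2 != 1)
    stop("unitsPerLayer must be >= 1 and kernel odd")
  invisible(spec)
}

kaiming <- function(dims, fanIn) array(rnorm(prod(dims), 0, sqrt(2 / fanIn)),
                                       dims)

initConvBN <- function(k, inC, outC) {
  list(W = kaiming(c(k, k, inC, outC), k * k * inC),
       b = numeric(outC),
       gamma = rep(1, outC), beta = numeric(outC))
}

initUnit <- function(inC, outC, stride, k) {
  u <- list(conv1 = initConvBN(k, inC, outC),
            conv2 = initConvBN(k, outC, outC),
            stride = stride)
  if (stride != 1 || inC != outC)
    u$proj <- initConvBN(1, inC, outC)
  u
}

bnBuffers <- function(outC) list(mean = numeric(outC), var = rep(1, outC))

unitBuffers <- function(u) {
  b <- list(bn1 = bnBuffers(length(u$conv1$gamma)),
            bn2 = bnBuffers(length(u$conv2$gamma)))
  if (!is.null(u$proj)) b$bnp <- bnBuffers(length(u$proj$gamma))
  b
}

#' Build a residual network
#'
#' Initializes all parameters deterministically under `seed`: convolution
#' weights use Kaiming fan-in scaling, biases start at zero, batch-norm
#' scale/shift at 1/0 with running statistics at 0/1.
#'
#' @param spec architecture from [networkSpec()].
#' @param seed integer seed controlling initialization.
#' @return a [ResidualNet-class].
#' @examples
#' net <- buildNetwork(networkSpec(inputSide = 28, stemChannels = 4,
#'                                 layerChannels = c(8, 16, 32)), seed = 1)
#' @export
buildNetwork <- function(spec = networkSpec(), seed = 1L) {
  validateNetworkSpec(spec)
  set.seed(seed)
  params <- list(stem = initConvBN(1, spec$inputChannels, spec$stemChannels))
  inC <- spec$stemChannels
  layers <- list()
  for (l in seq_along(spec$layerChannels)) {
    outC <- spec$layerChannels[l]
    units <- list()
    for (u in seq_len(spec$unitsPerLayer)) {
      stride <- if (u == 1) 2L else 1L
      units[[u]] <- initUnit(inC, outC, stride, spec$kernel)
      inC <- outC
    }
    layers[[l]] <- units
  }
  params$layers <- layers
  C <- spec$layerChannels[3]
  params$head <- list(W = matrix(rnorm(2 * C, 0, sqrt(1 / C)), 2, C),
                      b = numeric(2))
  buffers <- list(stem = bnBuffers(spec$stemChannels),
                  layers = lapply(layers, function(units)
                    lapply(units, unitBuffers)))
  new("ResidualNet", spec = spec, params = params, buffers = buffers,
      seed = as.numeric(seed))
}

#' Parameter count of an architecture
#'
#' Closed-form count of trainable parameters (convolution weights + biases,
#' batch-norm scale/shift, linear head) as a pure function of the spec.
#'
#' @param spec architecture from [networkSpec()].
#' @return integer parameter count.
#' @export
parameterCount <- function(spec) {
  validateNetworkSpec(spec)
  convBN <- function(k, inC, outC) k * k * inC * outC + outC + 2 * outC
  total <- convBN(1, spec$inputChannels, spec$stemChannels)
  inC <- spec$stemChannels
  for (outC in spec$layerChannels) {
    for (u in seq_len(spec$unitsPerLayer)) {
      stride <- if (u == 1) 2 else 1
      total <- total + convBN(spec$kernel, inC, outC) +
        convBN(spec$kernel, outC, outC)
      if (stride != 1 || inC != outC)
        total <- total + convBN(1, inC, outC)
      inC <- outC
    }
  }
  total + 2 * spec$layerChannels[3] + 2
}

convBNReluForward <- function(x, p, buffers, stride, pad, training,
                              relu = TRUE) {
  z <- convForward(x, p$W, p$b, stride, pad)
  bn <- bnForward(z, p$gamma, p$beta, buffers, training)
  if (relu) {
    r <- reluForward(bn$out)
    out <- r$out; mask <- r$mask
  } else {
    out <- bn$out; mask <- NULL
  }
  list(out = out, buffers = bn$buffers,
       cache = list(x = x, z = z, bn = bn$cache, mask = mask,
                    stride = stride, pad = pad))
}

convBNReluBackward <- function(dy, p, cache) {
  if (!is.null(cache$mask)) dy <- reluBackward(dy, cache$mask)
  b <- bnBackward(dy, cache$bn)
  cv <- convBackward(cache$x, p$W, b$dx, cache$stride, cache$pad)
  list(dx = cv$dx,
       grads = list(W = cv$dw, b = cv$db, gamma = b$dgamma, beta = b$dbeta))
}

#' Forward pass of one residual unit
#'
#' Computes `shortcut(x) + F(x, {W})` followed by ReLU, where the residual
#' branch F is conv-BN-ReLU-conv-BN and the shortcut is the identity (or a
#' 1x1 strided projection when the shape changes). With the residual branch
#' zeroed and an identity shortcut the unit returns its input unchanged.
#'
#' @param x input activations, array `(H, W, C, N)`.
#' @param unit a unit parameter list (see [buildNetwork()]).
#' @param buffers the unit's batch-norm buffers.
#' @param kernel spatial kernel size.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return list with `out`, updated `buffers`, and a backward `cache`.
#' @export
residualUnitForward <- function(x, unit, buffers = unitBuffers(unit),
                                kernel = dim(unit$conv1$W)[1],
                                training = FALSE) {
  pad <- (kernel - 1L) %/% 2L
  c1 <- convBNReluForward(x, unit$conv1, buffers$bn1, unit$stride, pad,
                          training, relu = TRUE)
  c2 <- convBNReluForward(c1$out, unit$conv2, buffers$bn2, 1L, pad,
                          training, relu = FALSE)
  if (!is.null(unit$proj)) {
    sc <- convBNReluForward(x, unit$proj, buffers$bnp, unit$stride, 0L,
                            training, relu = FALSE)
    shortcut <- sc$out
    buffers$bnp <- sc$buffers
  } else {
    sc <- NULL
    shortcut <- x
  }
  buffers$bn1 <- c1$buffers
  buffers$bn2 <- c2$buffers
  summed <- shortcut + c2$out
  r <- reluForward(summed)
  list(out = r$out, buffers = buffers,
       cache = list(c1 = c1$cache, c2 = c2$cache,
                    sc = if (!is.null(sc)) sc$cache, mask = r$mask))
}

residualUnitBackward <- function(dy, unit, cache) {
  dy <- reluBackward(dy, cache$mask)
  g2 <- convBNReluBackward(dy, unit$conv2, cache$c2)
  g1 <- convBNReluBackward(g2$dx, unit$conv1, cache$c1)
  grads <- list(conv1 = g1$grads, conv2 = g2$grads)
  if (!is.null(unit$proj)) {
    gp <- convBNReluBackward(dy, unit$proj, cache$sc)
    grads$proj <- gp$grads
    dx <- g1$dx + gp$dx
  } else {
    dx <- g1$dx + dy
  }
  list(dx = dx, grads = grads)
}

#' Forward pass of the network
#'
#' Maps a batch of single-channel square images to per-sample sigmoid
#' probability pairs. Column `pos` is the positive-class neuron used by the
#' loss and the decision rule; `neg` is trained with the complementary
#' label.
#'
#' @param net a [ResidualNet-class].
#' @param x image batch: array `(side, side, 1, N)`, a single matrix, or a
#'   `(side, side, N)` array.
#' @param training batch-norm mode; also returns a backward cache.
#' @return an `N x 2` probability matrix (columns `pos`, `neg`); in training
#'   mode a list with `probs`, `cache`, `buffers`.
#' @export
netForward <- function(net, x, training = FALSE) {
  x <- asImageBatch(x, net@spec$inputSide)
  p <- net@params
  buffers <- net@buffers
  caches <- list()

  stem <- convBNReluForward(x, p$stem, buffers$stem, 1L, 0L, training)
  buffers$stem <- stem$buffers
  caches$stem <- stem$cache
  caches$layers <- lapply(p$layers, function(units)
    vector("list", length(units)))
  h <- stem$out

  for (l in seq_along(p$layers)) {
    for (u in seq_along(p$layers[[l]])) {
      r <- residualUnitForward(h, p$layers[[l]][[u]],
                               buffers$layers[[l]][[u]],
                               net@spec$kernel, training)
      h <- r$out
      buffers$layers[[l]][[u]] <- r$buffers
      caches$layers[[l]][[u]] <- r$cache
    }
  }

  pooled <- gapForward(h)                       # C x N
  z <- linearForward(pooled, p$head$W, p$head$b) # 2 x N
  probs <- t(sigmoid(z))
  colnames(probs) <- c("pos", "neg")
  if (!training) return(probs)
  caches$poolDim <- dim(h)
  caches$pooled <- pooled
  caches$probs <- probs
  list(probs = probs, cache = caches, buffers = buffers)
}

# dProbs: N x 2 gradient of the loss wrt the sigmoid outputs
netBackward <- function(net, cache, dProbs) {
  p <- net@params
  probs <- cache$probs
  dz <- t(dProbs * probs * (1 - probs))          # 2 x N
  gradHead <- list(W = dz %*% t(cache$pooled), b = rowSums(dz))
  dpool <- t(p$head$W) %*% dz                    # C x N
  dh <- gapBackward(dpool, cache$poolDim[1:2])

  grads <- list(layers = vector("list", length(p$layers)))
  for (l in rev(seq_along(p$layers))) {
    grads$layers[[l]] <- vector("list", length(p$layers[[l]]))
    for (u in rev(seq_along(p$layers[[l]]))) {
      r <- residualUnitBackward(dh, p$layers[[l]][[u]],
                                cache$layers[[l]][[u]])
      dh <- r$dx
      grads$layers[[l]][[u]] <- r$grads
    }
  }
  gs <- convBNReluBackward(dh, p$stem, cache$stem)
  grads$stem <- gs$grads
  grads$head <- gradHead
  grads
}

asImageBatch <- function(x, side) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  if (length(dim(x)) == 3) {
    d <- dim(x)
    x <- array(x, c(d[1], d[2], 1, d[3]))
  }
  d <- dim(x)
  if (d[1] != side || d[2] != side)
    stop("network expects ", side, "x", side, " images, got ",
         d[1], "x", d[2])
  x
}

#' Threshold decision rule
#'
#' A sample is assigned the positive class (PD, moderate-to-advanced PD or
#' early PD, depending on the task) when its positive-class score is greater
#' than or equal to the threshold (default 0.5).
#'
#' @param probs probability matrix from [netForward()] (column `pos` used),
#'   or a vector of positive-class scores.
#' @param threshold decision threshold (default 0.5).
#' @return integer labels: 1 = positive, 0 = negative.
#' @export
classify <- function(probs, threshold = 0.5) {
  score <- if (is.matrix(probs)) probs[, 1] else probs
  as.integer(score >= threshold)
}

setMethod("show", "ResidualNet", function(object) {
  s <- object@spec
  cat("ResidualNet: ", s$inputSide, "x", s$inputSide, "x", s$inputChannels,
      " -> stem ", s$stemChannels, " -> layers [",
      paste(s$layerChannels, collapse = ", "), "] x", s$unitsPerLayer,
      " units -> GAP ", s$layerChannels[3], " -> 2 sigmoid outputs\n",
      sep = "")
  cat("  parameters:", parameterCount(s), " seed:", object@seed, "\n")
})
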