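#' Training configuration
#'
#' Defaults follow the training protocol: RMSprop (smoothing constant 0.99,
#' epsilon 1e-8, no momentum or weight decay), initial learning rate 1e-3
#' decaying to one-fifth of its value every 10 epochs, batch size 23,
#' improved focal loss, early stopping on the monitored held-out loss with
#' patience 5 and best-weights restoration.
#'
#' @param initialLR initial learning rate.
#' @param decayFactor multiplicative LR decay (default 1/5).
#' @param decayEvery epochs between decays (default 10).
#' @param batchSize mini-batch size (default 23).
#' @param maxEpochs epoch budget (default 100).
#' @param patience early-stopping patience in epochs (default 5).
#' @param monitor `"loss"` or `"accuracy"` on the held-out set.
#' @param loss `"improved_focal"`, `"focal"` or `"cross_entropy"`.
#' @param gamma focal-loss focusing exponent.
#' @param tau improved-focal-loss outlier threshold.
#' @param rho,eps RMSprop smoothing constant and stabilizer.
#' @param eraseProbability random-erasing probability (0 disables; applied
#'   online before each mini-batch, training images only).
#' @param seed seed for shuffling, erasing and any initialization drawn
#'   inside the loop.
#' @return a validated config list.
#' @export
trainConfig <- function(initialLR = 1e-3, decayFactor = 0.2, decayEvery = 10,
                        batchSize = 23, maxEpochs = 100, patience = 5,
                        monitor = c("loss", "accuracy"),
                        loss = c("improved_focal", "focal", "cross_entropy"),
                        gamma = 2, tau = 0.05, rho = 0.99, eps = 1e-8,
                        eraseProbability = 0.5, seed = 1L) {
  cfg <- list(initialLR = initialLR, decayFactor = decayFactor,
              decayEvery = decayEvery, batchSize = batchSize,
              maxEpochs = maxEpochs, patience = patience,
              monitor = match.arg(monitor), loss = match.arg(loss),
              gamma = gamma, tau = tau, rho = rho, eps = eps,
              eraseProbability = eraseProbability, seed = seed)
  stopifnot(cfg$initialLR > 0, cfg$decayFactor > 0, cfg$decayFactor < 1,
            cfg$decayEvery >= 1, cfg$batchSize >= 1, cfg$maxEpochs >= 1,
            cfg$patience >= 1)
  cfg
}

#' Learning rate at a given epoch
#'
#' Step decay: `initialLR * decayFactor^floor((epoch - 1) / decayEvery)`;
#' with the defaults, 1e-3 for epochs 1-10, 2e-4 for 11-20, 4e-5 for 21-30.
#'
#' @param config a [trainConfig()].
#' @param epoch epoch number, `>= 1`.
#' @return the learning rate.
#' @export
lrAtEpoch <- function(config, epoch) {
  if (any(epoch < 1)) stop("epoch must be >= 1")
  config$initialLR * config$decayFactor^floor((epoch - 1) / config$decayEvery)
}

#' Seed every source of randomness
#'
#' All stochastic stages (cohort generation, SMOTE, splitting, shuffling,
#' random erasing, weight initialization) draw from R's global RNG; setting
#' this seed before a run makes the whole pipeline bit-reproducible.
#'
#' @param seed integer seed.
#' @export
setGlobalSeed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

# one RMSprop step over the parameter tree; grads defines which leaves are
# trainable (the params tree also carries non-parameter fields like stride)
rmspropStep <- function(params, grads, state, lr, rho, eps) {
  step <- function(p, g, s) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- step(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    if (is.null(s)) s <- g * 0
    s <- rho * s + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(s) + eps), s = s)
  }
  step(params, grads, state)
}

# early-stopping bookkeeping; `better` compares monitored values
earlyStopUpdate <- function(state, value, epoch, patience,
                            mode = c("min", "max")) {
  mode <- match.arg(mode)
  better <- if (mode == "min") value < state$best else value > state$best
  if (is.null(state$bestEpoch) || better) {
    state$best <- value
    state$bestEpoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$stop <- state$wait >= patience
  state
}

newEarlyStopState <- function(mode = "min")
  list(best = if (mode == "min") Inf else -Inf, bestEpoch = NULL,
       wait = 0L, stop = FALSE, mode = mode)

batchLossAndGrad <- function(probs, y, config) {
  # probs: N x 2 (pos, neg); neuron 2 is trained with the complementary label
  pPrime <- cbind(degreeOfCorrectPrediction(probs[, 1], y),
                  degreeOfCorrectPrediction(probs[, 2], 1 - y))
  lossFun <- switch(config$loss,
    cross_entropy = crossEntropy,
    focal = function(p) focalLoss(p, config$gamma),
    improved_focal = function(p) improvedFocalLoss(p, config$tau))
  # each output neuron is trained against its own target (positive-class
  # label for neuron 1, complement for neuron 2); per-sample loss is the
  # sum over the two neurons, batch loss the mean over samples
  perSample <- rowSums(matrix(lossFun(pPrime), ncol = 2))
  dPPrime <- matrix(lossGradient(pPrime, config$loss, config$gamma,
                                 config$tau), ncol = 2)
  # dp'/dp = +1 for the true-label-1 branch, -1 otherwise
  sgn <- cbind(ifelse(y == 1, 1, -1), ifelse(y == 0, 1, -1))
  dProbs <- dPPrime * sgn / length(y)
  list(loss = perSample, dProbs = dProbs)
}

evaluateOn <- function(net, x, y, config) {
  probs <- netForward(net, x, training = FALSE)
  pPrime <- cbind(degreeOfCorrectPrediction(probs[, 1], y),
                  degreeOfCorrectPrediction(probs[, 2], 1 - y))
  lossFun <- switch(config$loss,
    cross_entropy = crossEntropy,
    focal = function(p) focalLoss(p, config$gamma),
    improved_focal = function(p) improvedFocalLoss(p, config$tau))
  list(loss = epochLoss(rowSums(matrix(lossFun(pPrime), ncol = 2))),
       accuracy = mean(classify(probs) == y),
       probs = probs)
}

#' Train a residual network
#'
#' One epoch = shuffle, batch (size 23 by default), per-batch online
#' random erasing, forward, mean loss over the batch, RMSprop update at the
#' scheduled learning rate. The held-out set is evaluated once per epoch
#' (running batch-norm statistics, no augmentation) and drives early
#' stopping: training stops when the monitored quantity has not improved
#' for `patience` epochs (or at `maxEpochs`), and the best-epoch weights
#' are restored.
#'
#' @param net a [ResidualNet-class] from [buildNetwork()].
#' @param x training images: array `(side, side, 1, N)` or `(side, side, N)`.
#' @param y training labels, 0/1 (1 = positive class).
#' @param xVal,yVal held-out images/labels used for monitoring; when
#'   omitted, the training loss is monitored instead.
#' @param config a [trainConfig()].
#' @return list with the trained `net` (best weights) and `history`, a
#'   data.frame with per-epoch learning rate, train/held-out loss and
#'   accuracy, and the attribute `stoppedEpoch`.
#' @export
trainNetwork <- function(net, x, y, xVal = NULL, yVal = NULL,
                         config = trainConfig()) {
  x <- asImageBatch(x, net@spec$inputSide)
  n <- dim(x)[4]
  if (n == 0 || length(y) != n)
    stop("training set is empty or labels do not match images")
  if (!is.null(xVal)) {
    xVal <- asImageBatch(xVal, net@spec$inputSide)
    if (dim(xVal)[4] == 0) stop("held-out set is empty")
  }
  set.seed(config$seed)
  state <- NULL
  esMode <- if (config$monitor == "loss") "min" else "max"
  es <- newEarlyStopState(esMode)
  bestParams <- net@params
  bestBuffers <- net@buffers
  hist <- data.frame()

  for (epoch in seq_len(config$maxEpochs)) {
    lr <- lrAtEpoch(config, epoch)
    batches <- makeBatches(seq_len(n), config$batchSize, shuffle = TRUE)
    epochLosses <- numeric(0)
    correct <- 0
    for (idx in batches) {
      xb <- x[, , , idx, drop = FALSE]
      if (config$eraseProbability > 0)
        for (i in seq_along(idx))
          xb[, , 1, i] <- randomErase(xb[, , 1, i],
                                      probability = config$eraseProbability)
      fw <- netForward(net, xb, training = TRUE)
      net@buffers <- fw$buffers
      lg <- batchLossAndGrad(fw$probs, y[idx], config)
      epochLosses <- c(epochLosses, lg$loss)
      correct <- correct + sum(classify(fw$probs) == y[idx])
      if (!all(is.finite(lg$loss)))
        stop("non-finite training loss at epoch ", epoch,
             "; check inputs and learning rate")
      grads <- netBackward(net, fw$cache, lg$dProbs)
      upd <- rmspropStep(net@params, grads, state, lr, config$rho,
                         config$eps)
      net@params <- upd$p
      state <- upd$s
    }
    trainLoss <- epochLoss(epochLosses)
    trainAcc <- correct / n
    if (!is.null(xVal)) {
      ev <- evaluateOn(net, xVal, yVal, config)
      valLoss <- ev$loss; valAcc <- ev$accuracy
    } else {
      valLoss <- trainLoss; valAcc <- trainAcc
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = trainLoss,
                                   train_accuracy = trainAcc,
                                   val_loss = valLoss,
                                   val_accuracy = valAcc))
    monitored <- if (config$monitor == "loss") valLoss else valAcc
    es <- earlyStopUpdate(es, monitored, epoch, config$patience, esMode)
    if (es$bestEpoch == epoch) {
      bestParams <- net@params
      bestBuffers <- net@buffers
    }
    if (es$stop) break
  }
  net@params <- bestParams
  net@buffers <- bestBuffers
  attr(hist, "stoppedEpoch") <- nrow(hist)
  attr(hist, "bestEpoch") <- es$bestEpoch
  list(net = net, history = hist)
}
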