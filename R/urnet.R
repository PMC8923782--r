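## UrNet: U-shaped encoder-decoder with a residual encoding path ------------

#' UrNet segmentation model
#'
#' Holds the architecture configuration, the flat parameter list, the
#' batch-norm running statistics, the emitted architecture table and a
#' trained flag. Build with \code{\link{buildUrNet}}; inspect the layer
#' layout with \code{\link{architectureTable}}.
#'
#' @slot config the \linkS4class{UrNetConfig}.
#' @slot params named list of weight arrays.
#' @slot state named list of batch-norm running means/variances.
#' @slot arch layer-by-layer architecture table (data.frame).
#' @slot trained logical.
#' @export
setClass("UrNetModel",
         representation(config = "UrNetConfig", params = "list",
                        state = "list", arch = "data.frame",
                        trained = "logical"))

setMethod("show", "UrNetModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("UrNetModel: input %dx%dx%d -> %d classes, %d tensors, %d parameters%s\n",
              object@config@inputSide, object@config@inputSide,
              object@config@inChannels, object@config@numClasses,
              length(object@params), np,
              if (object@trained) " (trained)" else " (untrained)"))
})

urnetChannels <- function(cfg) {
  ch <- pmax(2L, as.integer(round(cfg@encoderChannels * cfg@widthMultiplier)))
  list(enc = ch, d4 = max(2L, ch[1] %/% 2L))
}

initConvParams <- function(params, pfx, k, cin, cout) {
  params[[paste0(pfx, ".W")]] <-
    matrix(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
           k * k * cin, cout)
  params[[paste0(pfx, ".b")]] <- numeric(cout)
  params
}

initBnParams <- function(params, state, pfx, c) {
  params[[paste0(pfx, ".gamma")]] <- rep(1, c)
  params[[paste0(pfx, ".beta")]] <- numeric(c)
  state[[pfx]] <- list(mean = numeric(c), var = rep(1, c))
  list(params = params, state = state)
}

# (stage, block) -> stride and whether a projection shortcut is needed
blockPlan <- function(cfg) {
  ch <- urnetChannels(cfg)$enc
  plan <- list()
  cin <- ch[1]  # stem output
  for (s in 1:4) {
    for (b in seq_len(cfg@blocksPerStage)) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      cout <- ch[s]
      plan[[paste0("enc", s, ".b", b)]] <-
        list(cin = cin, cout = cout, stride = stride,
             proj = (stride != 1L || cin != cout))
      cin <- cout
    }
  }
  plan
}

#' Build an untrained UrNet model
#'
#' The encoder is a ResNet18-style stack (7x7 stride-2 stem, then four
#' stages of basic residual units; the first unit of stages 2-4 downsamples
#' with stride 2 and a 1x1 projection shortcut), giving skip features at
#' 1/2, 1/4, 1/8 resolution and a 1/16 bottleneck where dropout is applied.
#' The decoder mirrors with 2x bilinear upsampling, concatenation of the
#' same-resolution encoder features and two 3x3 conv+BN+ReLU per level; a
#' final 1x1 convolution emits the two per-pixel class scores at full
#' resolution. Weights are He-initialized from R's global RNG (seed with
#' \code{set.seed} for reproducibility); no pretrained weights are used.
#'
#' @param cfg an \linkS4class{UrNetConfig}.
#' @return An untrained \linkS4class{UrNetModel}.
#' @examples
#' set.seed(1)
#' m <- buildUrNet(urNetConfig(inputSide = 64, widthMultiplier = 1/8))
#' head(architectureTable(m))
#' @export
buildUrNet <- function(cfg = urNetConfig()) {
  validObject(cfg)
  ch <- urnetChannels(cfg)
  params <- list(); state <- list()
  addBn <- function(pfx, c) {
    r <- initBnParams(params, state, pfx, c)
    params <<- r$params; state <<- r$state
  }
  params <- initConvParams(params, "stem.conv", 7L, cfg@inChannels, ch$enc[1])
  addBn("stem.bn", ch$enc[1])
  plan <- blockPlan(cfg)
  for (nm in names(plan)) {
    p <- plan[[nm]]
    params <- initConvParams(params, paste0(nm, ".conv1"), 3L, p$cin, p$cout)
    addBn(paste0(nm, ".bn1"), p$cout)
    params <- initConvParams(params, paste0(nm, ".conv2"), 3L, p$cout, p$cout)
    addBn(paste0(nm, ".bn2"), p$cout)
    if (p$proj) {
      params <- initConvParams(params, paste0(nm, ".proj.conv"), 1L, p$cin, p$cout)
      addBn(paste0(nm, ".proj.bn"), p$cout)
    }
  }
  decIn <- c(ch$enc[4] + ch$enc[3], ch$enc[3] + ch$enc[2],
             ch$enc[2] + ch$enc[1], ch$enc[1])
  decOut <- c(ch$enc[3], ch$enc[2], ch$enc[1], ch$d4)
  for (l in 1:4) {
    params <- initConvParams(params, paste0("dec", l, ".conv1"), 3L,
                             decIn[l], decOut[l])
    addBn(paste0("dec", l, ".bn1"), decOut[l])
    params <- initConvParams(params, paste0("dec", l, ".conv2"), 3L,
                             decOut[l], decOut[l])
    addBn(paste0("dec", l, ".bn2"), decOut[l])
  }
  params <- initConvParams(params, "head.conv", 1L, ch$d4, cfg@numClasses)
  model <- new("UrNetModel", config = cfg, params = params, state = state,
               arch = data.frame(), trained = FALSE)
  model@arch <- buildArchTable(cfg)
  model
}

# Layer-by-layer table: every convolution and batch norm with its kernel,
# stride, channels, output side and trainable parameter count.
buildArchTable <- function(cfg) {
  ch <- urnetChannels(cfg)
  rows <- list()
  side <- cfg@inputSide
  addRow <- function(name, type, k, stride, cin, cout, outSide, nPar) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, type = type, kernel = k, stride = stride,
      in_ch = cin, out_ch = cout, out_side = outSide, n_params = nPar)
  }
  convN <- function(k, cin, cout) k * k * cin * cout + cout
  side <- side %/% 2L
  addRow("stem.conv", "conv", 7L, 2L, cfg@inChannels, ch$enc[1], side,
         convN(7L, cfg@inChannels, ch$enc[1]))
  addRow("stem.bn", "batchnorm", NA, NA, ch$enc[1], ch$enc[1], side,
         2L * ch$enc[1])
  plan <- blockPlan(cfg)
  for (nm in names(plan)) {
    p <- plan[[nm]]
    if (p$stride == 2L) side <- side %/% 2L
    addRow(paste0(nm, ".conv1"), "conv", 3L, p$stride, p$cin, p$cout, side,
           convN(3L, p$cin, p$cout))
    addRow(paste0(nm, ".bn1"), "batchnorm", NA, NA, p$cout, p$cout, side,
           2L * p$cout)
    addRow(paste0(nm, ".conv2"), "conv", 3L, 1L, p$cout, p$cout, side,
           convN(3L, p$cout, p$cout))
    addRow(paste0(nm, ".bn2"), "batchnorm", NA, NA, p$cout, p$cout, side,
           2L * p$cout)
    if (p$proj) {
      addRow(paste0(nm, ".proj.conv"), "conv", 1L, p$stride, p$cin, p$cout,
             side, convN(1L, p$cin, p$cout))
      addRow(paste0(nm, ".proj.bn"), "batchnorm", NA, NA, p$cout, p$cout,
             side, 2L * p$cout)
    }
  }
  addRow("bottleneck.dropout", "dropout", NA, NA, ch$enc[4], ch$enc[4], side, 0L)
  decIn <- c(ch$enc[4] + ch$enc[3], ch$enc[3] + ch$enc[2],
             ch$enc[2] + ch$enc[1], ch$enc[1])
  decOut <- c(ch$enc[3], ch$enc[2], ch$enc[1], ch$d4)
  skips <- c("enc3", "enc2", "enc1", NA)
  for (l in 1:4) {
    side <- side * 2L
    addRow(paste0("dec", l, ".up"), "upsample2x", NA, NA,
           if (l == 1L) ch$enc[4] else decOut[l - 1L],
           if (l == 1L) ch$enc[4] else decOut[l - 1L], side, 0L)
    if (!is.na(skips[l]))
      addRow(paste0("dec", l, ".concat"), paste0("concat+", skips[l]), NA, NA,
             decIn[l], decIn[l], side, 0L)
    addRow(paste0("dec", l, ".conv1"), "conv", 3L, 1L, decIn[l], decOut[l],
           side, convN(3L, decIn[l], decOut[l]))
    addRow(paste0("dec", l, ".bn1"), "batchnorm", NA, NA, decOut[l], decOut[l],
           side, 2L * decOut[l])
    addRow(paste0("dec", l, ".conv2"), "conv", 3L, 1L, decOut[l], decOut[l],
           side, convN(3L, decOut[l], decOut[l]))
    addRow(paste0("dec", l, ".bn2"), "batchnorm", NA, NA, decOut[l], decOut[l],
           side, 2L * decOut[l])
  }
  addRow("head.conv", "conv", 1L, 1L, ch$d4, cfg@numClasses, side,
         convN(1L, ch$d4, cfg@numClasses))
  do.call(rbind, rows)
}

#' @describeIn buildUrNet the emitted architecture table
#' @param model a \linkS4class{UrNetModel}
#' @export
architectureTable <- function(model) model@arch

## Forward / backward -------------------------------------------------------

cbrForward <- function(t, cpfx, bpfx, params, state, k, stride, training) {
  cv <- convForward(t, params[[paste0(cpfx, ".W")]],
                    params[[paste0(cpfx, ".b")]], k, stride)
  bn <- bnForward(cv$out, params[[paste0(bpfx, ".gamma")]],
                  params[[paste0(bpfx, ".beta")]], state[[bpfx]], training)
  state[[bpfx]] <- bn$run
  rl <- reluForward(bn$out)
  list(out = rl$out, state = state,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

cbrBackward <- function(dY, cpfx, bpfx, cache, grads) {
  dY <- reluBackward(dY, cache$relu)
  bb <- bnBackward(dY, cache$bn)
  grads[[paste0(bpfx, ".gamma")]] <- bb$dgamma
  grads[[paste0(bpfx, ".beta")]] <- bb$dbeta
  cb <- convBackward(bb$dX, cache$conv)
  grads[[paste0(cpfx, ".W")]] <- cb$dW
  grads[[paste0(cpfx, ".b")]] <- cb$db
  list(dX = cb$dX, grads = grads)
}

blockForward <- function(t, pfx, params, state, plan, training) {
  c1 <- convForward(t, params[[paste0(pfx, ".conv1.W")]],
                    params[[paste0(pfx, ".conv1.b")]], 3L, plan$stride)
  b1 <- bnForward(c1$out, params[[paste0(pfx, ".bn1.gamma")]],
                  params[[paste0(pfx, ".bn1.beta")]],
                  state[[paste0(pfx, ".bn1")]], training)
  state[[paste0(pfx, ".bn1")]] <- b1$run
  r1 <- reluForward(b1$out)
  c2 <- convForward(r1$out, params[[paste0(pfx, ".conv2.W")]],
                    params[[paste0(pfx, ".conv2.b")]], 3L, 1L)
  b2 <- bnForward(c2$out, params[[paste0(pfx, ".bn2.gamma")]],
                  params[[paste0(pfx, ".bn2.beta")]],
                  state[[paste0(pfx, ".bn2")]], training)
  state[[paste0(pfx, ".bn2")]] <- b2$run
  if (plan$proj) {
    pc <- convForward(t, params[[paste0(pfx, ".proj.conv.W")]],
                      params[[paste0(pfx, ".proj.conv.b")]], 1L, plan$stride)
    pb <- bnForward(pc$out, params[[paste0(pfx, ".proj.bn.gamma")]],
                    params[[paste0(pfx, ".proj.bn.beta")]],
                    state[[paste0(pfx, ".proj.bn")]], training)
    state[[paste0(pfx, ".proj.bn")]] <- pb$run
    short <- pb$out
    projCache <- list(conv = pc$cache, bn = pb$cache)
  } else {
    short <- t
    projCache <- NULL
  }
  s <- nnTensor(b2$out$x + short$x, b2$out$H, b2$out$W, b2$out$B)
  rOut <- reluForward(s)
  list(out = rOut$out, state = state,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, proj = projCache,
                    rout = rOut$cache))
}

blockBackward <- function(dY, pfx, cache, grads) {
  dSum <- reluBackward(dY, cache$rout)
  # main branch
  bb2 <- bnBackward(dSum, cache$b2)
  grads[[paste0(pfx, ".bn2.gamma")]] <- bb2$dgamma
  grads[[paste0(pfx, ".bn2.beta")]] <- bb2$dbeta
  cb2 <- convBackward(bb2$dX, cache$c2)
  grads[[paste0(pfx, ".conv2.W")]] <- cb2$dW
  grads[[paste0(pfx, ".conv2.b")]] <- cb2$db
  dR1 <- reluBackward(cb2$dX, cache$r1)
  bb1 <- bnBackward(dR1, cache$b1)
  grads[[paste0(pfx, ".bn1.gamma")]] <- bb1$dgamma
  grads[[paste0(pfx, ".bn1.beta")]] <- bb1$dbeta
  cb1 <- convBackward(bb1$dX, cache$c1)
  grads[[paste0(pfx, ".conv1.W")]] <- cb1$dW
  grads[[paste0(pfx, ".conv1.b")]] <- cb1$db
  dX <- cb1$dX
  # shortcut branch
  if (!is.null(cache$proj)) {
    pbb <- bnBackward(dSum, cache$proj$bn)
    grads[[paste0(pfx, ".proj.bn.gamma")]] <- pbb$dgamma
    grads[[paste0(pfx, ".proj.bn.beta")]] <- pbb$dbeta
    pcb <- convBackward(pbb$dX, cache$proj$conv)
    grads[[paste0(pfx, ".proj.conv.W")]] <- pcb$dW
    grads[[paste0(pfx, ".proj.conv.b")]] <- pcb$db
    dX <- dX + pcb$dX
  } else {
    dX <- dX + dSum
  }
  list(dX = dX, grads = grads)
}

urnetForward <- function(cfg, params, state, X, training) {
  plan <- blockPlan(cfg)
  caches <- list()
  t <- X
  st <- cbrForward(t, "stem.conv", "stem.bn", params, state, 7L, 2L, training)
  state <- st$state; caches$stem <- st$cache
  t <- st$out
  skips <- list()
  for (s in 1:4) {
    for (b in seq_len(cfg@blocksPerStage)) {
      pfx <- paste0("enc", s, ".b", b)
      bf <- blockForward(t, pfx, params, state, plan[[pfx]], training)
      state <- bf$state; caches[[pfx]] <- bf$cache
      t <- bf$out
    }
    skips[[s]] <- t
  }
  dp <- dropoutForward(t, cfg@dropoutRate, training)
  caches$dropout <- dp$cache
  t <- dp$out
  skipIdx <- c(3L, 2L, 1L, NA)
  for (l in 1:4) {
    up <- upsampleForward(t)
    caches[[paste0("dec", l, ".up")]] <- up$cache
    t <- up$out
    if (!is.na(skipIdx[l])) {
      sk <- skips[[skipIdx[l]]]
      caches[[paste0("dec", l, ".ccols")]] <- c(ncol(t$x), ncol(sk$x))
      t <- nnTensor(cbind(t$x, sk$x), t$H, t$W, t$B)
    }
    for (cv in 1:2) {
      r <- cbrForward(t, paste0("dec", l, ".conv", cv),
                      paste0("dec", l, ".bn", cv), params, state, 3L, 1L,
                      training)
      state <- r$state; caches[[paste0("dec", l, ".cbr", cv)]] <- r$cache
      t <- r$out
    }
  }
  hd <- convForward(t, params[["head.conv.W"]], params[["head.conv.b"]], 1L, 1L)
  caches$head <- hd$cache
  list(logits = hd$out, caches = caches, state = state)
}

urnetBackward <- function(cfg, params, caches, dLogits) {
  grads <- list()
  hb <- convBackward(dLogits, caches$head)
  grads[["head.conv.W"]] <- hb$dW
  grads[["head.conv.b"]] <- hb$db
  dY <- hb$dX
  skipIdx <- c(3L, 2L, 1L, NA)
  dSkip <- vector("list", 4L)
  for (l in 4:1) {
    for (cv in 2:1) {
      r <- cbrBackward(dY, paste0("dec", l, ".conv", cv),
                       paste0("dec", l, ".bn", cv),
                       caches[[paste0("dec", l, ".cbr", cv)]], grads)
      grads <- r$grads; dY <- r$dX
    }
    if (!is.na(skipIdx[l])) {
      cc <- caches[[paste0("dec", l, ".ccols")]]
      dSkip[[skipIdx[l]]] <- dY[, (cc[1] + 1L):(cc[1] + cc[2]), drop = FALSE]
      dY <- dY[, seq_len(cc[1]), drop = FALSE]
    }
    dY <- upsampleBackward(dY, caches[[paste0("dec", l, ".up")]])
  }
  dY <- dropoutBackward(dY, caches$dropout)
  for (s in 4:1) {
    if (s < 4L) dY <- dY + dSkip[[s]]
    for (b in rev(seq_len(cfg@blocksPerStage))) {
      pfx <- paste0("enc", s, ".b", b)
      r <- blockBackward(dY, pfx, caches[[pfx]], grads)
      grads <- r$grads; dY <- r$dX
    }
  }
  r <- cbrBackward(dY, "stem.conv", "stem.bn", caches$stem, grads)
  r$grads
}

## Data plumbing ------------------------------------------------------------

# Stack normalized RgbImages into the engine's N x 3 activation layout.
imagesToTensor <- function(imgs) {
  stopifnot(length(imgs) >= 1L)
  mats <- lapply(imgs, function(im) {
    stopifnot(is(im, "RgbImage"))
    if (valueRange(im) != "normalized")
      stop("images must be normalized before entering the network",
           call. = FALSE)
    px <- imgData(im)
    cbind(as.vector(t(px[, , 1])), as.vector(t(px[, , 2])),
          as.vector(t(px[, , 3])))
  })
  h <- imgHeight(imgs[[1]]); w <- imgWidth(imgs[[1]])
  nnTensor(do.call(rbind, mats), h, w, length(imgs))
}

masksToLabels <- function(masks) {
  unlist(lapply(masks, function(m) as.integer(t(m))), use.names = FALSE)
}

## Learning-rate schedule and early stopping --------------------------------

#' Inverse-time learning-rate decay
#'
#' \code{lr = lr0 / (1 + decay * iteration)}, the iteration counter being
#' optimizer steps starting at 0. Strictly decreasing for positive decay and
#' bounded in \code{(0, lr0]}.
#'
#' @param lr0 initial learning rate.
#' @param decay decay coefficient (0 gives a constant schedule).
#' @param iteration step counter, >= 0 (vectorized).
#' @return Learning-rate value(s).
#' @examples
#' lrSchedule(1e-3, 1e-4, c(0, 10000))  # 1e-3, 5e-4
#' @export
lrSchedule <- function(lr0, decay, iteration) {
  if (any(iteration < 0)) stop("iteration must be >= 0", call. = FALSE)
  if (lr0 <= 0) stop("lr0 must be > 0", call. = FALSE)
  if (decay < 0) stop("decay must be >= 0", call. = FALSE)
  lr0 / (1 + decay * iteration)
}

#' Early-stopping decision over a loss stream
#'
#' "Improvement" means strictly lower than the best loss seen so far.
#' Training stops at the first epoch whose end marks \code{patience}
#' consecutive epochs without improvement, or at the end of the stream.
#'
#' @param losses numeric vector of per-epoch monitored losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with \code{stopEpoch}, \code{bestEpoch} and
#'   \code{stopReason} ("early_stop" or "max_epochs").
#' @examples
#' stopEpochFromLosses(c(1, 0.9, rep(0.9, 10)), patience = 10)
#' @export
stopEpochFromLosses <- function(losses, patience = 10L) {
  stopifnot(length(losses) >= 1L, patience >= 1L)
  best <- Inf; bestEpoch <- 0L; since <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]; bestEpoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience)
        return(list(stopEpoch = e, bestEpoch = bestEpoch,
                    stopReason = "early_stop"))
    }
  }
  list(stopEpoch = length(losses), bestEpoch = bestEpoch,
       stopReason = "max_epochs")
}

## Training -----------------------------------------------------------------

#' Train a UrNet model
#'
#' Minibatch Adam on pixelwise softmax cross-entropy. The learning rate of
#' every optimizer step follows \code{\link{lrSchedule}}. After each epoch
#' the monitored loss (training loss by default, validation loss when
#' \code{tcfg@monitor == "val"} and a validation set is given) is fed to the
#' early-stopping rule; when training stops, the weights and batch-norm
#' statistics of the best monitored epoch are restored.
#'
#' @param model an untrained (or warm-started) \linkS4class{UrNetModel}.
#' @param trainPairs nonempty list of \code{list(img = , mask = )} pairs with
#'   normalized images at the model's input side.
#' @param valPairs optional validation pairs, same format.
#' @param tcfg a \linkS4class{TrainConfig}.
#' @param verbose print a line per epoch.
#' @return list with \code{model} (trained) and \code{history}
#'   (\linkS4class{TrainHistory}).
#' @export
trainUrNet <- function(model, trainPairs, valPairs = NULL,
                       tcfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "UrNetModel"), is(tcfg, "TrainConfig"))
  if (length(trainPairs) == 0L)
    stop("training set must be nonempty", call. = FALSE)
  if (tcfg@monitor == "val" && is.null(valPairs))
    stop("monitor = 'val' requires valPairs", call. = FALSE)
  set.seed(tcfg@seed)
  cfg <- model@config
  params <- model@params; state <- model@state
  opt <- list(state = adamInit(params), t = 0L)
  n <- length(trainPairs)
  step <- 0L
  monLosses <- numeric(0)
  best <- Inf; bestEpoch <- 0L; since <- 0L
  bestParams <- params; bestState <- state
  hist <- list()
  stopReason <- "max_epochs"; stopEpoch <- tcfg@maxEpochs
  for (epoch in seq_len(tcfg@maxEpochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg@batchSize))
    epochLoss <- 0; nPix <- 0
    lrLast <- NA_real_
    for (bi in batches) {
      X <- imagesToTensor(lapply(trainPairs[bi], `[[`, "img"))
      y <- masksToLabels(lapply(trainPairs[bi], `[[`, "mask"))
      fw <- urnetForward(cfg, params, state, X, training = TRUE)
      state <- fw$state
      ce <- softmaxCrossEntropy(fw$logits$x, y)
      if (!is.finite(ce$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      grads <- urnetBackward(cfg, params, fw$caches, ce$dlogits)
      lrLast <- lrSchedule(tcfg@lr0, tcfg@decay, step)
      upd <- adamStep(params, grads, opt, lrLast)
      params <- upd$params; opt <- upd$opt
      step <- step + 1L
      epochLoss <- epochLoss + ce$loss * length(y)
      nPix <- nPix + length(y)
    }
    trainLoss <- epochLoss / nPix
    row <- data.frame(epoch = epoch, loss = trainLoss, lr = lrLast)
    if (!is.null(valPairs)) {
      ev <- evalLossAndMetrics(cfg, params, state, valPairs)
      row$valLoss <- ev$loss; row$valPA <- ev$PA; row$valMIoU <- ev$MIoU
    }
    hist[[epoch]] <- row
    monitored <- if (tcfg@monitor == "val") row$valLoss else trainLoss
    monLosses <- c(monLosses, monitored)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  lr %.3g", epoch, trainLoss,
                      lrLast))
    if (monitored < best) {
      best <- monitored; bestEpoch <- epoch; since <- 0L
      bestParams <- params; bestState <- state
    } else {
      since <- since + 1L
      if (since >= tcfg@patience) {
        stopReason <- "early_stop"; stopEpoch <- epoch
        break
      }
    }
    stopEpoch <- epoch
  }
  model@params <- bestParams
  model@state <- bestState
  model@trained <- TRUE
  history <- new("TrainHistory", history = do.call(rbind, hist),
                 stopEpoch = as.integer(stopEpoch), stopReason = stopReason,
                 bestEpoch = as.integer(bestEpoch))
  list(model = model, history = history)
}

evalLossAndMetrics <- function(cfg, params, state, pairs) {
  X <- imagesToTensor(lapply(pairs, `[[`, "img"))
  y <- masksToLabels(lapply(pairs, `[[`, "mask"))
  fw <- urnetForward(cfg, params, state, X, training = FALSE)
  ce <- softmaxCrossEntropy(fw$logits$x, y)
  pred <- as.integer(fw$logits$x[, 2] > fw$logits$x[, 1])
  cc <- confusionCountsFromTallies(sum(pred == 1L & y == 1L),
                                   sum(pred == 1L & y == 0L),
                                   sum(pred == 0L & y == 1L),
                                   sum(pred == 0L & y == 0L))
  mr <- segMetrics(cc)
  list(loss = ce$loss, PA = mr@PA, MIoU = mr@MIoU)
}

#' Predict a coarse tongue mask
#'
#' Runs the network in evaluation mode (batch-norm running statistics, no
#' dropout) and takes the per-pixel argmax of the two class scores; exact
#' ties go to background.
#'
#' @param model a \linkS4class{UrNetModel}.
#' @param img a normalized \linkS4class{RgbImage} at the model's input side.
#' @return Integer \{0, 1\} mask matrix.
#' @export
predictMask <- function(model, img) {
  stopifnot(is(model, "UrNetModel"), is(img, "RgbImage"))
  side <- model@config@inputSide
  if (imgHeight(img) != side || imgWidth(img) != side)
    stop("image must be ", side, "x", side,
         " (resizeToCanonical first)", call. = FALSE)
  if (valueRange(img) != "normalized")
    stop("image must be normalized (normalizeImage first)", call. = FALSE)
  X <- imagesToTensor(list(img))
  fw <- urnetForward(model@config, model@params, model@state, X,
                     training = FALSE)
  scores <- fw$logits$x
  pred <- as.integer(scores[, 2] > scores[, 1])  # tie -> background
  mask <- matrix(pred, side, side, byrow = TRUE)
  storage.mode(mask) <- "integer"
  mask
}
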