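## Configuration classes ----------------------------------------------------

#' Data augmentation configuration
#'
#' Mirrors the standard augmentation dial set for small segmentation
#' datasets: bounded random rotation, bounded horizontal/vertical shifts
#' expressed as fractions of the image side, an additive per-channel
#' intensity shift, and independent horizontal/vertical flips. Defaults are
#' the training protocol of the tongue-segmentation study this package
#' implements (rotation 10 degrees, shifts 0.2, channel shift 0.2, both
#' flips on).
#'
#' @slot rotationRange max absolute rotation in degrees.
#' @slot widthShiftRange,heightShiftRange max absolute shift as a fraction of
#'   the image side.
#' @slot channelShiftRange max additive per-channel shift on the normalized
#'   \code{[-1, 1]} intensity scale.
#' @slot horizontalFlip,verticalFlip apply the flip with probability 0.5 when
#'   TRUE.
#' @export
setClass("AugmentConfig",
         representation(rotationRange = "numeric", widthShiftRange = "numeric",
                        heightShiftRange = "numeric",
                        channelShiftRange = "numeric",
                        horizontalFlip = "logical", verticalFlip = "logical"))

setValidity("AugmentConfig", function(object) {
  r <- c(object@rotationRange, object@widthShiftRange,
         object@heightShiftRange, object@channelShiftRange)
  if (any(r < 0)) return("all ranges must be >= 0")
  if (object@widthShiftRange > 1 || object@heightShiftRange > 1)
    return("shift fractions must be <= 1")
  TRUE
})

#' Construct an augmentation configuration
#'
#' @param rotationRange degrees (default 10).
#' @param widthShiftRange,heightShiftRange side fractions (default 0.2).
#' @param channelShiftRange normalized-scale shift (default 0.2).
#' @param horizontalFlip,verticalFlip enable flips (default TRUE).
#' @return An \linkS4class{AugmentConfig}.
#' @export
augmentConfig <- function(rotationRange = 10, widthShiftRange = 0.2,
                          heightShiftRange = 0.2, channelShiftRange = 0.2,
                          horizontalFlip = TRUE, verticalFlip = TRUE) {
  new("AugmentConfig", rotationRange = rotationRange,
      widthShiftRange = widthShiftRange, heightShiftRange = heightShiftRange,
      channelShiftRange = channelShiftRange, horizontalFlip = horizontalFlip,
      verticalFlip = verticalFlip)
}

#' UrNet architecture configuration
#'
#' UrNet is a U-shaped encoder-decoder whose encoding path is a ResNet18-style
#' stack: a 7x7 stride-2 stem followed by four stages of basic residual units
#' (two 3x3 conv+BN+ReLU with an identity shortcut; the first unit of stages
#' 2-4 downsamples with stride 2 and a 1x1 projection shortcut). The decoder
#' mirrors with 2x bilinear upsampling, concatenation of the same-resolution
#' encoder feature map, and two 3x3 conv+BN+ReLU per level; a 1x1 head maps
#' to the two class scores. Dropout is applied at the bottleneck.
#'
#' @slot inputSide input image side in pixels; must be divisible by 16
#'   (stem stride 2 plus three stage downsamplings).
#' @slot inChannels input channels (3).
#' @slot numClasses output classes (2: background, tongue).
#' @slot encoderChannels per-stage widths before scaling (64, 128, 256, 512).
#' @slot blocksPerStage residual units per stage (2, as in ResNet18).
#' @slot dropoutRate bottleneck dropout fraction in \code{[0, 1)}.
#' @slot widthMultiplier scale factor applied to all widths; fractions such
#'   as 1/8 give tiny models for tests.
#' @export
setClass("UrNetConfig",
         representation(inputSide = "integer", inChannels = "integer",
                        numClasses = "integer", encoderChannels = "integer",
                        blocksPerStage = "integer", dropoutRate = "numeric",
                        widthMultiplier = "numeric"))

setValidity("UrNetConfig", function(object) {
  if (object@inputSide %% 16L != 0L)
    return("inputSide must be divisible by 16 (total downsampling factor)")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  if (length(object@encoderChannels) != 4L)
    return("encoderChannels must have 4 stages")
  if (object@blocksPerStage < 1L) return("blocksPerStage must be >= 1")
  if (object@widthMultiplier <= 0) return("widthMultiplier must be > 0")
  TRUE
})

#' Construct a UrNet configuration
#'
#' @param inputSide input side (default 256).
#' @param inChannels input channels (default 3).
#' @param numClasses classes (default 2).
#' @param encoderChannels stage widths (default c(64, 128, 256, 512)).
#' @param blocksPerStage residual units per stage (default 2).
#' @param dropoutRate bottleneck dropout (default 0.6).
#' @param widthMultiplier width scale (default 1).
#' @return A \linkS4class{UrNetConfig}.
#' @export
urNetConfig <- function(inputSide = 256L, inChannels = 3L, numClasses = 2L,
                        encoderChannels = c(64L, 128L, 256L, 512L),
                        blocksPerStage = 2L, dropoutRate = 0.6,
                        widthMultiplier = 1) {
  new("UrNetConfig", inputSide = as.integer(inputSide),
      inChannels = as.integer(inChannels), numClasses = as.integer(numClasses),
      encoderChannels = as.integer(encoderChannels),
      blocksPerStage = as.integer(blocksPerStage),
      dropoutRate = as.numeric(dropoutRate),
      widthMultiplier = as.numeric(widthMultiplier))
}

#' Training configuration
#'
#' Adam with pixelwise cross-entropy; the learning rate follows the
#' inverse-time decay \code{lr0 / (1 + decay * iteration)} where the
#' iteration counter is optimizer steps (batches). Training stops early once
#' the monitored loss has not strictly improved for \code{patience}
#' consecutive epochs, and the best-loss weights are restored.
#'
#' @slot lr0 initial learning rate.
#' @slot decay inverse-time decay coefficient.
#' @slot optimizer only \code{"adam"}.
#' @slot loss only \code{"cross-entropy"}.
#' @slot patience early-stopping patience in epochs.
#' @slot maxEpochs epoch cap.
#' @slot batchSize minibatch size.
#' @slot seed RNG seed covering initialization, shuffling and dropout.
#' @slot monitor \code{"train"} (default) or \code{"val"} loss.
#' @export
setClass("TrainConfig",
         representation(lr0 = "numeric", decay = "numeric",
                        optimizer = "character", loss = "character",
                        patience = "integer", maxEpochs = "integer",
                        batchSize = "integer", seed = "integer",
                        monitor = "character"))

setValidity("TrainConfig", function(object) {
  if (object@lr0 <= 0) return("lr0 must be > 0")
  if (object@decay < 0) return("decay must be >= 0")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@optimizer != "adam") return("only the adam optimizer is provided")
  if (object@loss != "cross-entropy")
    return("only the cross-entropy loss is provided")
  if (!object@monitor %in% c("train", "val"))
    return("monitor must be 'train' or 'val'")
  TRUE
})

#' Construct a training configuration
#'
#' @param lr0 initial learning rate (default 1e-3).
#' @param decay decay coefficient (default 1e-4).
#' @param patience early-stop patience in epochs (default 10).
#' @param maxEpochs epoch cap (default 100).
#' @param batchSize minibatch size (default 4).
#' @param seed RNG seed (default 1).
#' @param monitor monitored loss, "train" (default) or "val".
#' @param optimizer,loss fixed to "adam" / "cross-entropy".
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lr0 = 1e-3, decay = 1e-4, patience = 10L,
                        maxEpochs = 100L, batchSize = 4L, seed = 1L,
                        monitor = "train", optimizer = "adam",
                        loss = "cross-entropy") {
  new("TrainConfig", lr0 = lr0, decay = decay, optimizer = optimizer,
      loss = loss, patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed), monitor = monitor)
}

#' Training history
#'
#' @slot history data.frame with one row per completed epoch: epoch, loss,
#'   lr (learning rate at the last step of the epoch) and, when a validation
#'   set was supplied, valLoss, valPA, valMIoU.
#' @slot stopEpoch last epoch run.
#' @slot stopReason \code{"early_stop"} or \code{"max_epochs"}.
#' @slot bestEpoch epoch whose weights were restored.
#' @export
setClass("TrainHistory",
         representation(history = "data.frame", stopEpoch = "integer",
                        stopReason = "character", bestEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  if (!object@stopReason %in% c("early_stop", "max_epochs"))
    return("stopReason must be 'early_stop' or 'max_epochs'")
  TRUE
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs (%s), best epoch %d, final loss %.5g\n",
              object@stopEpoch, object@stopReason, object@bestEpoch,
              object@history$loss[nrow(object@history)]))
})

## Synthetic scenes ---------------------------------------------------------

#' Synthetic tongue-scene specification
#'
#' Parameters of the generator that emulates the structure of a clinical
#' tongue photograph: a roughly elliptical reddish tongue, a lip band whose
#' color is deliberately close to the tongue (the hard case for
#' segmentation), and a noisy background, with exact ground truth.
#'
#' @slot side canvas side in pixels.
#' @slot tongueAxes numeric(4): (min, max) horizontal and (min, max) vertical
#'   semi-axis as fractions of the side, each in (0, 0.5).
#' @slot tongueColor,backgroundColor mean RGB colors in \code{[0, 255]}.
#' @slot lipTongueColorGap Euclidean RGB distance between the lip and tongue
#'   mean colors; the difficulty knob (smaller = harder).
#' @slot textureNoiseSd per-pixel Gaussian color noise sd.
#' @slot seed RNG seed.
#' @export
setClass("SceneSpec",
         representation(side = "integer", tongueAxes = "numeric",
                        tongueColor = "numeric", backgroundColor = "numeric",
                        lipTongueColorGap = "numeric",
                        textureNoiseSd = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (length(object@tongueAxes) != 4L ||
      any(object@tongueAxes <= 0) || any(object@tongueAxes >= 0.5))
    return("tongueAxes must be 4 fractions in (0, 0.5)")
  if (object@tongueAxes[1] > object@tongueAxes[2] ||
      object@tongueAxes[3] > object@tongueAxes[4])
    return("tongueAxes ranges must be (min, max) pairs")
  cols <- c(object@tongueColor, object@backgroundColor)
  if (any(cols < 0) || any(cols > 255)) return("colors must lie in [0, 255]")
  if (object@textureNoiseSd < 0) return("textureNoiseSd must be >= 0")
  if (object@lipTongueColorGap < 0) return("lipTongueColorGap must be >= 0")
  TRUE
})

#' Construct a scene specification
#'
#' Defaults render a 256 x 256 scene (the pipeline's canonical resolution, so
#' fixtures skip resizing) with a tongue occupying roughly 8-30 percent of
#' the canvas and a lip band 40 RGB units away from the tongue color.
#'
#' @param side canvas side (default 256).
#' @param tongueAxes c(aMin, aMax, bMin, bMax) semi-axis fractions
#'   (default c(0.16, 0.26, 0.20, 0.30)).
#' @param tongueColor mean tongue RGB (default c(185, 92, 96)).
#' @param backgroundColor mean background RGB (default c(70, 72, 82)).
#' @param lipTongueColorGap lip/tongue color distance (default 40).
#' @param textureNoiseSd pixel noise sd (default 8).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(side = 256L, tongueAxes = c(0.16, 0.26, 0.20, 0.30),
                      tongueColor = c(185, 92, 96),
                      backgroundColor = c(70, 72, 82),
                      lipTongueColorGap = 40, textureNoiseSd = 8, seed = 1L) {
  new("SceneSpec", side = as.integer(side), tongueAxes = tongueAxes,
      tongueColor = tongueColor, backgroundColor = backgroundColor,
      lipTongueColorGap = lipTongueColorGap, textureNoiseSd = textureNoiseSd,
      seed = as.integer(seed))
}

#' Mask corruption specification
#'
#' Emulates the error modes of a coarse CNN mask: a smooth bounded
#' displacement of the tongue boundary (over/under-segmentation at the
#' margin) plus small wrong-label speckles.
#'
#' @slot boundaryJitterPx max inward/outward boundary displacement in pixels.
#' @slot speckleCount number of flipped disks.
#' @slot speckleRadiusPx disk radius in pixels.
#' @slot seed RNG seed.
#' @export
setClass("CorruptionSpec",
         representation(boundaryJitterPx = "numeric", speckleCount = "integer",
                        speckleRadiusPx = "numeric", seed = "integer"))

setValidity("CorruptionSpec", function(object) {
  if (object@boundaryJitterPx < 0 || object@speckleCount < 0L ||
      object@speckleRadiusPx < 0)
    return("all corruption amounts must be >= 0")
  TRUE
})

#' Construct a corruption specification
#'
#' @param boundaryJitterPx boundary displacement bound (default 3).
#' @param speckleCount flipped disks (default 5).
#' @param speckleRadiusPx disk radius (default 2).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{CorruptionSpec}.
#' @export
corruptionSpec <- function(boundaryJitterPx = 3, speckleCount = 5L,
                           speckleRadiusPx = 2, seed = 1L) {
  new("CorruptionSpec", boundaryJitterPx = as.numeric(boundaryJitterPx),
      speckleCount = as.integer(speckleCount),
      speckleRadiusPx = as.numeric(speckleRadiusPx), seed = as.integer(seed))
}
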