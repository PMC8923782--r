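## Resize, normalize, augment, shuffle --------------------------------------

#' Resize an image (and optionally its mask) to the canonical square
#'
#' The image is resampled with bilinear interpolation; the mask with
#' nearest-neighbor so labels stay in \{0, 1\}. Inputs already at the target
#' size are returned unchanged.
#'
#' @param img an \linkS4class{RgbImage}.
#' @param mask optional \{0, 1\} integer matrix of the same height/width.
#' @param side target side in pixels (default 256).
#' @return The resized \code{RgbImage} when \code{mask} is NULL, otherwise
#'   \code{list(img = , mask = )}.
#' @export
resizeToCanonical <- function(img, mask = NULL, side = 256L) {
  stopifnot(is(img, "RgbImage"))
  if (side <= 0) stop("side must be positive", call. = FALSE)
  px <- imgData(img)
  if (!is.null(mask)) {
    assertMask(mask)
    assertSameShape(px, mask, "image", "mask")
  }
  if (all(dim(px)[1:2] == c(side, side))) {
    out <- img
  } else {
    lim <- if (valueRange(img) == "raw8bit") c(0, 255) else c(-1, 1)
    # EBImage works in x-first layout
    e <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    r <- EBImage::resize(e, w = side, h = side)  # bilinear
    out <- rgbImage(clamp(aperm(EBImage::imageData(r), c(2, 1, 3)),
                          lim[1], lim[2]),
                    valueRange = valueRange(img))
  }
  if (is.null(mask)) return(out)
  if (all(dim(mask) == c(side, side))) {
    rmask <- mask
  } else {
    em <- EBImage::Image(t(mask))
    rm_ <- EBImage::resize(em, w = side, h = side, filter = "none")
    rmask <- t(EBImage::imageData(rm_))
    storage.mode(rmask) <- "integer"
    assertMask(rmask, "resized mask")
  }
  list(img = out, mask = rmask)
}

#' Normalize a raw 8-bit image to the \code{[-1, +1]} interval
#'
#' Applies \code{2 * v / 255 - 1} to every pixel value and retags the image
#' as normalized. Normalizing an already-normalized image is an error (no
#' double normalization).
#'
#' @param img an \linkS4class{RgbImage} with \code{valueRange = "raw8bit"}.
#' @return The normalized \linkS4class{RgbImage}.
#' @examples
#' img <- rgbImage(array(255, c(2, 2, 3)))
#' range(imgData(normalizeImage(img)))  # +1, +1
#' @export
normalizeImage <- function(img) {
  stopifnot(is(img, "RgbImage"))
  if (valueRange(img) != "raw8bit")
    stop("image is already normalized", call. = FALSE)
  rgbImage(2 * imgData(img) / 255 - 1, valueRange = "normalized")
}

# Inverse-mapping affine warp shared by image (bilinear, edge-replicated
# fill) and mask (nearest neighbor, background fill). theta in degrees,
# shifts in pixels, flips applied about the image center.
affineWarp <- function(px, theta, tx, ty, flipH, flipV, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  ismat <- is.matrix(px)
  if (ismat) px <- array(px, c(dim(px), 1L))
  h <- dim(px)[1]; w <- dim(px)[2]; nc <- dim(px)[3]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  # output pixel grid (0-based), column-major to match R matrix layout
  xo <- rep(0:(w - 1), each = h) - cx
  yo <- rep(0:(h - 1), times = w) - cy
  if (flipH) xo <- -xo
  if (flipV) yo <- -yo
  rad <- -theta * pi / 180  # inverse rotation
  xs <- cos(rad) * (xo - tx) - sin(rad) * (yo - ty) + cx
  ys <- sin(rad) * (xo - tx) + cos(rad) * (yo - ty) + cy
  out <- array(0, dim(px))
  if (kind == "mask") {
    ri <- round(ys); ci <- round(xs)
    ok <- ri >= 0 & ri <= h - 1 & ci >= 0 & ci <= w - 1
    idx <- ri + 1 + ci * h
    v <- numeric(h * w)
    v[ok] <- px[, , 1][idx[ok]]
    out[, , 1] <- matrix(v, h, w)
  } else {
    xs <- clamp(xs, 0, w - 1); ys <- clamp(ys, 0, h - 1)
    r0 <- floor(ys); c0 <- floor(xs)
    r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
    fy <- ys - r0; fx <- xs - c0
    i00 <- r0 + 1 + c0 * h; i01 <- r0 + 1 + c1 * h
    i10 <- r1 + 1 + c0 * h; i11 <- r1 + 1 + c1 * h
    for (ch in seq_len(nc)) {
      v <- px[, , ch]
      out[, , ch] <- matrix(v[i00] * (1 - fy) * (1 - fx) +
                            v[i01] * (1 - fy) * fx +
                            v[i10] * fy * (1 - fx) +
                            v[i11] * fy * fx, h, w)
    }
  }
  if (ismat) out[, , 1] else out
}

#' Randomly augment an image/mask pair
#'
#' Draws one random geometric transform -- rotation within
#' \code{[-rotationRange, +rotationRange]} degrees, horizontal/vertical
#' shifts within the configured side fractions, and optional flips (each
#' applied with probability 0.5 when enabled) -- and applies it identically
#' to the image and the mask. An additive per-channel intensity shift is
#' then applied to the image only. Pixels exposed by the geometric transform
#' are filled with the nearest edge value in the image and with background
#' (0) in the mask, so augmentation can never create phantom tongue pixels.
#' Draws are consumed from R's global RNG; seed with \code{set.seed} for
#' reproducibility.
#'
#' @param img an \linkS4class{RgbImage} (raw or normalized).
#' @param mask \{0, 1\} integer matrix of the same height/width.
#' @param cfg an \linkS4class{AugmentConfig}.
#' @return \code{list(img = , mask = )}, plus attribute \code{"draws"}
#'   recording the sampled transform parameters.
#' @export
augmentPair <- function(img, mask, cfg = augmentConfig()) {
  stopifnot(is(img, "RgbImage"), is(cfg, "AugmentConfig"))
  assertMask(mask)
  px <- imgData(img)
  assertSameShape(px, mask, "image", "mask")
  h <- dim(px)[1]; w <- dim(px)[2]
  theta <- runif(1, -cfg@rotationRange, cfg@rotationRange)
  tx <- runif(1, -cfg@widthShiftRange, cfg@widthShiftRange) * w
  ty <- runif(1, -cfg@heightShiftRange, cfg@heightShiftRange) * h
  flipH <- cfg@horizontalFlip && runif(1) < 0.5
  flipV <- cfg@verticalFlip && runif(1) < 0.5
  geom <- !(theta == 0 && tx == 0 && ty == 0 && !flipH && !flipV)
  outPx <- if (geom) affineWarp(px, theta, tx, ty, flipH, flipV, "image") else px
  outMask <- if (geom) affineWarp(mask, theta, tx, ty, flipH, flipV, "mask") else mask
  storage.mode(outMask) <- "integer"
  cshift <- if (cfg@channelShiftRange > 0)
    runif(3, -cfg@channelShiftRange, cfg@channelShiftRange) else c(0, 0, 0)
  if (any(cshift != 0)) {
    # channel shift is defined on the normalized [-1, 1] scale
    scale <- if (valueRange(img) == "raw8bit") 127.5 else 1
    lim <- if (valueRange(img) == "raw8bit") c(0, 255) else c(-1, 1)
    for (ch in 1:3)
      outPx[, , ch] <- clamp(outPx[, , ch] + cshift[ch] * scale,
                             lim[1], lim[2])
  }
  out <- list(img = rgbImage(outPx, valueRange = valueRange(img)),
              mask = outMask)
  attr(out, "draws") <- list(theta = theta, tx = tx / w, ty = ty / h,
                             flipH = flipH, flipV = flipV,
                             channelShift = cshift)
  out
}

#' Randomly permute a dataset of image/mask pairs
#'
#' Uses R's global RNG; deterministic for a fixed \code{set.seed}.
#'
#' @param pairs list of image/mask pairs (any list).
#' @return The same list in permuted order.
#' @export
shuffleDataset <- function(pairs) {
  if (length(pairs) <= 1L) return(pairs)
  pairs[sample.int(length(pairs))]
}
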