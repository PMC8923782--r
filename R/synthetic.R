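## Synthetic tongue scenes with exact ground truth --------------------------

# Unit direction in RGB space along which the lip color departs from the
# tongue color; scaled by the lip/tongue color gap.
.lipDirection <- c(0.5, 0.7, 0.7) / sqrt(sum(c(0.5, 0.7, 0.7)^2))

#' Generate one synthetic tongue scene
#'
#' Renders, deterministically for the spec's seed: a noisy background, a lip
#' band (a partial annulus hugging the upper tongue boundary, at the
#' configured color distance from the tongue mean -- the deliberately hard
#' case where the adjoining area's color approaches the tongue's), and an
#' axis-aligned elliptical tongue with mild per-pixel texture noise. The
#' ground-truth mask is the exact rasterized ellipse (pixel centers inside
#' or on the boundary).
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return list with \code{img} (raw 8-bit \linkS4class{RgbImage}),
#'   \code{mask} (\{0, 1\} integer matrix) and \code{geometry} (the sampled
#'   ellipse center/semi-axes and the lip-band raster, for verification).
#' @examples
#' sc <- generateScene(sceneSpec(side = 64, seed = 7))
#' mean(sc$mask)
#' @export
generateScene <- function(spec = sceneSpec()) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@side
  a <- runif(1, spec@tongueAxes[1], spec@tongueAxes[2]) * n
  b <- runif(1, spec@tongueAxes[3], spec@tongueAxes[4]) * n
  # tongue sits slightly below center, as in a face/tongue photograph
  cx <- (n - 1) / 2 + runif(1, -0.05, 0.05) * n
  cy <- (n - 1) * 0.55 + runif(1, -0.05, 0.05) * n
  xs <- matrix(rep(0:(n - 1), each = n), n, n)   # xs[r, c] = c - 1
  ys <- matrix(rep(0:(n - 1), times = n), n, n)  # ys[r, c] = r - 1
  ell <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
  mask <- (ell <= 1) * 1L
  storage.mode(mask) <- "integer"
  # lip band: partial annulus over the upper tongue boundary
  lipOuter <- ell <= 1.45 & ell > 1
  upper <- ys < cy + 0.15 * b
  lip <- lipOuter & upper
  lipColor <- clamp(spec@tongueColor + spec@lipTongueColorGap * .lipDirection,
                    0, 255)
  px <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    layer <- matrix(spec@backgroundColor[ch], n, n)
    layer[lip] <- lipColor[ch]
    layer[mask == 1L] <- spec@tongueColor[ch]
    px[, , ch] <- layer
  }
  if (spec@textureNoiseSd > 0)
    px <- px + array(rnorm(n * n * 3, sd = spec@textureNoiseSd), c(n, n, 3))
  list(img = rgbImage(clamp(round(px), 0, 255)), mask = mask,
       geometry = list(cx = cx, cy = cy, a = a, b = b, lip = lip))
}

#' Corrupt a mask to emulate coarse-CNN errors
#'
#' Two error modes, both deterministic per seed: (1) boundary jitter -- a
#' smooth random field (Gaussian-blurred white noise, normalized to
#' \code{[-1, 1]}) scaled by \code{boundaryJitterPx} is added to the signed
#' distance transform of the mask and the sum rethresholded, displacing the
#' boundary by at most that many pixels inward or outward; (2) speckles --
#' \code{speckleCount} disks of radius \code{speckleRadiusPx}, placed with
#' centers mutually separated so the flipped regions stay disjoint, have
#' their labels inverted.
#'
#' @param mask \{0, 1\} integer matrix.
#' @param spec a \linkS4class{CorruptionSpec}.
#' @return The corrupted \{0, 1\} integer mask.
#' @export
corruptMask <- function(mask, spec = corruptionSpec()) {
  stopifnot(is(spec, "CorruptionSpec"))
  assertMask(mask)
  validObject(spec)
  set.seed(spec@seed)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  if (spec@boundaryJitterPx > 0 && any(mask == 1L) && any(mask == 0L)) {
    # signed distance: positive inside the tongue, negative outside;
    # EBImage works x-first, hence the transposes
    dIn <- t(EBImage::imageData(EBImage::distmap(t(mask))))
    dOut <- t(EBImage::imageData(EBImage::distmap(t(1L - mask))))
    sdist <- dIn - dOut + ifelse(mask == 1L, -0.5, 0.5)
    field <- matrix(rnorm(h * w), h, w)
    field <- t(EBImage::imageData(EBImage::gblur(t(field), sigma = max(3, spec@boundaryJitterPx * 2))))
    field <- field / max(abs(field))
    out <- (sdist + spec@boundaryJitterPx * field > 0) * 1L
  }
  if (spec@speckleCount > 0L) {
    r <- spec@speckleRadiusPx
    margin <- ceiling(r) + 1
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < spec@speckleCount && tries < 10000L) {
      tries <- tries + 1L
      cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
      if (nrow(centers) == 0L ||
          min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) > 2 * r + 2) {
        centers <- rbind(centers, cand)
      }
    }
    rr <- matrix(rep(seq_len(h), times = w), h, w)
    cc <- matrix(rep(seq_len(w), each = h), h, w)
    for (i in seq_len(nrow(centers))) {
      disk <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= r^2
      out[disk] <- 1L - out[disk]
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a dataset of synthetic scenes
#'
#' Draws per-scene geometry and noise from the template specification (each
#' scene receives its own derived seed, so the whole dataset is reproducible
#' from the master seed).
#'
#' @param n number of scenes (>= 1).
#' @param template a \linkS4class{SceneSpec} whose ranges/colors are shared
#'   by all scenes.
#' @param seed master RNG seed.
#' @return list of \code{list(img = , mask = )} scenes.
#' @export
generateDataset <- function(n, template = sceneSpec(), seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  seeds <- deriveSeeds(seed, n)
  lapply(seq_len(n), function(i) {
    sp <- template
    sp@seed <- seeds[i]
    generateScene(sp)
  })
}
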