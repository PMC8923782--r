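## SLIC superpixels ---------------------------------------------------------
##
## Localized k-means over joint (color, position) features. Seeds start on a
## regular grid with spacing floor(S), S = sqrt(N*N/K); each seed is nudged
## to the lowest-gradient pixel in its local window; pixels are then
## repeatedly assigned to the best seed within each seed's 2S x 2S search
## window under D' = sqrt((d_c/m)^2 + (d_s/S)^2) and seeds move to their
## cluster means. All positions are 0-based (row, col) externally consistent
## with the rest of the package; internal matrices are 1-based R indexing.

#' Initialize SLIC seeds on a regular grid
#'
#' For a square image of side \code{N} and a requested block count \code{K},
#' the seed spacing is \code{S = sqrt(N*N/K)}; seeds sit on a grid with step
#' \code{floor(S)}, offset \code{floor(S/2)} from the border, so the realized
#' seed count \code{floor(N/floor(S))^2} can differ from \code{K}.
#'
#' @param feats pixel feature matrix from the internal color conversion, or
#'   NULL to initialize positions only.
#' @param N image side in pixels (N >= 2).
#' @param K requested number of superpixels (1 <= K <= N*N).
#' @return list with \code{S} (the real-valued spacing) and \code{seeds}, a
#'   data.frame with 0-based \code{row}, \code{col} and (when \code{feats}
#'   is given) the seed colors \code{f1..f3}.
#' @export
initSeeds <- function(feats = NULL, N, K) {
  if (N < 2L) stop("image side must be >= 2", call. = FALSE)
  if (K < 1L || K > N * N)
    stop("K must lie in [1, N*N]", call. = FALSE)
  S <- sqrt(N * N / K)
  step <- floor(S)
  off <- floor(S / 2)
  nPer <- floor(N / step)
  pos <- off + step * (seq_len(nPer) - 1L)  # 0-based coordinates
  seeds <- expand.grid(row = pos, col = pos)[, c("row", "col")]
  seeds <- seeds[order(seeds$row, seeds$col), , drop = FALSE]
  rownames(seeds) <- NULL
  if (!is.null(feats)) {
    W <- attr(feats, "W")
    idx <- seeds$row * W + seeds$col + 1L
    cols <- feats[idx, , drop = FALSE]
    colnames(cols) <- paste0("f", 1:3)
    seeds <- cbind(seeds, cols)
  }
  list(S = S, seeds = seeds)
}

# Per-pixel gradient magnitude: sum over feature channels of squared central
# differences (edge-replicated), as a row-major vector.
featureGradient <- function(feats) {
  H <- attr(feats, "H"); W <- attr(feats, "W")
  g <- numeric(H * W)
  rr <- rep(seq_len(H), each = W); cc <- rep(seq_len(W), times = H)
  iE <- (rr - 1L) * W + pmin(cc + 1L, W)
  iW <- (rr - 1L) * W + pmax(cc - 1L, 1L)
  iS <- (pmin(rr + 1L, H) - 1L) * W + cc
  iN <- (pmax(rr - 1L, 1L) - 1L) * W + cc
  for (ch in seq_len(ncol(feats))) {
    f <- feats[, ch]
    g <- g + (f[iE] - f[iW])^2 + (f[iS] - f[iN])^2
  }
  g
}

#' Nudge seeds to the lowest-gradient pixel in their neighborhood
#'
#' Each seed moves to the pixel with minimum gradient magnitude (sum over
#' channels of squared central differences) within its \code{n x n} window,
#' clipped at the image border. Ties keep the original position when it
#' attains the minimum, otherwise the first minimal pixel in row-major
#' order. Seed colors are re-sampled at the new positions.
#'
#' @param feats pixel feature matrix (attributes H, W set).
#' @param seeds seed data.frame from \code{\link{initSeeds}}.
#' @param n odd window side (default 3).
#' @return The updated seed data.frame.
#' @export
perturbSeeds <- function(feats, seeds, n = 3L) {
  if (n %% 2L != 1L) stop("n must be odd", call. = FALSE)
  H <- attr(feats, "H"); W <- attr(feats, "W")
  g <- featureGradient(feats)
  half <- (n - 1L) %/% 2L
  for (i in seq_len(nrow(seeds))) {
    r0 <- seeds$row[i]; c0 <- seeds$col[i]
    rs <- max(0L, r0 - half):min(H - 1L, r0 + half)
    cs <- max(0L, c0 - half):min(W - 1L, c0 + half)
    win <- outer(rs * W, cs, `+`) + 1L  # row-major pixel indices
    gw <- g[win]
    dim(gw) <- dim(win)
    mn <- min(gw)
    if (g[r0 * W + c0 + 1L] <= mn) next  # original position is minimal
    # first minimal pixel in row-major order
    cand <- which(gw == mn, arr.ind = TRUE)
    ord <- order(rs[cand[, 1]], cs[cand[, 2]])
    pick <- cand[ord[1], ]
    seeds$row[i] <- rs[pick[1]]
    seeds$col[i] <- cs[pick[2]]
  }
  idx <- seeds$row * W + seeds$col + 1L
  seeds[, c("f1", "f2", "f3")] <- feats[idx, , drop = FALSE]
  seeds
}

#' Assign every pixel to its best seed within the search windows
#'
#' Each seed scans a window of half-width \code{ceiling(S)} (the 2S x 2S
#' search range) around its position; a pixel takes the label of the seed
#' minimizing \code{D' = sqrt((d_c/m)^2 + (d_s/S)^2)} among the seeds whose
#' windows cover it, ties going to the lowest seed id. Pixels covered by no
#' window fall back to the globally nearest seed under the same distance.
#'
#' @param feats pixel feature matrix (attributes H, W set).
#' @param seeds seed data.frame with row, col, f1..f3.
#' @param S seed spacing from \code{\link{initSeeds}}.
#' @param m compactness weight.
#' @return Integer vector of seed ids (1-based), row-major over pixels.
#' @export
assignPixels <- function(feats, seeds, S, m) {
  stopifnot(nrow(seeds) >= 1L)
  H <- attr(feats, "H"); W <- attr(feats, "W")
  nPix <- H * W
  bestD <- rep(Inf, nPix)
  label <- integer(nPix)
  half <- ceiling(S)
  fcols <- as.matrix(seeds[, c("f1", "f2", "f3")])
  for (i in seq_len(nrow(seeds))) {
    r0 <- seeds$row[i]; c0 <- seeds$col[i]
    rs <- max(0, ceiling(r0 - half)):min(H - 1, floor(r0 + half))
    cs <- max(0, ceiling(c0 - half)):min(W - 1, floor(c0 + half))
    win <- as.vector(outer(rs * W, cs, `+`)) + 1L
    pr <- rep(rs, times = length(cs)); pc <- rep(cs, each = length(rs))
    dc2 <- (feats[win, 1] - fcols[i, 1])^2 + (feats[win, 2] - fcols[i, 2])^2 +
      (feats[win, 3] - fcols[i, 3])^2
    ds2 <- (pr - r0)^2 + (pc - c0)^2
    D <- dc2 / m^2 + ds2 / S^2  # monotone in D'; sqrt not needed to compare
    better <- D < bestD[win]    # strict: ties keep the earlier (lower) id
    wb <- win[better]
    bestD[wb] <- D[better]
    label[wb] <- i
  }
  un <- which(label == 0L)
  if (length(un) > 0L) {
    pr <- (un - 1L) %/% W; pc <- (un - 1L) %% W
    for (j in seq_along(un)) {
      dc2 <- (fcols[, 1] - feats[un[j], 1])^2 +
        (fcols[, 2] - feats[un[j], 2])^2 + (fcols[, 3] - feats[un[j], 3])^2
      ds2 <- (seeds$row - pr[j])^2 + (seeds$col - pc[j])^2
      D <- dc2 / m^2 + ds2 / S^2
      label[un[j]] <- which.min(D)  # which.min takes the first (lowest id)
    }
  }
  label
}

#' Move seeds to the mean position and color of their members
#'
#' @param label integer assignment vector (row-major) over pixels.
#' @param feats pixel feature matrix (attributes H, W set).
#' @param seeds current seed data.frame (empty blocks keep their seed).
#' @return Updated seed data.frame.
#' @export
updateSeeds <- function(label, feats, seeds) {
  H <- attr(feats, "H"); W <- attr(feats, "W")
  pix <- seq_len(H * W) - 1L  # row-major pixel index
  pr <- pix %/% W
  pc <- pix %% W
  cnt <- tabulate(label, nbins = nrow(seeds))
  sums <- rowsum(cbind(pr, pc, feats), label)
  present <- as.integer(rownames(sums))  # empty blocks keep their seed
  seeds$row[present] <- sums[, 1] / cnt[present]
  seeds$col[present] <- sums[, 2] / cnt[present]
  seeds$f1[present] <- sums[, 3] / cnt[present]
  seeds$f2[present] <- sums[, 4] / cnt[present]
  seeds$f3[present] <- sums[, 5] / cnt[present]
  seeds
}

# Merge connected fragments that do not contain (the rounded position of)
# their seed into the largest adjacent block. Works on per-block bounding
# boxes so the cost scales with block size, not image size.
enforceConnectivity <- function(labMat, seeds) {
  H <- nrow(labMat); W <- ncol(labMat)
  sizes <- tabulate(labMat, nbins = max(labMat))
  for (i in seq_len(max(labMat))) {
    # block membership must be re-read each round: earlier merges may have
    # grown this block
    idx <- which(as.vector(labMat) == i)
    if (length(idx) == 0L) next
    rr <- (idx - 1L) %% H + 1L
    cc0 <- (idx - 1L) %/% H + 1L
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc0); c1 <- max(cc0)
    sub <- labMat[r0:r1, c0:c1, drop = FALSE] == i
    cc <- t(EBImage::imageData(EBImage::bwlabel(t(sub))))  # EBImage: x first
    ncc <- max(cc)
    if (ncc <= 1L) next
    sr <- clamp(round(seeds$row[i]), 0, H - 1) + 1L - r0 + 1L
    sc <- clamp(round(seeds$col[i]), 0, W - 1) + 1L - c0 + 1L
    keepComp <- if (sr >= 1L && sr <= nrow(cc) && sc >= 1L && sc <= ncol(cc))
      cc[sr, sc] else 0L
    if (keepComp == 0L)  # seed drifted outside its block: keep largest
      keepComp <- which.max(tabulate(cc[cc > 0L], nbins = ncc))
    for (comp in seq_len(ncc)) {
      if (comp == keepComp) next
      frag <- which(cc == comp, arr.ind = TRUE)
      frag[, 1] <- frag[, 1] + r0 - 1L
      frag[, 2] <- frag[, 2] + c0 - 1L
      # adjacent block labels of the fragment (4-connectivity)
      neigh <- integer(0)
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nr <- frag[, 1] + d[1]; nc <- frag[, 2] + d[2]
        ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
        v <- labMat[cbind(nr[ok], nc[ok])]
        neigh <- c(neigh, v[v != i])
      }
      target <- if (length(neigh) > 0L) {
        u <- unique(neigh)
        u[which.max(sizes[u])]  # largest adjacent block
      } else i
      labMat[frag] <- target
    }
  }
  labMat
}

#' SLIC superpixel segmentation
#'
#' Runs the full procedure: grid seed initialization, gradient-based seed
#' perturbation, iterated windowed assignment and mean update (with early
#' exit once no label changes), then consecutive relabeling and optional
#' connectivity enforcement (orphan fragments merged into their largest
#' adjacent block). The algorithm is fully deterministic.
#'
#' @param img a square \linkS4class{RgbImage} (resize first if needed).
#' @param params a \linkS4class{SlicParams}.
#' @return A \linkS4class{SuperpixelLabeling}.
#' @examples
#' img <- rgbImage(array(128, c(64, 64, 3)))
#' sp <- slicSuperpixels(img, slicParams(K = 16))
#' nBlocks(sp)
#' @export
slicSuperpixels <- function(img, params = slicParams(K = 200L)) {
  stopifnot(is(img, "RgbImage"), is(params, "SlicParams"))
  validObject(params)
  H <- imgHeight(img); W <- imgWidth(img)
  if (H != W)
    stop("SLIC expects a square image; resizeToCanonical first",
         call. = FALSE)
  if (params@smoothSigma > 0) {
    lim <- if (valueRange(img) == "raw8bit") c(0, 255) else c(-1, 1)
    px <- imgData(img)
    sm <- EBImage::gblur(EBImage::Image(aperm(px, c(2, 1, 3)),
                                        colormode = "Color"),
                         sigma = params@smoothSigma)
    img <- rgbImage(clamp(aperm(EBImage::imageData(sm), c(2, 1, 3)),
                          lim[1], lim[2]), valueRange(img))
  }
  feats <- pixelFeatures(img, params@colorSpace)
  ini <- initSeeds(feats, N = H, K = params@K)
  seeds <- perturbSeeds(feats, ini$seeds, params@perturbWindow)
  label <- NULL
  for (it in seq_len(params@nIters)) {
    newLabel <- assignPixels(feats, seeds, ini$S, params@m)
    if (!is.null(label) && all(newLabel == label)) break
    label <- newLabel
    seeds <- updateSeeds(label, feats, seeds)
  }
  labMat <- matrix(label, H, W, byrow = TRUE)
  if (params@enforceConnectivity)
    labMat <- enforceConnectivity(labMat, seeds)
  # consecutive ids
  u <- sort(unique(as.vector(labMat)))
  labMat <- matrix(match(labMat, u), H, W)
  superpixelLabeling(labMat, params = params)
}

## Export -------------------------------------------------------------------

#' Write / read a superpixel labeling
#'
#' The block-id raster is stored losslessly as a PNG whose first two 8-bit
#' channels carry the high and low byte of each id (supporting up to 65535
#' blocks), accompanied by a JSON sidecar recording the requested K, the
#' realized block count and the SLIC parameters.
#'
#' @param sp a \linkS4class{SuperpixelLabeling}.
#' @param path output PNG path; the sidecar is written next to it with a
#'   \code{.json} extension.
#' @return \code{writeSuperpixels} returns the path invisibly;
#'   \code{readSuperpixels} the restored \linkS4class{SuperpixelLabeling}.
#' @export
writeSuperpixels <- function(sp, path) {
  stopifnot(is(sp, "SuperpixelLabeling"))
  lab <- sp@labels
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  arr[, , 1] <- (lab %/% 256L) / 255
  arr[, , 2] <- (lab %% 256L) / 255
  png::writePNG(arr, path)
  side <- list(nBlocks = sp@nBlocks)
  if (is(sp@params, "SlicParams"))
    side <- c(side, list(K = sp@params@K, m = sp@params@m,
                         nIters = sp@params@nIters,
                         colorSpace = sp@params@colorSpace,
                         smoothSigma = sp@params@smoothSigma))
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSuperpixels
#' @export
readSuperpixels <- function(path) {
  v <- png::readPNG(path)
  lab <- round(v[, , 1] * 255) * 256L + round(v[, , 2] * 255)
  storage.mode(lab) <- "integer"
  superpixelLabeling(lab)
}

#' Write a boundary-overlay image for visual inspection
#'
#' Marks every pixel whose right or lower neighbor carries a different block
#' id in red over the input image.
#'
#' @param img the \linkS4class{RgbImage} the labeling was computed on.
#' @param sp a \linkS4class{SuperpixelLabeling} of the same height/width.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
writeSuperpixelOverlay <- function(img, sp, path) {
  stopifnot(is(img, "RgbImage"), is(sp, "SuperpixelLabeling"))
  lab <- sp@labels
  assertSameShape(imgData(img), lab, "image", "labeling")
  h <- nrow(lab); w <- ncol(lab)
  edge <- matrix(FALSE, h, w)
  edge[, -w] <- lab[, -w] != lab[, -1]
  edge[-h, ] <- edge[-h, ] | (lab[-h, ] != lab[-1, ])
  px <- imgData(img)
  if (valueRange(img) == "normalized") px <- (px + 1) * 127.5
  px <- px / 255
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  r[edge] <- 1; g[edge] <- 0; b[edge] <- 0
  png::writePNG(array(c(r, g, b), c(h, w, 3)), path)
  invisible(path)
}
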