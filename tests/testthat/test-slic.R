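test_that("seed initialization follows the grid spacing rule", {
  s <- initSeeds(N = 256, K = 64)
  expect_equal(s$S, 32)
  expect_equal(nrow(s$seeds), 64)

  s2 <- initSeeds(N = 6, K = 4)
  expect_equal(s2$S, 3)
  expect_equal(sort(unique(s2$seeds$row)), c(1, 4))
  expect_equal(nrow(s2$seeds), 4)

  s3 <- initSeeds(N = 256, K = 50)
  expect_equal(s3$S, sqrt(65536 / 50))
  expect_equal(nrow(s3$seeds), 49)  # grid spacing 36 -> 7 x 7

  expect_error(initSeeds(N = 4, K = 17), "K must lie")
  expect_error(initSeeds(N = 1, K = 1), ">= 2")
})

test_that("seed perturbation finds the window's gradient minimum", {
  # constant image: zero gradient everywhere, tie-break keeps positions
  img <- rgbImage(array(100, c(16, 16, 3)))
  feats <- SpurNet:::pixelFeatures(img)
  ini <- initSeeds(feats, 16, 4)
  moved <- perturbSeeds(feats, ini$seeds)
  expect_equal(moved$row, ini$seeds$row)
  expect_equal(moved$col, ini$seeds$col)

  # crafted gradient field with a unique minimum at the east neighbor:
  # a quadratic valley centered one column right of the seed
  px <- array(0, c(16, 16, 3))
  seedPos <- ini$seeds[1, ]  # at (row, col) = (3, 3) for this grid
  valley <- outer((0:15 - seedPos$row)^2, (0:15 - (seedPos$col + 1))^2, `+`)
  px[, , 1] <- 2 * sqrt(valley)  # |gradient| grows away from the valley floor
  img2 <- rgbImage(pmin(pmax(px, 0), 255))
  feats2 <- SpurNet:::pixelFeatures(img2, colorSpace = "rgb")
  moved2 <- perturbSeeds(feats2, ini$seeds[1, , drop = FALSE])
  expect_equal(moved2$col, seedPos$col + 1)
  expect_equal(moved2$row, seedPos$row)

  # random image: every perturbed position is the exhaustive window argmin
  set.seed(31)
  img3 <- rgbImage(array(runif(24 * 24 * 3) * 255, c(24, 24, 3)))
  feats3 <- SpurNet:::pixelFeatures(img3)
  ini3 <- initSeeds(feats3, 24, 36)
  g <- SpurNet:::featureGradient(feats3)
  moved3 <- perturbSeeds(feats3, ini3$seeds)
  for (i in seq_len(nrow(moved3))) {
    r0 <- ini3$seeds$row[i]; c0 <- ini3$seeds$col[i]
    rs <- max(0, r0 - 1):min(23, r0 + 1)
    cs <- max(0, c0 - 1):min(23, c0 + 1)
    vals <- sapply(rs, function(r) sapply(cs, function(c) g[r * 24 + c + 1]))
    expect_equal(g[moved3$row[i] * 24 + moved3$col[i] + 1], min(vals))
  }
  expect_error(perturbSeeds(feats3, ini3$seeds, n = 4), "odd")
})

test_that("windowed assignment equals the all-seeds oracle when covered", {
  # The windowed pass provably equals exhaustive nearest-seed search when
  # every pixel is window-covered and the color term cannot outweigh the
  # spatial penalty of leaving the window (color spread bounded relative to
  # m) -- the regime superpixels are designed for. Moderate-contrast random
  # images with m = 100 satisfy both premises.
  set.seed(32)
  for (rep in 1:3) for (K in c(4, 9, 16)) {
    N <- sample(16:32, 1)
    img <- rgbImage(array(108 + runif(N * N * 3) * 40, c(N, N, 3)))
    feats <- SpurNet:::pixelFeatures(img)
    ini <- initSeeds(feats, N, K)
    if (!windowsCoverImage(ini$seeds, ini$S, N, N)) next
    lab <- assignPixels(feats, ini$seeds, ini$S, m = 100)
    expect_identical(lab, oracleAssignAllSeeds(feats, ini$seeds, ini$S, 100))
  }
})

test_that("assignment distances behave as the metric dictates", {
  # identical colors: the spatially closer seed wins
  img <- rgbImage(array(50, c(12, 12, 3)))
  feats <- SpurNet:::pixelFeatures(img)
  seeds <- data.frame(row = c(3, 9), col = c(3, 9),
                      f1 = unname(feats[1, 1]), f2 = unname(feats[1, 2]),
                      f3 = unname(feats[1, 3]))
  lab <- assignPixels(feats, seeds, S = 6, m = 10)
  expect_equal(lab[3 * 12 + 4 + 1], 1)   # pixel (3,4): near seed 1
  expect_equal(lab[9 * 12 + 8 + 1], 2)   # pixel (9,8): near seed 2

  # m -> infinity: labeling approaches the purely spatial Voronoi partition
  set.seed(33)
  img2 <- rgbImage(array(runif(12 * 12 * 3) * 255, c(12, 12, 3)))
  feats2 <- SpurNet:::pixelFeatures(img2)
  ini <- initSeeds(feats2, 12, 4)
  labBig <- assignPixels(feats2, ini$seeds, ini$S, m = 1e9)
  for (p in 1:144) {
    pr <- (p - 1) %/% 12; pc <- (p - 1) %% 12
    ds2 <- (ini$seeds$row - pr)^2 + (ini$seeds$col - pc)^2
    if (sum(ds2 == min(ds2)) == 1L)  # spatially tied pixels excluded:
      expect_equal(labBig[p], which.min(ds2))  # residual color noise decides
  }
})

test_that("seed update moves to member centroids and stays in bounds", {
  img <- rgbImage(array(77, c(8, 8, 3)))
  feats <- SpurNet:::pixelFeatures(img)
  # exact quadrant blocks on an 8x8 canvas
  labMat <- matrix(1L, 8, 8)
  labMat[1:4, 5:8] <- 2L; labMat[5:8, 1:4] <- 3L; labMat[5:8, 5:8] <- 4L
  label <- as.integer(t(labMat))
  seeds <- data.frame(row = c(0, 0, 7, 7), col = c(0, 7, 0, 7),
                      f1 = unname(feats[1, 1]), f2 = unname(feats[1, 2]),
                      f3 = unname(feats[1, 3]))
  up <- updateSeeds(label, feats, seeds)
  expect_equal(up$row, c(1.5, 1.5, 5.5, 5.5))
  expect_equal(up$col, c(1.5, 5.5, 1.5, 5.5))
  expect_true(all(up$row >= 0 & up$row <= 7 & up$col >= 0 & up$col <= 7))
  # fixed point: updating again changes nothing
  up2 <- updateSeeds(label, feats, up)
  expect_equal(up2, up)
  # empty blocks keep their previous seed
  seeds5 <- rbind(seeds, data.frame(row = 3, col = 3, f1 = 0, f2 = 0, f3 = 0))
  up5 <- updateSeeds(label, feats, seeds5)
  expect_equal(unlist(up5[5, ]), unlist(seeds5[5, ]))
})

test_that("full SLIC yields a deterministic near-regular partition", {
  img <- rgbImage(array(128, c(64, 64, 3)))
  sp <- slicSuperpixels(img, slicParams(K = 16))
  expect_s4_class(sp, "SuperpixelLabeling")
  expect_equal(nBlocks(sp), 16)
  sizes <- tabulate(spLabels(sp), nbins = 16)
  expect_true(all(sizes >= 225 & sizes <= 289))  # ~256 pixels each
  expect_true(all(sort(unique(as.vector(spLabels(sp)))) == 1:16))

  # determinism: no RNG anywhere in SLIC
  sp2 <- slicSuperpixels(img, slicParams(K = 16))
  expect_identical(spLabels(sp), spLabels(sp2))

  expect_error(slicSuperpixels(rgbImage(array(1, c(8, 16, 3)))), "square")
})

test_that("SLIC blocks respect a strong color boundary", {
  # two flat color halves: with a small compactness weight every block must
  # stay inside one half, so the block boundary coincides with the color edge
  px <- array(30, c(32, 32, 3))
  px[, 17:32, 1] <- 220
  img <- rgbImage(px)
  sp <- slicSuperpixels(img, slicParams(K = 4, m = 1))
  lab <- spLabels(sp)
  for (b in seq_len(nBlocks(sp))) {
    cols <- which(lab == b, arr.ind = TRUE)[, 2]
    expect_true(all(cols <= 16) || all(cols >= 17))
  }
})

test_that("SLIC partitions survive connectivity enforcement", {
  set.seed(35)
  img <- rgbImage(array(runif(48 * 48 * 3) * 255, c(48, 48, 3)))
  sp <- slicSuperpixels(img, slicParams(K = 9))
  lab <- spLabels(sp)
  expect_equal(length(lab), 48 * 48)
  expect_identical(sort(unique(as.vector(lab))), seq_len(nBlocks(sp)))
  expect_gte(nBlocks(sp), 1)
  # every block is one connected component after enforcement
  for (b in seq_len(nBlocks(sp))) {
    cc <- EBImage::bwlabel(t(lab == b))
    expect_equal(max(cc), 1)
  }
})

test_that("superpixel labelings export losslessly with a sidecar and overlay", {
  img <- rgbImage(array(128, c(32, 32, 3)))
  sp <- slicSuperpixels(img, slicParams(K = 9))
  f <- tempfile(fileext = ".png")
  writeSuperpixels(sp, f)
  back <- readSuperpixels(f)
  expect_identical(spLabels(back), spLabels(sp))
  side <- jsonlite::fromJSON(paste0(tools::file_path_sans_ext(f), ".json"))
  expect_equal(side$nBlocks, nBlocks(sp))
  expect_equal(side$K, 9)
  ov <- tempfile(fileext = ".png")
  writeSuperpixelOverlay(img, sp, ov)
  v <- png::readPNG(ov)
  edges <- v[, , 1] == 1 & v[, , 2] == 0
  expect_gt(sum(edges), 0)  # boundaries marked in red
})
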