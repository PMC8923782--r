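## Superpixel coverage refinement (SpurNet stage two) -----------------------

#' Per-block tongue coverage
#'
#' For every superpixel block, the fraction of its pixels carrying the
#' tongue label (1) in the coarse mask.
#'
#' @param sp a \linkS4class{SuperpixelLabeling}.
#' @param mask \{0, 1\} integer matrix of the same height/width.
#' @return Numeric vector of length \code{nBlocks(sp)} with values in
#'   \code{[0, 1]}.
#' @export
blockCoverage <- function(sp, mask) {
  stopifnot(is(sp, "SuperpixelLabeling"))
  assertMask(mask)
  assertSameShape(sp@labels, mask, "superpixel labeling", "mask")
  lab <- as.vector(sp@labels)
  tot <- tabulate(lab, nbins = sp@nBlocks)
  pos <- tabulate(lab[as.vector(mask) == 1L], nbins = sp@nBlocks)
  pos / tot
}

#' Refine a coarse mask by superpixel coverage thresholding
#'
#' Every block whose tongue coverage is strictly greater than \code{theta}
#' survives: in \code{"retain"} mode its pixels keep their coarse labels (so
#' refinement never adds tongue pixels); in \code{"fill"} mode its pixels
#' are all set to tongue. Blocks at or below the threshold are cleared to
#' background. With \code{theta = 1} no block can survive (coverage cannot
#' exceed 1) and the result is the empty mask.
#'
#' @param mask coarse \{0, 1\} integer matrix.
#' @param sp a \linkS4class{SuperpixelLabeling} of the same height/width.
#' @param params a \linkS4class{RefineParams} (only \code{theta} and
#'   \code{mode} are used here; \code{slicParams} documents provenance).
#' @return The refined \{0, 1\} integer mask.
#' @examples
#' sp <- superpixelLabeling(matrix(rep(1:2, each = 8), 4, 4))
#' mask <- matrix(c(rep(1L, 7), rep(0L, 9)), 4, 4)
#' refineMask(mask, sp, refineParams(theta = 0.5))
#' @export
refineMask <- function(mask, sp, params = refineParams()) {
  stopifnot(is(sp, "SuperpixelLabeling"), is(params, "RefineParams"))
  assertMask(mask)
  assertSameShape(mask, sp@labels, "mask", "superpixel labeling")
  keep <- blockCoverage(sp, mask) > params@theta  # strictly "more than theta"
  keepPix <- matrix(keep[sp@labels], nrow(mask), ncol(mask))
  out <- if (params@mode == "retain") mask * keepPix else keepPix * 1L
  storage.mode(out) <- "integer"
  out
}

#' Full two-stage segmentation: coarse network mask + superpixel refinement
#'
#' Composition of the pipeline on one image: normalize (if needed), predict
#' the coarse mask with the network, compute SLIC superpixels on the image,
#' and refine the coarse mask by coverage thresholding.
#'
#' @param img an \linkS4class{RgbImage} at the model's input side (raw or
#'   already normalized).
#' @param model a trained \linkS4class{UrNetModel}.
#' @param params a \linkS4class{RefineParams}; its \code{slicParams} drive
#'   the superpixel stage.
#' @return list with \code{mask} (refined), \code{coarse} and \code{sp} (the
#'   \linkS4class{SuperpixelLabeling}).
#' @export
spurnetSegment <- function(img, model, params = refineParams()) {
  stopifnot(is(img, "RgbImage"))
  norm <- if (valueRange(img) == "raw8bit") normalizeImage(img) else img
  coarse <- predictMask(model, norm)
  sp <- slicSuperpixels(img, params@slicParams)
  refined <- refineMask(coarse, sp, params)
  list(mask = refined, coarse = coarse, sp = sp)
}
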