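#' @import methods
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils head modifyList read.csv write.csv
NULL

## Central raster containers ------------------------------------------------

#' RGB image container
#'
#' An H x W x 3 numeric array of color intensities together with a tag
#' recording whether values are raw 8-bit (\code{[0, 255]}) or normalized to
#' \code{[-1, +1]}. All SpurNet operations consume and produce this class;
#' masks, by contrast, are plain integer matrices with values 0 (background)
#' and 1 (tongue).
#'
#' @slot pixels numeric array, height x width x 3.
#' @slot valueRange \code{"raw8bit"} or \code{"normalized"}.
#' @export
setClass("RgbImage", representation(pixels = "array", valueRange = "character"))

setValidity("RgbImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have at least one row and one column")
  if (!object@valueRange %in% c("raw8bit", "normalized"))
    return("valueRange must be 'raw8bit' or 'normalized'")
  lim <- if (object@valueRange == "raw8bit") c(0, 255) else c(-1, 1)
  px <- object@pixels
  if (anyNA(px) || min(px) < lim[1] - 1e-9 || max(px) > lim[2] + 1e-9)
    return(sprintf("pixel values outside declared range [%g, %g]", lim[1], lim[2]))
  TRUE
})

#' Construct an RgbImage
#'
#' @param pixels H x W x 3 numeric array (a 2D matrix is replicated to 3
#'   identical channels).
#' @param valueRange \code{"raw8bit"} (default) or \code{"normalized"}.
#' @return An \linkS4class{RgbImage}.
#' @examples
#' img <- rgbImage(array(128, dim = c(8, 8, 3)))
#' imgHeight(img)
#' @export
rgbImage <- function(pixels, valueRange = "raw8bit") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  new("RgbImage", pixels = pixels, valueRange = valueRange)
}

#' @describeIn rgbImage pixel array accessor
#' @param x an \code{RgbImage}
#' @export
imgData <- function(x) x@pixels

#' @describeIn rgbImage declared value range ("raw8bit" or "normalized")
#' @export
valueRange <- function(x) x@valueRange

#' @describeIn rgbImage image height in pixels
#' @export
imgHeight <- function(x) dim(x@pixels)[1]

#' @describeIn rgbImage image width in pixels
#' @export
imgWidth <- function(x) dim(x@pixels)[2]

setMethod("show", "RgbImage", function(object) {
  cat(sprintf("RgbImage %d x %d x 3 (%s)\n",
              imgHeight(object), imgWidth(object), object@valueRange))
})

#' Polygon annotation (Labelme dialect)
#'
#' Ordered polygon outlines with category names, as produced by graphical
#' contour labeling tools. Vertices are (x, y) pixel coordinates, x along
#' width, y along height, 0-based at the top-left pixel center.
#'
#' @slot shapes list; each element a list with \code{label} (character) and
#'   \code{points} (n x 2 numeric matrix of (x, y) vertices, n >= 3).
#' @slot imageHeight,imageWidth canvas size in pixels.
#' @export
setClass("PolygonAnnotation",
         representation(shapes = "list", imageHeight = "integer",
                        imageWidth = "integer"))

setValidity("PolygonAnnotation", function(object) {
  for (s in object@shapes) {
    if (!is.character(s$label)) return("each shape needs a character label")
    p <- s$points
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return("each polygon needs an n x 2 vertex matrix with n >= 3")
  }
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    return("canvas must be at least 1 x 1")
  TRUE
})

#' Construct a PolygonAnnotation
#'
#' @param shapes list of \code{list(label = , points = )} entries; each
#'   \code{points} an n x 2 matrix of (x, y) vertices.
#' @param imageHeight,imageWidth canvas size in pixels.
#' @return A \linkS4class{PolygonAnnotation}.
#' @export
polygonAnnotation <- function(shapes, imageHeight, imageWidth) {
  shapes <- lapply(shapes, function(s)
    list(label = as.character(s$label),
         points = matrix(as.numeric(s$points), ncol = 2L,
                         nrow = NROW(s$points))))
  new("PolygonAnnotation", shapes = shapes,
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth))
}

setMethod("show", "PolygonAnnotation", function(object) {
  cat(sprintf("PolygonAnnotation: %d shape(s) on %d x %d canvas\n",
              length(object@shapes), object@imageHeight, object@imageWidth))
  for (s in object@shapes)
    cat(sprintf("  '%s' (%d vertices)\n", s$label, nrow(s$points)))
})

## SLIC ---------------------------------------------------------------------

#' SLIC superpixel parameters
#'
#' @slot K requested number of superpixels; the realized count can differ
#'   because seeds sit on an integer grid.
#' @slot m compactness weight trading color fidelity against spatial
#'   regularity; larger m gives more compact, grid-like blocks. Expressed on
#'   the scale of the working color space (CIELAB by default).
#' @slot nIters number of assign/update iterations.
#' @slot perturbWindow odd side of the neighborhood searched for the lowest
#'   gradient when seeds are nudged off edges at initialization.
#' @slot enforceConnectivity merge orphan fragments into their largest
#'   adjacent block after clustering.
#' @slot colorSpace \code{"lab"} (default) or \code{"rgb"} for the distance
#'   computation.
#' @slot smoothSigma Gaussian pre-smoothing of the image (in pixels) before
#'   color features are extracted; 0 disables. Smoothing suppresses pixel
#'   noise that would otherwise degrade superpixel boundary adherence.
#' @export
setClass("SlicParams",
         representation(K = "integer", m = "numeric", nIters = "integer",
                        perturbWindow = "integer",
                        enforceConnectivity = "logical",
                        colorSpace = "character", smoothSigma = "numeric"))

setValidity("SlicParams", function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (object@m <= 0) return("m must be > 0")
  if (object@nIters < 1L) return("nIters must be >= 1")
  if (object@perturbWindow %% 2L != 1L) return("perturbWindow must be odd")
  if (!object@colorSpace %in% c("lab", "rgb"))
    return("colorSpace must be 'lab' or 'rgb'")
  if (object@smoothSigma < 0) return("smoothSigma must be >= 0")
  TRUE
})

#' Construct SLIC parameters
#'
#' @param K requested number of superpixels.
#' @param m compactness weight (default 10, on the CIELAB scale).
#' @param nIters assign/update iterations (default 10; iteration exits early
#'   once no label changes).
#' @param perturbWindow odd gradient-search window side (default 3).
#' @param enforceConnectivity merge orphan fragments (default TRUE).
#' @param colorSpace "lab" (default) or "rgb".
#' @param smoothSigma Gaussian pre-smoothing in pixels (default 1; 0
#'   disables).
#' @return A \linkS4class{SlicParams}.
#' @export
slicParams <- function(K, m = 10, nIters = 10L, perturbWindow = 3L,
                       enforceConnectivity = TRUE, colorSpace = "lab",
                       smoothSigma = 1) {
  new("SlicParams", K = as.integer(K), m = as.numeric(m),
      nIters = as.integer(nIters), perturbWindow = as.integer(perturbWindow),
      enforceConnectivity = enforceConnectivity, colorSpace = colorSpace,
      smoothSigma = as.numeric(smoothSigma))
}

#' Superpixel labeling
#'
#' A partition of an image into spatially coherent blocks: every pixel
#' carries exactly one block id, ids are consecutive integers 1..nBlocks
#' (the 1-based translation of the 0-based block ids used elsewhere).
#'
#' @slot labels integer matrix, H x W, values in 1..nBlocks.
#' @slot nBlocks realized number of blocks (may differ from the requested K).
#' @slot params the \linkS4class{SlicParams} that produced the labeling (or
#'   NULL for labelings built directly in tests).
#' @export
setClass("SuperpixelLabeling",
         representation(labels = "matrix", nBlocks = "integer", params = "ANY"))

setValidity("SuperpixelLabeling", function(object) {
  lab <- object@labels
  if (anyNA(lab)) return("labels must not contain NA")
  u <- sort(unique(as.integer(lab)))
  if (!identical(u, seq_len(object@nBlocks)))
    return("labels must be exactly the consecutive integers 1..nBlocks")
  TRUE
})

#' Construct a SuperpixelLabeling
#'
#' @param labels integer matrix with consecutive block ids starting at 1.
#' @param params optional \linkS4class{SlicParams} provenance.
#' @return A \linkS4class{SuperpixelLabeling}.
#' @export
superpixelLabeling <- function(labels, params = NULL) {
  storage.mode(labels) <- "integer"
  new("SuperpixelLabeling", labels = labels,
      nBlocks = max(labels), params = params)
}

#' @describeIn superpixelLabeling label matrix accessor
#' @param x a \code{SuperpixelLabeling}
#' @export
spLabels <- function(x) x@labels

#' @describeIn superpixelLabeling realized block count
#' @export
nBlocks <- function(x) x@nBlocks

setMethod("show", "SuperpixelLabeling", function(object) {
  cat(sprintf("SuperpixelLabeling: %d blocks over %d x %d pixels\n",
              object@nBlocks, nrow(object@labels), ncol(object@labels)))
})

## Refinement ---------------------------------------------------------------

#' Superpixel refinement parameters
#'
#' Controls stage two of SpurNet: each superpixel block whose tongue-pixel
#' coverage exceeds \code{theta} survives; all other blocks are cleared to
#' background.
#'
#' @slot theta coverage threshold in \code{[0, 1]}; a block survives only if
#'   its coverage is strictly greater than theta.
#' @slot mode \code{"retain"} keeps the coarse labels inside surviving blocks
#'   (never adds tongue pixels); \code{"fill"} sets surviving blocks entirely
#'   to tongue (can repair under-segmentation).
#' @slot slicParams the \linkS4class{SlicParams} used to build the blocks.
#' @export
setClass("RefineParams",
         representation(theta = "numeric", mode = "character",
                        slicParams = "SlicParams"))

setValidity("RefineParams", function(object) {
  if (object@theta < 0 || object@theta > 1) return("theta must lie in [0, 1]")
  if (!object@mode %in% c("retain", "fill"))
    return("mode must be 'retain' or 'fill'")
  TRUE
})

#' Construct refinement parameters
#'
#' @param theta coverage threshold in \code{[0, 1]} (default 0.5).
#' @param mode "retain" (default) or "fill".
#' @param slicParams \linkS4class{SlicParams} for the superpixel stage.
#' @return A \linkS4class{RefineParams}.
#' @export
refineParams <- function(theta = 0.5, mode = "retain",
                         slicParams = SpurNet::slicParams(K = 200L)) {
  new("RefineParams", theta = as.numeric(theta), mode = mode,
      slicParams = slicParams)
}

## Metrics ------------------------------------------------------------------

#' Pixelwise confusion counts
#'
#' Tallies of the four prediction/truth outcomes over all pixels: TP
#' (predicted tongue, truly tongue), FP (predicted tongue, truly background),
#' FN (predicted background, truly tongue), TN (both background).
#'
#' @slot TP,FP,FN,TN non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
         representation(TP = "numeric", FP = "numeric", FN = "numeric",
                        TN = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(v < 0)) return("counts must be non-negative")
  if (any(v != floor(v))) return("counts must be whole numbers")
  TRUE
})

#' Construct confusion counts directly
#'
#' @param TP,FP,FN,TN non-negative pixel tallies.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCountsFromTallies <- function(TP, FP, FN, TN) {
  new("ConfusionCounts", TP = as.numeric(TP), FP = as.numeric(FP),
      FN = as.numeric(FN), TN = as.numeric(TN))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g (total %g)\n",
              object@TP, object@FP, object@FN, object@TN,
              object@TP + object@FP + object@FN + object@TN))
})

#' Segmentation metrics report
#'
#' The four summary metrics for one predicted mask (or a fold aggregate):
#' pixel accuracy (PA), mean per-class accuracy (MPA), mean
#' intersection-over-union (MIoU) and frequency-weighted IoU (FWIoU), all
#' fractions in \code{[0, 1]}.
#'
#' @slot PA,MPA,MIoU,FWIoU metric values.
#' @slot formulaMode \code{"paper"} (printed-formula fidelity: precision-style
#'   MPA, tongue-term-only FWIoU) or \code{"standard"} (conventional
#'   recall-based MPA and both-class FWIoU).
#' @export
setClass("MetricsReport",
         representation(PA = "numeric", MPA = "numeric", MIoU = "numeric",
                        FWIoU = "numeric", formulaMode = "character"))

setValidity("MetricsReport", function(object) {
  v <- c(object@PA, object@MPA, object@MIoU, object@FWIoU)
  if (any(!is.na(v) & (v < -1e-12 | v > 1 + 1e-12)))
    return("metrics must lie in [0, 1]")
  if (!object@formulaMode %in% c("paper", "standard"))
    return("formulaMode must be 'paper' or 'standard'")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s mode): PA=%.4f MPA=%.4f MIoU=%.4f FWIoU=%.4f\n",
              object@formulaMode, object@PA, object@MPA, object@MIoU,
              object@FWIoU))
})

#' Convert a MetricsReport to a one-row data.frame
#' @param report a \linkS4class{MetricsReport}
#' @return data.frame with columns PA, MPA, MIoU, FWIoU.
#' @export
metricsAsDataFrame <- function(report) {
  data.frame(PA = report@PA, MPA = report@MPA, MIoU = report@MIoU,
             FWIoU = report@FWIoU)
}

#' Cross-validation result
#'
#' @slot folds list of per-fold results; each element holds the fold's test
#'   indices and its coarse (and, when refinement parameters were supplied,
#'   refined) \linkS4class{MetricsReport}.
#' @slot summary data.frame of mean and sample (n-1) standard deviation per
#'   metric and stage.
#' @slot k number of folds.
#' @slot seed RNG seed used for the fold assignment.
#' @export
setClass("CvResult",
         representation(folds = "list", summary = "data.frame",
                        k = "integer", seed = "integer"))

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %d-fold cross-validation (seed %d)\n",
              object@k, object@seed))
  print(object@summary, row.names = FALSE)
})

#' @describeIn kfoldCv summary table accessor (mean +/- sd per metric)
#' @param x a \code{CvResult}
#' @export
cvSummary <- function(x) x@summary
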