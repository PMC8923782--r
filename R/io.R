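## Image, mask, annotation and checkpoint I/O -------------------------------

#' Read an RGB image from a PNG or JPEG file
#'
#' Grayscale inputs are replicated to three channels; an alpha channel, if
#' present, is dropped. Values are returned on the raw 8-bit scale.
#'
#' @param path file path to a PNG or JPEG image.
#' @return An \linkS4class{RgbImage} with \code{valueRange = "raw8bit"}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(48), c(4, 4, 3)), f)
#' img <- readRgbImage(f)
#' @export
readRgbImage <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("jpg", "jpeg")) {
    e <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode JPEG image '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    d <- EBImage::imageData(e)
    if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 1L))
    aperm(d, c(2, 1, 3))  # EBImage stores x (width) first
  } else {
    tryCatch(png::readPNG(path),
             error = function(e) stop("cannot decode PNG image '", path,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
  else px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  rgbImage(round(px * 255), valueRange = "raw8bit")
}

#' Write / read a binary segmentation mask as single-channel PNG
#'
#' The storage convention writes the raw label values \{0, 1\}; with
#' \code{visual = TRUE} labels are scaled to \{0, 255\} for direct viewing.
#' \code{readMask} recognizes both variants.
#'
#' @param mask integer matrix with values in \{0, 1\}.
#' @param path output (input) file path.
#' @param visual scale labels to \{0, 255\} on write.
#' @return \code{writeMask} returns the path invisibly; \code{readMask}
#'   returns an integer \{0, 1\} matrix.
#' @export
writeMask <- function(mask, path, visual = FALSE) {
  assertMask(mask)
  scale <- if (visual) 1 else 255
  ok <- tryCatch({png::writePNG(mask / scale, path); TRUE},
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write mask to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v <- round(v * 255)
  m <- if (max(v) > 1) (v >= 128) * 1L else v
  storage.mode(m) <- "integer"
  assertMask(m, "decoded mask")
  m
}

#' Read a Labelme-style polygon annotation JSON file
#'
#' Accepts the common polygon-annotation dialect:
#' \code{\{"shapes": [\{"label": ..., "points": [[x, y], ...]\}],
#' "imageHeight": ..., "imageWidth": ...\}}. Vertices are clipped to the
#' image bounds.
#'
#' @param path path to the JSON file.
#' @return A \linkS4class{PolygonAnnotation}.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  h <- as.integer(j$imageHeight); w <- as.integer(j$imageWidth)
  shapes <- lapply(j$shapes, function(s) {
    p <- do.call(rbind, lapply(s$points, function(v) as.numeric(unlist(v))))
    if (is.null(p) || nrow(p) < 3L)
      stop("polygon '", s$label, "' has fewer than 3 vertices", call. = FALSE)
    p[, 1] <- clamp(p[, 1], 0, w - 1)
    p[, 2] <- clamp(p[, 2], 0, h - 1)
    list(label = s$label, points = p)
  })
  polygonAnnotation(shapes, imageHeight = h, imageWidth = w)
}

# Boundary-inclusive even-odd point-in-polygon, vectorized over query points.
# px, py: point coordinates; poly: n x 2 (x, y) vertex matrix.
pointsInPolygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    # on-segment test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onseg <- abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | onseg
    # even-odd ray crossing (ray toward +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | boundary
}

#' Rasterize a polygon annotation to a binary mask
#'
#' A pixel becomes tongue (1) when its center lies inside, or on the boundary
#' of, any polygon carrying \code{positiveLabel}; multiple polygons are
#' unioned. Pixel centers are at integer (x, y) coordinates, matching the
#' annotation's vertex convention. Category names other than
#' \code{positiveLabel} are ignored, so multi-class label files degrade
#' gracefully to binary tongue/background.
#'
#' @param ann a \linkS4class{PolygonAnnotation}.
#' @param positiveLabel category name rasterized as foreground
#'   (default "tongue").
#' @param allowEmpty allow an annotation with no matching polygon (returns an
#'   all-zero mask) instead of raising an error.
#' @return Integer \{0, 1\} matrix of size imageHeight x imageWidth.
#' @export
annotationToMask <- function(ann, positiveLabel = "tongue",
                             allowEmpty = FALSE) {
  stopifnot(is(ann, "PolygonAnnotation"))
  h <- ann@imageHeight; w <- ann@imageWidth
  polys <- Filter(function(s) s$label == positiveLabel, ann@shapes)
  if (length(polys) == 0L && !allowEmpty)
    stop("no polygon labeled '", positiveLabel,
         "' (set allowEmpty = TRUE to accept an empty mask)", call. = FALSE)
  mask <- matrix(0L, h, w)
  if (length(polys) > 0L) {
    px <- rep(0:(w - 1), each = h)   # column-major grid: x varies by column
    py <- rep(0:(h - 1), times = w)
    hit <- logical(h * w)
    for (s in polys)
      hit <- hit | pointsInPolygon(px, py, s$points)
    mask[hit] <- 1L
  }
  mask
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialization and round-trip to a bitwise
#' identical parameter set.
#'
#' @param model a \linkS4class{UrNetModel}.
#' @param path checkpoint file path.
#' @return \code{saveCheckpoint} returns the path invisibly;
#'   \code{loadCheckpoint} the restored \linkS4class{UrNetModel}.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "UrNetModel"))
  ok <- tryCatch({
    saveRDS(list(format = "spurnet-checkpoint-1", config = model@config,
                 params = model@params, state = model@state,
                 arch = model@arch, trained = model@trained), path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write checkpoint to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!identical(x$format, "spurnet-checkpoint-1"))
    stop("not a SpurNet checkpoint: ", path, call. = FALSE)
  new("UrNetModel", config = x$config, params = x$params, state = x$state,
      arch = x$arch, trained = x$trained)
}
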