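## Internal helpers ---------------------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Masks are plain integer matrices with values in {0, 1}.
assertMask <- function(mask, what = "mask") {
  if (!is.matrix(mask))
    stop(what, " must be a matrix", call. = FALSE)
  if (anyNA(mask) || !all(mask == 0L | mask == 1L))
    stop(what, " labels must all be 0 or 1", call. = FALSE)
  invisible(mask)
}

assertSameShape <- function(a, b, whatA = "first", whatB = "second") {
  da <- if (is.matrix(a)) dim(a) else dim(a)[1:2]
  db <- if (is.matrix(b)) dim(b) else dim(b)[1:2]
  if (!identical(da, db))
    stop(whatA, " (", paste(da, collapse = "x"), ") and ", whatB, " (",
         paste(db, collapse = "x"), ") must share the same height and width",
         call. = FALSE)
  invisible(TRUE)
}

# Per-pixel color features for SLIC: rows indexed (r-1)*W + c (row-major),
# columns the 3 channels of the chosen space. Input is a raw 8-bit RgbImage.
pixelFeatures <- function(img, colorSpace = "lab") {
  px <- imgData(img)
  if (valueRange(img) == "normalized")
    px <- (px + 1) * 127.5
  h <- dim(px)[1]; w <- dim(px)[2]
  # row-major flattening: transpose each channel
  rgb <- cbind(as.vector(t(px[, , 1])), as.vector(t(px[, , 2])),
               as.vector(t(px[, , 3]))) / 255
  if (colorSpace == "rgb") {
    feats <- rgb * 100  # comparable numeric scale to Lab
  } else {
    feats <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  }
  attr(feats, "H") <- h
  attr(feats, "W") <- w
  feats
}

# Polynomial rolling hash (mod 2^48, exact in double precision) of an
# arbitrary R object, as hex; used to fingerprint configs in run artifacts
# without an external digest dependency.
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  # modulus 2^40 keeps every intermediate product exact in double precision
  for (b in bytes) h <- (h * 257 + b + 1) %% 1099511627776
  paste0(sprintf("%05x", h %/% 1048576), sprintf("%05x", h %% 1048576))
}

# Derive a stream of well-separated 31-bit seeds from one master seed.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
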