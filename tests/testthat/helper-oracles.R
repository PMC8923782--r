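# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# Even-odd point-in-polygon with boundary inclusion, one point at a time.
oraclePointInPolygon <- function(x, y, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    if (abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &&
        x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
        y >= min(y1, y2) - eps && y <= max(y1, y2) + eps)
      return(TRUE)
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracleRasterize <- function(poly, h, w) {
  m <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w))
    if (oraclePointInPolygon(c - 1, r - 1, poly)) m[r, c] <- 1L
  m
}

# Loop-based confusion tallies and metric formulas.
oracleConfusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

oraclePaperMetrics <- function(tp, fp, fn, tn) {
  tot <- tp + fp + fn + tn
  c(PA = (tp + tn) / tot,
    MPA = (tp / (tp + fp) + tn / (tn + fn)) / 2,
    MIoU = (tp / (tp + fp + fn) + tn / (tn + fn + fp)) / 2,
    FWIoU = ((tp + fn) / tot) * tp / (tp + fp + fn))
}

# Brute-force nearest-seed assignment over all seeds (no search windows).
oracleAssignAllSeeds <- function(feats, seeds, S, m) {
  H <- attr(feats, "H"); W <- attr(feats, "W")
  label <- integer(H * W)
  for (p in seq_len(H * W)) {
    pr <- (p - 1) %/% W; pc <- (p - 1) %% W
    bestD <- Inf; bestI <- 0L
    for (i in seq_len(nrow(seeds))) {
      dc2 <- sum((feats[p, ] - c(seeds$f1[i], seeds$f2[i], seeds$f3[i]))^2)
      ds2 <- (pr - seeds$row[i])^2 + (pc - seeds$col[i])^2
      D <- dc2 / m^2 + ds2 / S^2
      if (D < bestD) { bestD <- D; bestI <- i }
    }
    label[p] <- bestI
  }
  label
}

# Coverage of the 2S-halfwidth search windows: TRUE when every pixel lies in
# at least one seed's window.
windowsCoverImage <- function(seeds, S, H, W) {
  covered <- matrix(FALSE, H, W)
  half <- ceiling(S)
  for (i in seq_len(nrow(seeds))) {
    rs <- max(0, ceiling(seeds$row[i] - half)):min(H - 1, floor(seeds$row[i] + half))
    cs <- max(0, ceiling(seeds$col[i] - half)):min(W - 1, floor(seeds$col[i] + half))
    covered[rs + 1, cs + 1] <- TRUE
  }
  all(covered)
}

makeNormalizedPairs <- function(n, side, seed) {
  scenes <- generateDataset(n, sceneSpec(side = side), seed = seed)
  lapply(scenes, function(s) list(img = normalizeImage(s$img), mask = s$mask))
}

randomMask <- function(h, w, p = 0.5) {
  m <- matrix(rbinom(h * w, 1L, p), h, w)
  storage.mode(m) <- "integer"
  m
}
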