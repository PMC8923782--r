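## Confusion counts, segmentation metrics, sweep, cross-validation ----------

#' Pixelwise confusion counts between prediction and truth
#'
#' @param pred,truth \{0, 1\} integer matrices of the same height/width;
#'   label 1 is tongue.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' confusionCounts(matrix(1L, 4, 4), matrix(1L, 4, 4))  # TP = 16
#' @export
confusionCounts <- function(pred, truth) {
  assertMask(pred, "prediction")
  assertMask(truth, "truth")
  assertSameShape(pred, truth, "prediction", "truth")
  p <- pred == 1L; t <- truth == 1L
  confusionCountsFromTallies(sum(p & t), sum(p & !t), sum(!p & t),
                             sum(!p & !t))
}

# A 0/0 per-class term (class absent in both prediction and truth) is
# dropped from the average; if every term is undefined the metric is NA.
.meanDefined <- function(terms) {
  ok <- !is.nan(terms) & !is.na(terms)
  if (!any(ok)) return(NA_real_)
  mean(terms[ok])
}

#' Segmentation metrics from confusion counts
#'
#' Computes PA, MPA, MIoU and FWIoU. The default \code{"paper"} mode
#' reproduces the printed two-class formulas of the study this package
#' implements verbatim: MPA averages the per-class precisions
#' \code{TP/(TP+FP)} and \code{TN/(TN+FN)}, and FWIoU contains only the
#' tongue-class term \code{((TP+FN)/total) * TP/(TP+FP+FN)}. The
#' \code{"standard"} mode gives the conventional definitions: recall-based
#' MPA and the frequency-weighted sum of both class IoUs. PA and MIoU agree
#' between modes. Per-class 0/0 terms (class absent in both prediction and
#' truth) are dropped from averages.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @param formulaMode \code{"paper"} (default) or \code{"standard"}.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' m <- segMetrics(confusionCountsFromTallies(1, 0, 1, 2))
#' m  # PA 0.75, MPA 5/6, MIoU 7/12, FWIoU 0.25
#' @export
segMetrics <- function(counts, formulaMode = c("paper", "standard")) {
  stopifnot(is(counts, "ConfusionCounts"))
  formulaMode <- match.arg(formulaMode)
  TP <- counts@TP; FP <- counts@FP; FN <- counts@FN; TN <- counts@TN
  tot <- TP + FP + FN + TN
  PA <- (TP + TN) / tot
  iouT <- TP / (TP + FP + FN)
  iouB <- TN / (TN + FN + FP)
  MIoU <- .meanDefined(c(iouT, iouB))
  if (formulaMode == "paper") {
    MPA <- .meanDefined(c(TP / (TP + FP), TN / (TN + FN)))
    FWIoU <- ((TP + FN) / tot) * iouT
    if (is.nan(FWIoU)) FWIoU <- if (TP + FN == 0) 0 else NA_real_
  } else {
    MPA <- .meanDefined(c(TP / (TP + FN), TN / (TN + FP)))
    fT <- (TP + FN) / tot; fB <- (TN + FP) / tot
    termT <- if (fT > 0) fT * iouT else 0
    termB <- if (fB > 0) fB * iouB else 0
    FWIoU <- termT + termB
  }
  new("MetricsReport", PA = PA, MPA = MPA, MIoU = MIoU, FWIoU = FWIoU,
      formulaMode = formulaMode)
}

#' Metrics of one predicted mask against its ground truth
#'
#' Convenience composition of \code{\link{confusionCounts}} and
#' \code{\link{segMetrics}}.
#'
#' @param pred,truth \{0, 1\} integer matrices.
#' @param formulaMode "paper" or "standard".
#' @return A \linkS4class{MetricsReport}.
#' @export
maskMetrics <- function(pred, truth, formulaMode = "paper") {
  segMetrics(confusionCounts(pred, truth), formulaMode)
}

#' Sweep the superpixel seed count and coverage threshold
#'
#' For every (K, theta) pair, superpixels are computed per scene at that K,
#' the coarse mask is refined at that theta, and the MIoU against truth is
#' averaged over scenes. Superpixels are computed once per (scene, K) and
#' shared across thetas. Ties for the best cell go to the smaller K, then
#' the smaller theta.
#'
#' @param scenes list of \code{list(img = , coarse = , truth = )} entries.
#' @param kGrid integer vector of seed counts.
#' @param thetaGrid numeric vector of coverage thresholds.
#' @param m SLIC compactness (default 10).
#' @param mode refinement mode, "retain" (default) or "fill".
#' @param formulaMode metrics mode (default "paper"; MIoU is identical in
#'   both).
#' @return list with \code{surface} (data.frame K, theta, meanMIoU) and
#'   \code{best} (row of the argmax cell).
#' @export
sweepParams <- function(scenes, kGrid, thetaGrid, m = 10, mode = "retain",
                        formulaMode = "paper") {
  stopifnot(length(scenes) >= 1L, length(kGrid) >= 1L,
            length(thetaGrid) >= 1L)
  kGrid <- sort(unique(as.integer(kGrid)))
  thetaGrid <- sort(unique(as.numeric(thetaGrid)))
  rows <- list()
  for (K in kGrid) {
    sps <- lapply(scenes, function(sc)
      slicSuperpixels(sc$img, slicParams(K = K, m = m)))
    for (theta in thetaGrid) {
      rp <- refineParams(theta = theta, mode = mode,
                         slicParams = slicParams(K = K, m = m))
      mious <- vapply(seq_along(scenes), function(i) {
        ref <- refineMask(scenes[[i]]$coarse, sps[[i]], rp)
        maskMetrics(ref, scenes[[i]]$truth, formulaMode)@MIoU
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(K = K, theta = theta, meanMIoU = mean(mious))
    }
  }
  surface <- do.call(rbind, rows)
  # argmax with ties to smaller K then smaller theta: surface is already
  # ordered by (K, theta), so the first maximum wins
  best <- surface[which.max(surface$meanMIoU), , drop = FALSE]
  rownames(best) <- NULL
  list(surface = surface, best = best)
}

#' k-fold cross-validation of a segmentation pipeline
#'
#' Partitions the dataset into k near-equal folds from the given seed (fold
#' sizes differ by at most 1). For each fold a predictor is fit on the
#' remaining data via \code{trainer} and evaluated on the held-out fold:
#' coarse metrics always, refined metrics additionally when
#' \code{refineParams} is supplied. Fold metrics are aggregated as mean and
#' sample (n-1) standard deviation.
#'
#' @param dataset list of \code{list(img = , mask = )} pairs (size >= k).
#' @param k number of folds (default 10).
#' @param trainer function(trainPairs) returning a predictor
#'   function(img) -> \{0, 1\} mask. Wrap \code{\link{trainUrNet}} here, or
#'   pass a stub for harness tests.
#' @param refineParams optional \linkS4class{RefineParams} to also score the
#'   superpixel-refined masks.
#' @param seed fold-assignment seed.
#' @param formulaMode metrics mode (default "paper").
#' @return A \linkS4class{CvResult}.
#' @export
kfoldCv <- function(dataset, k = 10L, trainer, refineParams = NULL,
                    seed = 1L, formulaMode = "paper") {
  n <- length(dataset)
  if (n < k) stop("dataset must contain at least k items", call. = FALSE)
  set.seed(seed)
  assign_ <- rep_len(seq_len(k), n)[sample.int(n)]
  folds <- list()
  for (fold in seq_len(k)) {
    testIdx <- which(assign_ == fold)
    predictor <- trainer(dataset[-testIdx])
    evalOne <- function(refine) {
      reps <- lapply(testIdx, function(i) {
        pred <- predictor(dataset[[i]]$img)
        if (refine) {
          sp <- slicSuperpixels(dataset[[i]]$img, refineParams@slicParams)
          pred <- refineMask(pred, sp, refineParams)
        }
        confusionCounts(pred, dataset[[i]]$mask)
      })
      # pool pixels across the fold's images
      cc <- confusionCountsFromTallies(
        sum(vapply(reps, function(x) x@TP, 1)),
        sum(vapply(reps, function(x) x@FP, 1)),
        sum(vapply(reps, function(x) x@FN, 1)),
        sum(vapply(reps, function(x) x@TN, 1)))
      segMetrics(cc, formulaMode)
    }
    res <- list(testIdx = testIdx, coarse = evalOne(FALSE))
    if (!is.null(refineParams)) res$refined <- evalOne(TRUE)
    folds[[fold]] <- res
  }
  stages <- c("coarse", if (!is.null(refineParams)) "refined")
  summ <- do.call(rbind, lapply(stages, function(st) {
    df <- do.call(rbind, lapply(folds, function(f) metricsAsDataFrame(f[[st]])))
    data.frame(stage = st, metric = names(df),
               mean = vapply(df, mean, 1),
               sd = vapply(df, function(v) if (length(v) > 1) sd(v) else 0, 1),
               row.names = NULL)
  }))
  new("CvResult", folds = folds, summary = summ, k = as.integer(k),
      seed = as.integer(seed))
}

#' Format a CvResult as a "mean +/- sd" Markdown table
#'
#' One row per stage, one column per metric, formatted like the result
#' tables of segmentation papers.
#'
#' @param cv a \linkS4class{CvResult}.
#' @param digits digits after the decimal point (default 4).
#' @return Character vector of Markdown lines.
#' @export
cvMarkdownTable <- function(cv, digits = 4L) {
  s <- cv@summary
  metrics <- unique(s$metric)
  lines <- c(paste0("| Stage | ", paste(metrics, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(metrics) + 1L),
                               collapse = "|"), "|"))
  for (st in unique(s$stage)) {
    cells <- vapply(metrics, function(m) {
      r <- s[s$stage == st & s$metric == m, ]
      sprintf(paste0("%.", digits, "f ± %.", digits, "f"), r$mean, r$sd)
    }, character(1))
    lines <- c(lines, paste0("| ", st, " | ", paste(cells, collapse = " | "),
                             " |"))
  }
  lines
}
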