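test_that("confusion counts enumerate the four outcomes", {
  ones <- matrix(1L, 4, 4)
  cc <- confusionCounts(ones, ones)
  expect_equal(c(cc@TP, cc@FP, cc@FN, cc@TN), c(16, 0, 0, 0))

  truth <- matrix(c(1L, 0L, 1L, 0L), 2, 2)  # [[1,1],[0,0]] row-major
  pred <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  cc2 <- confusionCounts(pred, truth)
  expect_equal(c(cc2@TP, cc2@FP, cc2@FN, cc2@TN), c(1, 0, 1, 2))

  # complement prediction swaps everything off the diagonal
  set.seed(51)
  t3 <- randomMask(6, 6, 0.4)
  cc3 <- confusionCounts(1L - t3, t3)
  expect_equal(cc3@TP, 0); expect_equal(cc3@TN, 0)
  expect_equal(cc3@FP, sum(t3 == 0L)); expect_equal(cc3@FN, sum(t3 == 1L))

  expect_error(confusionCounts(matrix(1L, 2, 2), matrix(1L, 3, 3)),
               "same height")
  expect_error(confusionCounts(matrix(2L, 2, 2), matrix(1L, 2, 2)), "0 or 1")
})

test_that("the hand-worked metric example evaluates exactly", {
  m <- segMetrics(confusionCountsFromTallies(1, 0, 1, 2))
  expect_equal(m@PA, 0.75)
  expect_equal(m@MPA, 5 / 6)
  expect_equal(m@MIoU, 7 / 12)
  expect_equal(m@FWIoU, 0.25)
  expect_equal(m@formulaMode, "paper")
})

test_that("perfect prediction saturates the metrics in both modes", {
  set.seed(52)
  truth <- randomMask(10, 10, 0.3)
  cc <- confusionCounts(truth, truth)
  paper <- segMetrics(cc, "paper")
  std <- segMetrics(cc, "standard")
  expect_equal(paper@PA, 1); expect_equal(std@PA, 1)
  expect_equal(paper@MPA, 1); expect_equal(std@MPA, 1)
  expect_equal(paper@MIoU, 1); expect_equal(std@MIoU, 1)
  # printed FWIoU has only the tongue term: frequency x 1
  expect_equal(paper@FWIoU, mean(truth))
  expect_equal(std@FWIoU, 1)
})

test_that("metrics match the loop-based oracle on random masks", {
  set.seed(53)
  for (i in 1:200) {
    pred <- randomMask(8, 8, runif(1, 0.1, 0.9))
    truth <- randomMask(8, 8, runif(1, 0.1, 0.9))
    oc <- oracleConfusion(as.vector(pred), as.vector(truth))
    cc <- confusionCounts(pred, truth)
    expect_equal(c(cc@TP, cc@FP, cc@FN, cc@TN), unname(oc))
    om <- oraclePaperMetrics(oc["TP"], oc["FP"], oc["FN"], oc["TN"])
    m <- segMetrics(cc)
    expect_equal(c(m@PA, m@MPA, m@MIoU, m@FWIoU), unname(om),
                 tolerance = 1e-12)
    expect_gte(m@PA, m@MIoU)  # arithmetic mean dominates IoU
  }
})

test_that("metrics are scale-invariant in the counts", {
  cc1 <- confusionCountsFromTallies(5, 3, 2, 10)
  cc7 <- confusionCountsFromTallies(35, 21, 14, 70)
  for (mode in c("paper", "standard")) {
    a <- segMetrics(cc1, mode); b <- segMetrics(cc7, mode)
    expect_equal(metricsAsDataFrame(a), metricsAsDataFrame(b))
  }
})

test_that("degenerate all-background masks follow the empty-class policy", {
  z <- matrix(0L, 4, 4)
  m <- segMetrics(confusionCounts(z, z))
  expect_equal(m@PA, 1)
  expect_equal(m@MPA, 1)   # tongue term 0/0 dropped
  expect_equal(m@MIoU, 1)
  expect_equal(m@FWIoU, 0) # no tongue pixels: zero tongue frequency
})

test_that("cross-validation folds are balanced, disjoint and reproducible", {
  # 367 one-pixel items exercise the fold assignment at the study's size
  dataset <- replicate(367, list(img = NULL, mask = matrix(1L, 1, 1)),
                       simplify = FALSE)
  stub <- function(trainPairs) function(img) matrix(1L, 1, 1)
  cv <- kfoldCv(dataset, k = 10, trainer = stub, seed = 9)
  sizes <- vapply(cv@folds, function(f) length(f$testIdx), 1L)
  expect_setequal(unique(sizes), c(36L, 37L))
  expect_equal(sum(sizes), 367)
  allIdx <- unlist(lapply(cv@folds, `[[`, "testIdx"))
  expect_equal(sort(allIdx), 1:367)  # disjoint cover
  cv2 <- kfoldCv(dataset, k = 10, trainer = stub, seed = 9)
  expect_identical(lapply(cv2@folds, `[[`, "testIdx"),
                   lapply(cv@folds, `[[`, "testIdx"))
  expect_error(kfoldCv(dataset[1:5], k = 10, trainer = stub), "at least k")
})

test_that("a ground-truth stub gives all-one metrics with zero spread", {
  # the stub recovers the exact mask from the noiseless tongue color
  stub <- function(trainPairs) {
    function(img) {
      px <- imgData(img)
      m <- (px[, , 1] == 185 & px[, , 2] == 92 & px[, , 3] == 96) * 1L
      storage.mode(m) <- "integer"
      m
    }
  }
  noiseless <- generateDataset(4, sceneSpec(side = 32, textureNoiseSd = 0),
                               seed = 55)
  dataset <- lapply(noiseless, function(s) list(img = s$img, mask = s$mask))
  p <- stub(NULL)
  expect_true(all(vapply(dataset,
                         function(d) identical(p(d$img), d$mask), TRUE)))
  # standard mode: perfect prediction saturates all four metrics
  cv <- kfoldCv(dataset, k = 2, trainer = stub, seed = 3,
                formulaMode = "standard")
  expect_true(all(cv@summary$mean == 1))
  expect_true(all(cv@summary$sd == 0))
  # paper mode: PA/MPA/MIoU saturate; the printed FWIoU equals the
  # tongue-class frequency by construction, so it stays below 1
  cvp <- kfoldCv(dataset, k = 2, trainer = stub, seed = 3)
  sat <- cvp@summary[cvp@summary$metric %in% c("PA", "MPA", "MIoU"), ]
  expect_true(all(sat$mean == 1))
  expect_true(all(sat$sd == 0))
  fw <- cvp@summary[cvp@summary$metric == "FWIoU", ]
  expect_lt(fw$mean, 1)
})

test_that("fold aggregation reports mean and sample standard deviation", {
  # two folds engineered to score PA 0.8 and 0.9: truth all ones, the
  # predictor reads the prediction out of the image's red channel
  mkItem <- function(nWrong) {
    px <- array(0, c(2, 5, 3))
    pred <- matrix(1L, 2, 5); pred[seq_len(nWrong)] <- 0L
    px[, , 1] <- pred * 255
    list(img = rgbImage(px), mask = matrix(1L, 2, 5))
  }
  dataset <- list(mkItem(2), mkItem(1))  # PA 0.8 and 0.9
  stub <- function(trainPairs) function(img) {
    m <- (imgData(img)[, , 1] > 0) * 1L; storage.mode(m) <- "integer"; m
  }
  cv <- kfoldCv(dataset, k = 2, trainer = stub, seed = 1)
  pa <- cv@summary[cv@summary$metric == "PA", ]
  expect_equal(pa$mean, 0.85)
  expect_equal(pa$sd, sd(c(0.8, 0.9)))  # sample (n-1) convention, ~0.0707
  expect_equal(round(pa$sd, 4), 0.0707)
})

test_that("the parameter sweep scores the grid and breaks ties low", {
  # label-pure scene: left color half is the truth and the coarse mask
  px <- array(30, c(32, 32, 3)); px[, 1:16, 1] <- 220
  truth <- matrix(0L, 32, 32); truth[, 1:16] <- 1L
  scenes <- list(list(img = rgbImage(px), coarse = truth, truth = truth))
  sw <- sweepParams(scenes, kGrid = 4, thetaGrid = c(0.1, 0.5, 0.9), m = 1)
  expect_equal(nrow(sw$surface), 3)
  expect_true(all(sw$surface$meanMIoU == 1))  # conservative refinement
  expect_equal(sw$best$theta, 0.1)            # tie -> smallest theta
  sw1 <- sweepParams(scenes, kGrid = 4, thetaGrid = 0.5)
  expect_equal(nrow(sw1$surface), 1)
  expect_equal(sw1$best$K, 4)
})

test_that("cross-validation summaries format as a Markdown table", {
  dataset <- replicate(4, list(img = NULL, mask = matrix(1L, 2, 2)),
                       simplify = FALSE)
  stub <- function(trainPairs) function(img) matrix(1L, 2, 2)
  cv <- kfoldCv(dataset, k = 2, trainer = stub, seed = 1)
  md <- cvMarkdownTable(cv)
  expect_true(grepl("^\\| Stage \\| PA", md[1]))
  expect_true(any(grepl("1.0000 ± 0.0000", md, fixed = TRUE)))
})
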