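tinyCfg <- function(side = 16L, dropout = 0)
  urNetConfig(inputSide = side, widthMultiplier = 1 / 16,
              blocksPerStage = 1L, dropoutRate = dropout)

test_that("the network maps images to per-pixel class scores of the right shape", {
  set.seed(10)
  cfg <- tinyCfg(32L)
  model <- buildUrNet(cfg)
  img <- rgbImage(array(0, c(32, 32, 3)), "normalized")
  X <- SpurNet:::imagesToTensor(list(img))
  fw <- SpurNet:::urnetForward(cfg, model@params, model@state, X, FALSE)
  expect_equal(dim(fw$logits$x), c(32 * 32, 2))
  expect_true(all(is.finite(fw$logits$x)))  # well-posed on zero input
  expect_equal(fw$logits$H, 32L)
  expect_error(buildUrNet(urNetConfig(inputSide = 100)), "divisible")
})

test_that("the emitted architecture table accounts for every parameter", {
  set.seed(11)
  for (cfg in list(tinyCfg(), urNetConfig(inputSide = 32,
                                          widthMultiplier = 1 / 8))) {
    model <- buildUrNet(cfg)
    tab <- architectureTable(model)
    expect_equal(sum(tab$n_params), sum(vapply(model@params, length, 1L)))
    # spatial bookkeeping: only stride-2 layers shrink, upsampling doubles,
    # and the head emits at full input resolution
    expect_equal(tab$out_side[nrow(tab)], cfg@inputSide)
    convs <- tab[tab$type == "conv", ]
    expect_true(all(convs$n_params ==
                      convs$kernel^2 * convs$in_ch * convs$out_ch +
                      convs$out_ch))
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- tinyCfg()
  model <- buildUrNet(cfg)
  imgs <- lapply(1:2, function(i)
    rgbImage(array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3)), "normalized"))
  masks <- lapply(1:2, function(i) randomMask(16, 16, 0.3))
  X <- SpurNet:::imagesToTensor(imgs)
  y <- SpurNet:::masksToLabels(masks)
  fw <- SpurNet:::urnetForward(cfg, model@params, model@state, X, TRUE)
  ce <- SpurNet:::softmaxCrossEntropy(fw$logits$x, y)
  grads <- SpurNet:::urnetBackward(cfg, model@params, fw$caches, ce$dlogits)
  expect_setequal(names(grads), names(model@params))
  lossAt <- function(params) {
    f <- SpurNet:::urnetForward(cfg, params, model@state, X, TRUE)
    SpurNet:::softmaxCrossEntropy(f$logits$x, y)$loss
  }
  set.seed(7)
  for (nm in sample(names(model@params), 10)) {
    p <- model@params
    i <- sample(length(p[[nm]]), 1)
    eps <- 1e-6
    p[[nm]][i] <- p[[nm]][i] + eps; lp <- lossAt(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps; lm <- lossAt(p)
    expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("the learning-rate schedule follows inverse-time decay", {
  expect_equal(lrSchedule(1e-3, 1e-4, 0), 1e-3)
  expect_equal(lrSchedule(1e-3, 1e-4, 10000), 5e-4)
  expect_equal(lrSchedule(1e-3, 0, c(0, 5, 500)), rep(1e-3, 3))
  it <- 0:1000
  lrs <- lrSchedule(1e-3, 1e-4, it)
  expect_true(all(diff(lrs) < 0))          # strictly decreasing
  expect_true(all(lrs > 0 & lrs <= 1e-3))  # bounded in (0, lr0]
  expect_error(lrSchedule(1e-3, 1e-4, -1), ">= 0")
})

test_that("early stopping fires exactly at the patience horizon", {
  r <- stopEpochFromLosses(c(1.0, 0.9, rep(0.9, 10)), patience = 10)
  expect_equal(r$stopEpoch, 12)  # 10 epochs after the improvement at 2
  expect_equal(r$bestEpoch, 2)
  expect_equal(r$stopReason, "early_stop")

  # any improvement resets the counter
  r2 <- stopEpochFromLosses(c(1, rep(0.9, 9), 0.8, rep(0.8, 10)),
                            patience = 10)
  expect_equal(r2$bestEpoch, 11)
  expect_equal(r2$stopEpoch, 21)

  r3 <- stopEpochFromLosses(c(3, 2, 1), patience = 2)
  expect_equal(r3$stopReason, "max_epochs")
  expect_equal(r3$stopEpoch, 3)

  # equality is not an improvement (strict decrease)
  r4 <- stopEpochFromLosses(c(1, rep(1, 3)), patience = 3)
  expect_equal(r4$stopReason, "early_stop")
  expect_equal(r4$bestEpoch, 1)
})

test_that("training is seed-deterministic and its loss trend decreases", {
  pairs <- makeNormalizedPairs(4, 16, seed = 21)
  runOnce <- function() {
    set.seed(5)
    model <- buildUrNet(tinyCfg(dropout = 0.1))
    trainUrNet(model, pairs,
               tcfg = trainConfig(maxEpochs = 6L, batchSize = 2L, seed = 5L))
  }
  a <- runOnce(); b <- runOnce()
  expect_identical(a$history@history$loss, b$history@history$loss)
  expect_identical(a$model@params, b$model@params)
  # running minimum strictly decreases over the first epochs
  expect_lt(min(a$history@history$loss), a$history@history$loss[1])
  expect_s4_class(a$history, "TrainHistory")
  expect_error(trainUrNet(buildUrNet(tinyCfg()), list()), "nonempty")
})

test_that("mask prediction is the per-pixel argmax with ties to background", {
  set.seed(12)
  cfg <- tinyCfg()
  model <- buildUrNet(cfg)
  img <- rgbImage(array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3)),
                  "normalized")
  mask <- predictMask(model, img)
  # independent route: raw forward scores compared pixel by pixel
  fw <- SpurNet:::urnetForward(cfg, model@params, model@state,
                               SpurNet:::imagesToTensor(list(img)), FALSE)
  expected <- matrix(0L, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    p <- (r - 1) * 16 + c  # row-major pixel index
    s <- fw$logits$x[p, ]
    expected[r, c] <- if (s[2] > s[1]) 1L else 0L  # tie -> background
  }
  expect_identical(mask, expected)
  expect_error(predictMask(model, rgbImage(array(0, c(8, 8, 3)),
                                           "normalized")), "16")
  expect_error(predictMask(model, rgbImage(array(0, c(16, 16, 3)))),
               "normalized")
})
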