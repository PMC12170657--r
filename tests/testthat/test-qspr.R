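# Correlation, linear regression and the SVR tuning protocol.

# minimal index/property frames for synthetic correlation tests
synthFrames <- function(x, y) {
  idx <- data.frame(drug = paste0("M", seq_along(x)),
                    W = x, WW = x, H = x, D = x, DH = x)
  pr <- data.frame(drug = idx$drug, BP = y, E = y, FP = y, MR = y,
                   P = y, MV = y)
  list(indices = idx, props = pr)
}

test_that("pearsonMatrix returns exact coefficients and flags constants", {
  f <- synthFrames(1:10, 2 * (1:10) + 1)
  cm <- pearsonMatrix(f$indices, f$props)
  expect_equal(dim(cm), c(5, 6))
  expect_true(all(abs(cm - 1) < 1e-12))

  f2 <- synthFrames(rep(3, 10), rnorm(10))
  expect_error(pearsonMatrix(f2$indices, f2$props),
               class = "tcaQSPR_degenerate_error")
  f3 <- synthFrames(1:2, 1:2)
  expect_error(pearsonMatrix(f3$indices, f3$props),
               class = "tcaQSPR_config_error")
})

test_that("fitLR matches the closed-form metrics and recovers parameters", {
  x <- 1:20
  f <- fitLR(x, 2 * x)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0)
  expect_equal(f$slope, 2)

  # parameter recovery from a near-noiseless linear law
  set.seed(11)
  x <- runif(100, 0, 10)
  y <- 3 + 0.5 * x + rnorm(100, 0, 1e-6)
  f <- fitLR(x, y)
  expect_equal(f$intercept, 3, tolerance = 1e-3)
  expect_equal(f$slope, 0.5, tolerance = 1e-3)

  # RMSE treats actual and predicted symmetrically
  res <- y - (f$intercept + f$slope * x)
  expect_equal(f$rmse, sqrt(mean((-res)^2)))

  expect_error(fitLR(rep(1, 10), 1:10), class = "tcaQSPR_degenerate_error")
  expect_error(fitLR(1:2, 1:2), class = "tcaQSPR_config_error")
})

test_that("full-data LR R2 equals the squared Pearson correlation", {
  drugs <- fixtureDrugs()
  for (mode in c("heavy", "all-h")) {
    ref <- loadReferenceIndices(mode)[, 1:6]
    cm <- pearsonMatrix(ref, drugs)
    lr <- lrReport(ref, drugs)
    for (i in seq_len(nrow(lr)))
      expect_lt(abs(lr$r2[i] - cm[lr$index[i], lr$property[i]]^2), 1e-12)
  }
})

test_that("rbfKernel follows the closed form and is symmetric", {
  x <- c(1, 2, 3)
  expect_equal(rbfKernel(x, x, 0.5), 1)
  expect_equal(rbfKernel(0, 1, 1), exp(-1))
  set.seed(4)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(rbfKernel(a, b, 2.3), rbfKernel(b, a, 2.3))
  expect_lte(rbfKernel(a, b, 2.3), 1)
  expect_gt(rbfKernel(a, b, 2.3), 0)
  expect_error(rbfKernel(a, b, -1), class = "tcaQSPR_config_error")
})

test_that("featureScaling standardizes and round-trips", {
  tf <- featureScaling(c(1, 2, 3))
  expect_equal(mean(tf$scaled), 0)
  expect_equal(sd(tf$scaled), 1)
  x <- rnorm(50, 100, 17)
  tf <- featureScaling(x)
  expect_equal(invertScaling(tf, applyScaling(tf, x)), x, tolerance = 1e-12)
  expect_error(featureScaling(rep(2, 5)), class = "tcaQSPR_degenerate_error")
})

test_that("tuneSVR is deterministic, stays on the grid and records scaling", {
  x <- as.numeric(1:40)
  set.seed(2)
  y <- 100 + 3 * x + rnorm(40, 0, 5)
  spec <- svrSpec(seed = 7)
  r1 <- tuneSVR(x, y, spec)
  r2 <- tuneSVR(x, y, spec)
  keep <- c("cost", "epsilon", "gammaMode", "cvR2", "testR2", "testRMSE",
            "trainIndex", "testIndex")
  expect_identical(r1[keep], r2[keep])

  expect_true(r1$cost %in% c(10, 50, 100, 500))
  expect_true(any(abs(r1$epsilon - seq(0.1, 0.5, 0.1)) < 1e-12))
  expect_true(r1$gammaMode %in% c("scale", "auto"))
  expect_true(r1$scaledX && r1$scaledY)
  expect_equal(length(r1$trainIndex), 32)  # 80% of 40
  expect_equal(length(r1$testIndex), 8)

  rRaw <- tuneSVR(x, y, svrSpec(seed = 7, scaleX = FALSE, scaleY = FALSE))
  expect_false(rRaw$scaledX || rRaw$scaledY)

  expect_error(tuneSVR(1:5, 1:5), class = "tcaQSPR_config_error")
})

test_that("predictSVR inverts the stored transforms", {
  x <- as.numeric(1:50)
  y <- 10 + 2 * x
  r <- tuneSVR(x, y, svrSpec(seed = 1))
  p <- predictSVR(r, x)
  # predictions live on the original response scale
  expect_lt(max(abs(p - y)) / diff(range(y)), 0.1)
})

test_that("selectBestIndex takes the argmax with a lexicographic tie-break", {
  res <- data.frame(property = c("BP", "BP"), index = c("A", "B"),
                    r2 = c(0.3, 0.9))
  expect_equal(selectBestIndex(res)$index, "B")
  tie <- data.frame(property = c("BP", "BP"), index = c("WW", "D"),
                    r2 = c(0.5, 0.5))
  expect_equal(selectBestIndex(tie)$index, "D")
})
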