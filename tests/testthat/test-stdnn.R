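test_that("LDAM margins follow the inverse fourth-root law with rescaling", {
  expect_equal(ldamMargins(c(16, 256), C = 1, maxMargin = 0.5),
               c(0.5, 0.25), tolerance = 0)
  # equal counts collapse to the cap
  expect_equal(ldamMargins(c(50, 50)), c(0.5, 0.5), tolerance = 0)
  # ratio is (n1/n0)^(1/4) regardless of the cap
  m <- ldamMargins(c(20, 80))
  expect_equal(m[1] / m[2], (80 / 20)^0.25, tolerance = 1e-12)
  # the cap absorbs the scale C entirely
  expect_identical(ldamMargins(c(20, 80), C = 1), ldamMargins(c(20, 80), C = 2))
  # without the cap, margins are linear in C
  expect_equal(ldamMargins(c(20, 80), C = 2, maxMargin = NA),
               2 * ldamMargins(c(20, 80), C = 1, maxMargin = NA),
               tolerance = 1e-12)
  expect_error(ldamMargins(c(0, 10)), "counts")
  expect_error(ldamMargins(c(5, 10), C = 0), "C")
})

test_that("LDAM loss reduces to softmax cross-entropy and penalizes margins", {
  expect_equal(ldamLoss(c(0, 0), 1), log(2), tolerance = 1e-12)
  # a margin on the true class always increases the loss
  expect_gt(ldamLoss(c(0, 0), 1, margins = c(0, 0.3)), log(2))
  # with margins and scale, match an independent sigmoid-form evaluation:
  # loss = log(1 + exp(-s * (z_y - margin_y - z_other)))
  z <- c(1.3, -0.7); s <- 30; mar <- c(0.5, 0.25)
  indep <- log1p(exp(-s * (z[1] - mar[1] - z[2])))
  expect_equal(ldamLoss(z, 0, margins = mar, scale = s), indep,
               tolerance = 1e-12)
  # equivalence to plain cross-entropy over randomized logits
  set.seed(1)
  worst <- max(vapply(1:200, function(i) {
    z <- rnorm(2, sd = 3); y <- sample(0:1, 1)
    p <- exp(z) / sum(exp(z))
    abs(ldamLoss(z, y) - (-log(p[y + 1])))
  }, numeric(1)))
  expect_lt(worst, 1e-12)
  expect_error(ldamLoss(c(Inf, 0), 1), "finite")
})

test_that("the forward pass matches a hand-computed convolution oracle", {
  m <- handModel()
  # identity-tap kernels: conv1 of (1..6) -> (2,3,4,5); conv2 -> (3,4);
  # temporal average 3.5; head weights (1, 2) -> logits (3.5, 7)
  out <- forwardPass(m, matrix(1:6, 1), siteOnehot = 0)
  expect_equal(out$logits, c(3.5, 7), tolerance = 1e-6)
  expect_equal(out$prob1, 1 / (1 + exp(-3.5)), tolerance = 1e-12)
})

test_that("zero input with zero site vector propagates to indifferent logits", {
  co <- tinyCohort()
  # zero epochs: freshly initialized weights, all biases zero
  model <- trainStDNN(co, config = tinyModelConfig(epochs = 0L))
  out <- forwardPass(model, matrix(0, 8, 60), siteOnehot = numeric(2))
  expect_equal(out$logits, c(0, 0), tolerance = 1e-12)
  expect_equal(out$prob1, 0.5, tolerance = 1e-12)
})

test_that("the forward pass validates shapes and receptive-field length", {
  m <- smallTrainedNet()$model
  expect_error(forwardPass(m, matrix(0, 5, 60), numeric(2)), "regions")
  # receptive field with k = (21, 9), stride 1 is 29 timepoints
  expect_error(forwardPass(m, matrix(0, 8, 20), numeric(2)), "at least 29")
  expect_error(forwardPass(m, matrix(0, 8, 60), numeric(5)), "one-hot")
})

test_that("padded timepoints beyond the validity length do not change logits", {
  net <- smallTrainedNet()
  x <- getTimeseries(net$cohort, 1)
  ref <- forwardPass(net$model, x, numeric(2))
  padded <- cbind(x, matrix(99, nrow(x), 17))
  out <- forwardPass(net$model, padded, numeric(2), ntValid = ncol(x))
  expect_equal(out$logits, ref$logits, tolerance = 1e-12)
})

test_that("backpropagation agrees with numerical differentiation", {
  sf <- asNamespace("stFingerprint")
  cfg <- stdnnConfig(3L, convChannels = c(4L, 3L), kernelSizes = c(3L, 3L),
                     siteVocabSize = 2L, seed = 1L)
  set.seed(42)
  par <- sf$.initParams(cfg)
  X <- matrix(rnorm(36), 3, 12)
  site <- c(0, 1); y <- 1L; margins <- c(0.25, 0.5); s <- 30
  lossOf <- function(par, X) {
    fc <- sf$.forwardCore(par, X, site, cfg, keepCache = TRUE)
    sf$.ldamTerms(fc$logits, y, margins, s)$loss
  }
  fc <- sf$.forwardCore(par, X, site, cfg, keepCache = TRUE)
  lt <- sf$.ldamTerms(fc$logits, y, margins, s)
  g <- sf$.backwardCore(par, fc, lt$grad, cfg, wantInputGrad = TRUE)
  eps <- 1e-6
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(10, length(par[[nm]])))) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossOf(up, X) - lossOf(dn, X)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-5)
    }
  }
  for (i in sample(length(X), 10)) {
    up <- X; up[i] <- up[i] + eps
    dn <- X; dn[i] <- dn[i] - eps
    num <- (lossOf(par, up) - lossOf(par, dn)) / (2 * eps)
    expect_equal(g$X[i], num, tolerance = 1e-5)
  }
})

test_that("training is deterministic given the seed and learns planted signal", {
  co <- tinyCohort()
  m1 <- trainStDNN(co, config = tinyModelConfig())
  m2 <- trainStDNN(co, config = tinyModelConfig())
  expect_identical(m1@parameters, m2@parameters)
  expect_identical(m1@trainingLog, m2@trainingLog)
  # strong planted signal is learnable to high training accuracy
  fit <- trainStDNN(co, config = stdnnConfig(
    8L, convChannels = c(16L, 8L), epochs = 40L, seed = 2L,
    augmentNoiseSd = 0))
  pr <- predict(fit, co)
  expect_gt(computeMetrics(pr$class, classLabels(co))$accuracy, 0.95)
  # training loss trends downward
  lg <- fit@trainingLog
  expect_lt(mean(tail(lg, 3)), mean(head(lg, 3)))
})

test_that("training rejects degenerate inputs", {
  co <- tinyCohort()
  expect_error(trainStDNN(co, which(classLabels(co) == 0L),
                          tinyModelConfig()), "both classes")
  expect_error(trainStDNN(co, integer(0), tinyModelConfig()), "empty")
  expect_error(trainStDNN(co, config = tinyModelConfig(nRegions = 9L)),
               "nRegions")
})

test_that("model containers survive a save/load cycle", {
  net <- smallTrainedNet()
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(net$model, path)
  m2 <- loadModel(path)
  expect_identical(m2@parameters, net$model@parameters)
  expect_identical(m2@siteVocabulary, net$model@siteVocabulary)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(container = "other"), bad)
  expect_error(loadModel(bad), "container")
})
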