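test_that("integrated gradients are exact for linear models at any step count", {
  set.seed(3)
  w <- matrix(rnorm(40), 4, 10)
  x <- matrix(rnorm(40), 4, 10)
  for (m in c(1L, 7L, 50L)) {
    ig <- igRiemann(x, x * 0, m, function(z) w)
    expect_equal(ig, w * x, tolerance = 1e-12)
  }
})

test_that("attributing the baseline itself yields all-zero scores", {
  net <- smallTrainedNet()
  x <- getTimeseries(net$cohort, 1)
  map <- integratedGradients(net$model, net$cohort, 1, nSteps = 16L,
                             baseline = x)
  expect_true(all(map@scores == 0))
})

test_that("completeness holds on a trained network and improves with steps", {
  net <- smallTrainedNet()
  subs <- c(1L, 13L, 25L)
  errAt <- function(m) mean(vapply(subs, function(i)
    igCompletenessErr(net$model, net$cohort, i, m), numeric(1)))
  errs <- vapply(c(8L, 32L, 128L, 512L), errAt, numeric(1))
  expect_lt(errAt(200L), 0.01)
  expect_true(all(diff(errs) < 0))
})

test_that("group aggregation is the nested median of subject and fold maps", {
  mkmap <- function(s, id = "x") new("AttributionMap", subjectId = id,
                                     scores = s, targetClass = 1L,
                                     nSteps = 8L)
  base <- matrix(1:12, 3, 4)
  # identical maps across subjects and folds reproduce the map
  tab <- aggregateGroupFeatures(list(list(mkmap(base), mkmap(base)),
                                     list(mkmap(base), mkmap(base))))
  expect_equal(tab@medianScores, base * 1)
  # one outlier among an odd majority leaves the median untouched
  nine <- c(replicate(9, mkmap(base), simplify = FALSE),
            list(mkmap(base + 100)))
  tab2 <- aggregateGroupFeatures(list(nine))
  expect_equal(tab2@medianScores, base * 1)
  # random maps match a brute-force nested median
  set.seed(9)
  folds <- lapply(1:3, function(f)
    lapply(1:5, function(s) mkmap(matrix(rnorm(12), 3, 4))))
  tab3 <- aggregateGroupFeatures(folds)
  oracle <- apply(vapply(folds, function(maps)
    apply(vapply(maps, function(m) m@scores, matrix(0, 3, 4)),
          c(1, 2), median), matrix(0, 3, 4)), c(1, 2), median)
  expect_equal(tab3@medianScores, oracle, tolerance = 1e-12)
  # maps of unequal length are cropped to the common Nt
  mixed <- list(list(mkmap(matrix(1, 3, 6)), mkmap(matrix(2, 3, 4))))
  expect_identical(dim(aggregateGroupFeatures(mixed)@medianScores), c(3L, 4L))
  expect_error(aggregateGroupFeatures(list(list(), list(mkmap(base)))),
               "fold")
})

test_that("top-percentile thresholding keeps the exact cell count and ranks regions", {
  set.seed(4)
  tab <- new("FeatureScoreTable", perFoldScores = list(),
             medianScores = matrix(rnorm(246 * 200), 246, 200),
             topMask = matrix(logical(0), 0, 0),
             regionHits = data.frame(), pct = NA_real_)
  out <- thresholdTopFeatures(tab, 5)
  expect_identical(sum(out@topMask), as.integer(ceiling(0.05 * 246 * 200)))
  expect_identical(sum(out@topMask), 2460L)
  # retained set equals the full sort-and-cut oracle
  keep <- sort(as.vector(tab@medianScores), decreasing = TRUE)[1:2460]
  expect_equal(sort(tab@medianScores[out@topMask], decreasing = TRUE), keep)

  # a dominating region is ranked first
  sc <- matrix(0, 10, 20)
  sc[7, ] <- 5
  sc[2, 1:3] <- 3
  tab2 <- new("FeatureScoreTable", perFoldScores = list(),
              medianScores = sc, topMask = matrix(logical(0), 0, 0),
              regionHits = data.frame(), pct = NA_real_)
  out2 <- thresholdTopFeatures(tab2, 10)
  expect_identical(out2@regionHits$region_index[1], 7L)

  # ties at the threshold are all included
  sc3 <- matrix(c(rep(1, 10), rep(0, 90)), 10, 10)
  tab3 <- new("FeatureScoreTable", perFoldScores = list(),
              medianScores = sc3, topMask = matrix(logical(0), 0, 0),
              regionHits = data.frame(), pct = NA_real_)
  out3 <- thresholdTopFeatures(tab3, 5)
  expect_identical(sum(out3@topMask), 10L)
  expect_error(thresholdTopFeatures(tab3, 0), "pct")
})

test_that("region scores are the temporal means of attribution rows", {
  sc <- rbind(rep(2.5, 8), c(-4, 4, -4, 4, -4, 4, -4, 4), rnorm(8))
  map <- new("AttributionMap", subjectId = "s", scores = sc,
             targetClass = 1L, nSteps = 8L)
  v <- subjectRegionScores(map)
  expect_equal(v[1], 2.5)
  expect_equal(v[2], 0)
  expect_equal(v[3], mean(sc[3, ]), tolerance = 1e-12)
})

test_that("fingerprints of planted-signal carriers concentrate on planted regions", {
  net <- smallTrainedNet()
  co <- net$cohort
  g1 <- which(classLabels(co) == 1L)
  maps <- lapply(g1, function(i)
    integratedGradients(net$model, co, i, nSteps = 24L))
  tab <- thresholdTopFeatures(aggregateGroupFeatures(list(maps)), 10)
  # both planted regions (1, 2) appear among the hits
  expect_true(all(1:2 %in% tab@regionHits$region_index))
})
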