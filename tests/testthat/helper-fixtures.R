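# Shared fixtures. Heavy objects (the reference cohort and its fivefold
# cross-validation) are computed once per session and cached, because
# several acceptance properties are measured on the same study.

.fixtures <- new.env(parent = emptyenv())

# a small cohort for fast unit tests of the training/attribution plumbing
tinyCohort <- function(seed = 11L, effectSize = 2.0) {
  zscoreNormalize(generateCohort(synthConfig(
    nClass0 = 24L, nClass1 = 12L, nRegions = 8L, ntRange = c(48L, 64L),
    nSites = 2L, plantedRegions = 1:2, symptomRegion = 1L,
    effectSize = effectSize, seed = seed)))
}

tinyModelConfig <- function(nRegions = 8L, epochs = 20L, ...) {
  stdnnConfig(nRegions, convChannels = c(8L, 6L), epochs = epochs,
              seed = 2L, ...)
}

# hand-built single-channel model with identity-tap kernels, used by the
# hand-computed convolution oracle
handModel <- function() {
  cfg <- stdnnConfig(1L, convChannels = c(1L, 1L), kernelSizes = c(3L, 3L),
                     siteVocabSize = 1L)
  par <- list(W1 = matrix(c(0, 1, 0), 1, 3), b1 = 0,
              W2 = matrix(c(0, 1, 0), 1, 3), b2 = 0,
              W3 = matrix(c(1, 2, 0, 0), 2, 2), b3 = c(0, 0))
  new("TrainedModel", config = cfg, parameters = par,
      siteVocabulary = "s1", classCounts = c(1L, 1L),
      margins = c(0, 0), trainingLog = numeric(0))
}

# reference study: the default synthetic cohort, its fivefold CV, the
# matched transfer cohort, and the signal-free analogue
referenceStudy <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  scfg <- synthConfig()
  cohort <- zscoreNormalize(generateCohort(scfg))
  mcfg <- stdnnConfig(nRegions(cohort))
  folds <- makeFolds(classLabels(cohort), siteLabels(cohort), k = 5L,
                     seed = mcfg@seed)
  cv <- crossValidate(cohort, mcfg, folds)
  transfer <- zscoreNormalize(generateTransferCohort(scfg, c("extA", "extB")))
  nullCfg <- synthConfig(effectSize = 0, symptomNoiseSd = 0.5, seed = 101L)
  nullCohort <- zscoreNormalize(generateCohort(nullCfg))
  .fixtures$study <- list(scfg = scfg, cohort = cohort, mcfg = mcfg,
                          folds = folds, cv = cv, transfer = transfer,
                          nullCfg = nullCfg, nullCohort = nullCohort)
  .fixtures$study
}

referenceNullCV <- function() {
  if (!is.null(.fixtures$nullcv)) return(.fixtures$nullcv)
  st <- referenceStudy()
  folds <- makeFolds(classLabels(st$nullCohort), siteLabels(st$nullCohort),
                     k = 5L, seed = st$mcfg@seed)
  .fixtures$nullcv <- crossValidate(st$nullCohort, st$mcfg, folds)
  .fixtures$nullcv
}

# small trained network shared by attribution tests
smallTrainedNet <- function() {
  if (!is.null(.fixtures$smallnet)) return(.fixtures$smallnet)
  co <- tinyCohort()
  .fixtures$smallnet <- list(cohort = co,
                             model = trainStDNN(co, config = tinyModelConfig()))
  .fixtures$smallnet
}

# completeness relative error of integrated gradients for one subject
igCompletenessErr <- function(model, cohort, i, steps) {
  site <- encodeSites(siteLabels(cohort)[i], model@siteVocabulary)$matrix[1, ]
  f1 <- forwardPass(model, getTimeseries(cohort, i), site)$logits[2]
  f0 <- forwardPass(model, getTimeseries(cohort, i) * 0, site)$logits[2]
  ig <- integratedGradients(model, cohort, i, nSteps = steps)
  abs(sum(ig@scores) - (f1 - f0)) / abs(f1 - f0)
}

# one repetition of the symptom-association recovery study: a 90-subject
# two-class cohort with one planted region driving the "rrb" score,
# fivefold CV, fingerprint region scores, association in both groups
associationRep <- function(rep) {
  scfg <- synthConfig(nClass0 = 60L, nClass1 = 30L, nRegions = 12L,
                      ntRange = c(64L, 96L), plantedRegions = 1L,
                      symptomRegion = 1L, seed = 1000L + rep)
  co <- zscoreNormalize(generateCohort(scfg))
  mcfg <- stdnnConfig(12L, convChannels = c(32L, 16L), epochs = 40L,
                      seed = rep)
  folds <- makeFolds(classLabels(co), siteLabels(co), 5L, seed = rep)
  cv <- crossValidate(co, mcfg, folds)
  rs <- regionScoreMatrix(cv@models, co, nSteps = 32L)
  a1 <- associateSymptoms(co, rs, c("rrb", "social", "comm"), 1L)
  a0 <- associateSymptoms(co, rs, c("rrb", "social", "comm"), 0L)
  rrb <- a1[a1$domain == "rrb", ]
  nullRows <- rbind(a1[a1$domain != "rrb", ], a0)
  list(plantedSmallestP = which.min(rrb$p_raw) == 1L,
       plantedRho = rrb$rho[1], plantedQ = rrb$q_fdr[1],
       anyNullSig = any(nullRows$q_fdr < 0.01, na.rm = TRUE))
}
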