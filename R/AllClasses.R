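## S4 class definitions and validity for the central data objects.

#' Cohort of subjects with regional time series
#'
#' Ordered collection of subjects, each carrying a numeric regions-by-time
#' matrix, a binary class label, an acquisition-site label and optional
#' symptom-domain scores and head-motion summaries. The number of regions
#' (Nc) is identical across subjects; the number of timepoints (Nt) may
#' differ between subjects and sites.
#'
#' @slot timeseries named list of numeric matrices, one per subject,
#'   each \code{Nc x Nt} with \code{Nt >= 8}.
#' @slot phenotype data.frame with columns \code{subject_id},
#'   \code{class_label} (integer 0/1), \code{site}, and optionally
#'   \code{score_*} symptom columns and \code{mean_fd} (mean framewise
#'   displacement, mm). Row order defines subject order.
#' @slot regionNames character vector of length Nc.
#' @slot siteVocabulary ordered character vector covering every subject's
#'   site.
#'
#' @seealso \code{\link{loadCohort}}, \code{\link{generateCohort}}
#' @exportClass Cohort
setClass("Cohort",
  slots = c(
    timeseries = "list",
    phenotype = "data.frame",
    regionNames = "character",
    siteVocabulary = "character"
  )
)

setValidity("Cohort", function(object) {
  ph <- object@phenotype
  need <- c("subject_id", "class_label", "site")
  if (!all(need %in% names(ph)))
    return(paste("phenotype must contain columns:", paste(need, collapse = ", ")))
  ids <- as.character(ph$subject_id)
  if (anyDuplicated(ids)) return("subject ids must be unique")
  if (length(object@timeseries) != nrow(ph))
    return("timeseries list length must equal phenotype rows")
  if (!identical(names(object@timeseries), ids))
    return("names(timeseries) must equal phenotype$subject_id in order")
  if (!all(ph$class_label %in% c(0L, 1L)))
    return("class_label must be 0 or 1")
  nc <- length(object@regionNames)
  if (anyDuplicated(object@regionNames)) return("region names must be unique")
  for (i in seq_along(object@timeseries)) {
    m <- object@timeseries[[i]]
    if (!is.matrix(m) || !is.numeric(m))
      return(sprintf("timeseries of subject '%s' is not a numeric matrix", ids[i]))
    if (nrow(m) != nc)
      return(sprintf("subject '%s' has %d regions; cohort has %d",
                     ids[i], nrow(m), nc))
    if (ncol(m) < 8L)
      return(sprintf("subject '%s' has Nt = %d < 8 timepoints", ids[i], ncol(m)))
    if (!all(is.finite(m)))
      return(sprintf("subject '%s' has non-finite timeseries values", ids[i]))
  }
  if (!all(as.character(ph$site) %in% object@siteVocabulary))
    return("site_vocabulary must cover every subject's site")
  TRUE
})

#' Synthetic cohort generator configuration
#'
#' Study conditions for \code{\link{generateCohort}}: a multi-site,
#' class-imbalanced cohort whose group difference is carried by a
#' subject-specific oscillatory component confined to a planted subset of
#' regions, with a symptom score monotonically linked to the oscillation
#' amplitude in one planted region.
#'
#' @slot nClass0,nClass1 subject counts per class (default 80/20, the 4:1
#'   imbalance typical of male-skewed autism cohorts).
#' @slot nRegions number of regions Nc (default 30).
#' @slot ntRange integer \code{c(min, max)} timepoints; each site draws its
#'   own Nt uniformly from this range (min must be >= 16).
#' @slot nSites number of acquisition sites (round-robin assignment).
#' @slot plantedRegions region indices carrying class-1 signal.
#' @slot effectSize oscillation amplitude mean, in baseline-noise s.d.
#'   units; per-subject amplitudes are Normal(effectSize, effectSize/4).
#' @slot siteOffsetSd s.d. of the per-site, per-region additive offset.
#' @slot arCoefficient AR(1) coefficient of the baseline noise, in [0, 1).
#' @slot oscFrequency oscillation frequency in cycles per timepoint.
#' @slot symptomRegion planted region whose amplitude drives the "rrb"
#'   symptom score.
#' @slot symptomNoiseSd s.d. of the additive noise on the symptom score.
#' @slot seed RNG seed; the whole cohort is reproducible from it.
#'
#' @exportClass SynthConfig
setClass("SynthConfig",
  slots = c(
    nClass0 = "integer", nClass1 = "integer", nRegions = "integer",
    ntRange = "integer", nSites = "integer", plantedRegions = "integer",
    effectSize = "numeric", siteOffsetSd = "numeric",
    arCoefficient = "numeric", oscFrequency = "numeric",
    symptomRegion = "integer", symptomNoiseSd = "numeric", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  if (object@nClass0 < 1L || object@nClass1 < 1L)
    return("both classes need at least one subject")
  if (object@effectSize < 0) return("effect_size must be >= 0")
  if (length(object@ntRange) != 2L || object@ntRange[1] < 16L ||
      object@ntRange[2] < object@ntRange[1])
    return("ntRange must be c(min, max) with min >= 16")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    return("arCoefficient must be in [0, 1)")
  if (!all(object@plantedRegions >= 1L & object@plantedRegions <= object@nRegions))
    return("plantedRegions must lie within 1..nRegions")
  if (length(object@plantedRegions) > 0 &&
      !(object@symptomRegion %in% object@plantedRegions))
    return("symptomRegion must be one of plantedRegions")
  if (object@nSites < 1L) return("need at least one site")
  TRUE
})

#' Architecture and training hyperparameters of the stDNN classifier
#'
#' Two 1D-convolutional blocks over time (regions as input channels, each
#' followed by ReLU), temporal averaging, concatenation of a one-hot site
#' vector, and an affine head producing two class logits. Trained by Adam
#' on the LDAM loss.
#'
#' @slot nRegions input channels Nc.
#' @slot convChannels integer \code{c(F1, F2)} filter counts.
#' @slot kernelSizes integer \code{c(k1, k2)}, odd.
#' @slot strides integer \code{c(S1, S2)}.
#' @slot siteVocabSize length of the one-hot site vector (0 = set from the
#'   cohort at training time).
#' @slot ldamC margin scale C of the LDAM loss; 0 disables margins
#'   (plain softmax cross-entropy when \code{logitScale = 1}).
#' @slot ldamMaxMargin cap: margins are rescaled so the largest equals
#'   this value (NA disables rescaling).
#' @slot logitScale multiplicative logit scale s of the LDAM loss.
#' @slot learningRate,epochs,batchSize Adam step size, passes over the
#'   training set, and minibatch size.
#' @slot weightDecay decoupled (AdamW-style) L2 penalty applied to the
#'   weight matrices (not biases) at each update.
#' @slot augmentNoiseSd s.d. of fresh Gaussian noise added to each
#'   training input at every presentation (train-time only). Penalizes
#'   memorization of subject-specific noise patterns in small cohorts;
#'   0 disables.
#' @slot seed RNG seed for weight initialization and batch shuffling.
#'
#' @exportClass StDNNConfig
setClass("StDNNConfig",
  slots = c(
    nRegions = "integer", convChannels = "integer", kernelSizes = "integer",
    strides = "integer", siteVocabSize = "integer",
    ldamC = "numeric", ldamMaxMargin = "numeric", logitScale = "numeric",
    learningRate = "numeric", weightDecay = "numeric",
    augmentNoiseSd = "numeric", epochs = "integer",
    batchSize = "integer", seed = "integer"
  )
)

setValidity("StDNNConfig", function(object) {
  if (any(object@convChannels < 1L)) return("filter counts must be >= 1")
  if (any(object@kernelSizes %% 2L == 0L)) return("kernel sizes must be odd")
  if (any(object@strides < 1L)) return("strides must be >= 1")
  if (object@ldamC < 0) return("ldamC must be >= 0")
  if (object@logitScale <= 0) return("logitScale must be > 0")
  if (object@nRegions < 1L) return("nRegions must be >= 1")
  TRUE
})

#' A fitted stDNN classifier
#'
#' @slot config the \code{\linkS4class{StDNNConfig}} used for training.
#' @slot parameters list of weight matrices/vectors
#'   (\code{W1,b1,W2,b2,W3,b3}).
#' @slot siteVocabulary ordered site names seen at training time; sites
#'   outside it are encoded as all-zero vectors at inference.
#' @slot classCounts training-set subjects per class (0, 1).
#' @slot margins the per-class LDAM margins used during training.
#' @slot trainingLog mean training loss per epoch.
#'
#' @exportClass TrainedModel
setClass("TrainedModel",
  slots = c(
    config = "StDNNConfig", parameters = "list",
    siteVocabulary = "character", classCounts = "integer",
    margins = "numeric", trainingLog = "numeric"
  )
)

setValidity("TrainedModel", function(object) {
  need <- c("W1", "b1", "W2", "b2", "W3", "b3")
  if (!all(need %in% names(object@parameters)))
    return(paste("parameters must contain", paste(need, collapse = ", ")))
  if (length(object@classCounts) != 2L) return("classCounts must have length 2")
  if (length(object@margins) != 2L) return("margins must have length 2")
  TRUE
})

#' Stratified fold assignment for k-fold cross-validation
#'
#' @slot k number of folds.
#' @slot fold integer fold index (1..k) per subject, in cohort order.
#' @slot seed RNG seed that produced the assignment.
#' @slot stratifiedBySite whether site-level balancing was applied.
#'
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  slots = c(k = "integer", fold = "integer", seed = "integer",
            stratifiedBySite = "logical")
)

setValidity("FoldAssignment", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (!all(object@fold %in% seq_len(object@k)))
    return("fold indices must lie in 1..k")
  TRUE
})

#' Result of a k-fold cross-validation run
#'
#' @slot models list of k \code{\linkS4class{TrainedModel}} objects.
#' @slot foldMetrics data.frame of per-fold metrics (accuracy, weighted
#'   precision/recall/F1 and the per-class values).
#' @slot summary data.frame with across-fold mean and s.d. per metric.
#' @slot folds the \code{\linkS4class{FoldAssignment}} used.
#'
#' @exportClass CVResult
setClass("CVResult",
  slots = c(models = "list", foldMetrics = "data.frame",
            summary = "data.frame", folds = "FoldAssignment")
)

#' Integrated-gradients fingerprint of one subject
#'
#' Signed attribution of the target-class logit to every (region, time)
#' cell of the subject's input, for one trained model.
#'
#' @slot subjectId subject identifier.
#' @slot scores numeric matrix, same shape as the subject's input.
#' @slot targetClass class label (0/1) whose logit was attributed.
#' @slot nSteps Riemann steps used.
#'
#' @exportClass AttributionMap
setClass("AttributionMap",
  slots = c(subjectId = "character", scores = "matrix",
            targetClass = "integer", nSteps = "integer")
)

setValidity("AttributionMap", function(object) {
  if (!all(is.finite(object@scores))) return("attribution scores must be finite")
  TRUE
})

#' Group-level per-(region, time) feature scores
#'
#' Fold-wise group medians of subject fingerprints, their across-fold
#' median consensus, and (after \code{\link{thresholdTopFeatures}}) the
#' top-percentile mask and per-region hit summary.
#'
#' @slot perFoldScores list of k matrices (Nc x common Nt).
#' @slot medianScores consensus matrix (median across folds).
#' @slot topMask logical matrix marking top-percentile cells (empty until
#'   thresholded).
#' @slot regionHits data.frame (region, n_cells, peak_score) for regions
#'   with at least one surviving cell, sorted by peak score.
#' @slot pct percentile used (e.g. 5 = top 5%).
#'
#' @exportClass FeatureScoreTable
setClass("FeatureScoreTable",
  slots = c(perFoldScores = "list", medianScores = "matrix",
            topMask = "matrix", regionHits = "data.frame", pct = "numeric")
)
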