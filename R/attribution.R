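## Integrated-gradients fingerprints and group-level feature scores.
##
## Integrated gradients attribute the target-class logit F to each input
## cell along the straight path from a baseline x' to the input x:
##   IG_i = (x_i - x'_i) * (1/m) * sum_{t=1..m} dF/dx_i at x' + (t-.5)/m (x-x')
## (midpoint Riemann approximation of the path integral). The attributions
## satisfy the completeness axiom sum_i IG_i ~= F(x) - F(x') up to the
## Riemann discretization error, which shrinks as m grows; for a linear F
## the midpoint rule is exact at any m >= 1.

#' Midpoint-rule integrated gradients for an arbitrary gradient function
#'
#' Building block used by \code{\link{integratedGradients}}; exposed so
#' that closed-form models (e.g. linear maps) can be attributed directly.
#'
#' @param x input (vector or matrix)
#' @param baseline baseline x', same shape as \code{x}
#' @param m number of Riemann steps, >= 1
#' @param gradFun function taking an input of the shape of \code{x} and
#'   returning dF/dx of the same shape
#' @return attribution array of the shape of \code{x}.
#' @export
igRiemann <- function(x, baseline, m, gradFun) {
  if (m < 1L) .stopf("need at least one Riemann step")
  diff <- x - baseline
  acc <- baseline * 0
  for (t in seq_len(m)) {
    g <- gradFun(baseline + ((t - 0.5) / m) * diff)
    if (!all(is.finite(g)))
      .stopf("non-finite gradient at Riemann step %d", t)
    acc <- acc + g
  }
  diff * acc / m
}

## gradient of the target-class logit wrt the input matrix
.logitInputGrad <- function(model, X, siteVec, targetClass) {
  cfg <- model@config
  fc <- .forwardCore(model@parameters, X, siteVec, cfg, keepCache = TRUE)
  dlogits <- c(0, 0)
  dlogits[targetClass + 1L] <- 1
  .backwardCore(model@parameters, fc, dlogits, cfg, wantInputGrad = TRUE)$X
}

#' Integrated-gradients fingerprint of one subject
#'
#' Signed attribution of the chosen class logit over every (region, time)
#' cell of the subject's time series, for one trained model.
#'
#' @param model a \code{\linkS4class{TrainedModel}}
#' @param cohort the subject's \code{\linkS4class{Cohort}} (supplies the
#'   site encoding against the model's vocabulary)
#' @param subject subject index or id
#' @param targetClass class (0/1) whose logit is attributed (default 1)
#' @param nSteps Riemann steps m (default 50)
#' @param baseline \code{"zeros"} (the no-signal reference after
#'   z-scoring) or a numeric matrix of the subject's shape
#' @return An \code{\linkS4class{AttributionMap}}.
#' @export
integratedGradients <- function(model, cohort, subject, targetClass = 1L,
                                nSteps = 50L, baseline = "zeros") {
  if (is.character(subject)) subject <- match(subject, subjectIds(cohort))
  X <- cohort@timeseries[[subject]]
  if (nrow(X) != model@config@nRegions)
    .stopf("subject has %d regions but the model expects %d",
           nrow(X), model@config@nRegions)
  siteVec <- drop(encodeSites(siteLabels(cohort)[subject],
                              model@siteVocabulary)$matrix)
  B <- if (is.matrix(baseline)) {
    if (!identical(dim(baseline), dim(X)))
      .stopf("baseline shape does not match the subject's input")
    baseline
  } else X * 0
  scores <- igRiemann(X, B, as.integer(nSteps), function(xt)
    .logitInputGrad(model, xt, siteVec, as.integer(targetClass)))
  new("AttributionMap", subjectId = subjectIds(cohort)[subject],
      scores = scores, targetClass = as.integer(targetClass),
      nSteps = as.integer(nSteps))
}

#' Group-level feature scores with median-across-folds consensus
#'
#' Each fold's score matrix is the per-cell median, across the
#' target-group subjects, of their signed fingerprints under that fold's
#' model; the consensus is the per-cell median across the fold matrices
#' (a nested median: subjects first, then folds). All maps are cropped to
#' the shortest Nt present so cells align across subjects and sites.
#'
#' @param perFoldMaps list over folds; each element a list of
#'   \code{\linkS4class{AttributionMap}} objects for the target-group
#'   subjects under that fold's model
#' @return A \code{\linkS4class{FeatureScoreTable}} (mask unfilled; see
#'   \code{\link{thresholdTopFeatures}}).
#' @export
aggregateGroupFeatures <- function(perFoldMaps) {
  if (!length(perFoldMaps)) .stopf("no folds supplied")
  empty <- which(!vapply(perFoldMaps, length, integer(1)))
  if (length(empty))
    .stopf("no target-group maps in fold(s): %s",
           paste(empty, collapse = ", "))
  allMaps <- unlist(perFoldMaps, recursive = FALSE)
  ntCommon <- min(vapply(allMaps, function(m) ncol(m@scores), integer(1)))
  nc <- nrow(allMaps[[1]]@scores)
  foldScores <- lapply(perFoldMaps, function(maps) {
    arr <- vapply(maps, function(m) m@scores[, seq_len(ntCommon)],
                  matrix(0, nc, ntCommon))
    apply(arr, c(1, 2), median)
  })
  consensus <- apply(
    vapply(foldScores, identity, matrix(0, nc, ntCommon)),
    c(1, 2), median)
  new("FeatureScoreTable", perFoldScores = foldScores,
      medianScores = consensus,
      topMask = matrix(logical(0), 0, 0),
      regionHits = data.frame(), pct = NA_real_)
}

#' Identify the top-percentile features
#'
#' Thresholds the consensus score matrix at the (100 - pct)-th percentile
#' of all pooled (region, time) values: the threshold is the
#' \code{ceiling(pct/100 * Ncells)}-th largest score, and the mask keeps
#' every cell >= it, so exactly that many cells survive unless ties at
#' the threshold expand the set (ties are all included and the achieved
#' count is reported via the mask itself).
#'
#' @param table a \code{\linkS4class{FeatureScoreTable}} from
#'   \code{\link{aggregateGroupFeatures}}
#' @param pct percentage of cells to keep (default 5)
#' @param regionNames optional names for the region-hit summary
#' @return The table with \code{topMask} and \code{regionHits} filled;
#'   \code{regionHits} lists each region with >= 1 surviving cell,
#'   its surviving-cell count and peak consensus score, sorted by peak
#'   score descending.
#' @export
thresholdTopFeatures <- function(table, pct = 5, regionNames = NULL) {
  if (pct <= 0 || pct >= 100) .stopf("pct must be in (0, 100)")
  sc <- table@medianScores
  nKeep <- as.integer(ceiling(pct / 100 * length(sc)))
  thr <- sort(as.vector(sc), decreasing = TRUE)[nKeep]
  mask <- sc >= thr
  nc <- nrow(sc)
  if (is.null(regionNames)) regionNames <- sprintf("R%03d", seq_len(nc))
  cells <- rowSums(mask)
  hitIdx <- which(cells > 0)
  hits <- data.frame(region = regionNames[hitIdx],
                     region_index = hitIdx,
                     n_cells = cells[hitIdx],
                     peak_score = apply(sc[hitIdx, , drop = FALSE], 1, max),
                     row.names = NULL)
  hits <- hits[order(-hits$peak_score), , drop = FALSE]
  rownames(hits) <- NULL
  table@topMask <- mask
  table@regionHits <- hits
  table@pct <- pct
  table
}

#' Per-region scalar scores of one fingerprint
#'
#' The temporal mean of each region's signed attribution row — the
#' subject-level "brain feature" entering symptom association.
#'
#' @param map an \code{\linkS4class{AttributionMap}}
#' @return numeric vector of length Nc.
#' @export
subjectRegionScores <- function(map) rowMeans(map@scores)

#' Fingerprint a whole group under each fold model
#'
#' Computes every subject's fingerprint under each model and reduces it
#' to per-region scores; the workhorse behind symptom association.
#'
#' @param models list of \code{\linkS4class{TrainedModel}} objects
#' @param cohort the \code{\linkS4class{Cohort}}
#' @param subjects subject indices (default all)
#' @param targetClass class whose logit is attributed
#' @param nSteps Riemann steps
#' @return list over models, each an (n subjects x Nc) matrix of region
#'   scores with subject ids as row names.
#' @export
regionScoreMatrix <- function(models, cohort,
                              subjects = seq_len(nSubjects(cohort)),
                              targetClass = 1L, nSteps = 50L) {
  if (is(models, "CVResult")) models <- models@models
  lapply(models, function(mod) {
    out <- matrix(NA_real_, length(subjects), nRegions(cohort),
                  dimnames = list(subjectIds(cohort)[subjects],
                                  regionNames(cohort)))
    for (j in seq_along(subjects)) {
      map <- integratedGradients(mod, cohort, subjects[j],
                                 targetClass = targetClass, nSteps = nSteps)
      out[j, ] <- subjectRegionScores(map)
    }
    out
  })
}
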