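## Stratified k-fold cross-validation, transfer/specificity evaluation and
## classification metrics with across-fold mean/s.d. reporting.

#' Stratified fold assignment
#'
#' Folds partition the subjects; within each class, fold sizes differ by
#' at most one (class-stratified). When \code{sites} are supplied and
#' every site-by-class cell holds at least \code{k} subjects, subjects of
#' each class are dealt to folds after grouping by site, spreading every
#' site across folds as well; otherwise class-only stratification is used
#' with a warning.
#'
#' @param labels integer 0/1 class per subject
#' @param sites optional site label per subject
#' @param k number of folds (default 5)
#' @param seed RNG seed; the assignment is deterministic given it
#' @return A \code{\linkS4class{FoldAssignment}}.
#' @export
makeFolds <- function(labels, sites = NULL, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) .stopf("k must be >= 2")
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < k))
    .stopf("every class needs at least k=%d members (counts %d/%d)",
           k, tab[1], tab[2])
  bySite <- FALSE
  if (!is.null(sites)) {
    cell <- table(sites, labels)
    if (all(cell >= k)) bySite <- TRUE
    else warning("site-by-class cells smaller than k; stratifying by class only",
                 call. = FALSE)
  }
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]         # shuffle
      if (bySite) idx <- idx[order(match(sites[idx], unique(sites)))]
      # deal cyclically: per-class fold sizes differ by <= 1, and with the
      # site ordering each site is spread across consecutive folds
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  new("FoldAssignment", k = k, fold = fold, seed = as.integer(seed),
      stratifiedBySite = bySite)
}

#' Classification metrics from predicted and true labels
#'
#' Returns accuracy, the 2x2 confusion table (rows = truth, columns =
#' prediction) and precision/recall/F1 both per class and as the
#' support-weighted average across classes. Undefined ratios (a class
#' never predicted) are reported as 0.
#'
#' @param predicted integer 0/1 predictions
#' @param truth integer 0/1 true labels
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1} (support-weighted), \code{perClass} data.frame and
#'   \code{confusion} matrix.
#' @export
computeMetrics <- function(predicted, truth) {
  if (length(predicted) == 0L) .stopf("empty prediction vector")
  if (length(predicted) != length(truth))
    .stopf("predicted and truth lengths differ")
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (!all(c(predicted, truth) %in% c(0L, 1L)))
    .stopf("labels must be 0 or 1")
  conf <- table(factor(truth, levels = c(0L, 1L)),
                factor(predicted, levels = c(0L, 1L)))
  conf <- matrix(as.integer(conf), 2, 2,
                 dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  perClass <- data.frame(class = c(0L, 1L), support = rowSums(conf),
                         precision = 0, recall = 0, f1 = 0)
  for (c0 in 1:2) {
    tp <- conf[c0, c0]
    predN <- sum(conf[, c0]); suppN <- sum(conf[c0, ])
    prec <- if (predN > 0) tp / predN else 0
    rec <- if (suppN > 0) tp / suppN else 0
    perClass$precision[c0] <- prec
    perClass$recall[c0] <- rec
    perClass$f1[c0] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  w <- perClass$support / sum(perClass$support)
  list(accuracy = sum(diag(conf)) / sum(conf),
       precision = sum(w * perClass$precision),
       recall = sum(w * perClass$recall),
       f1 = sum(w * perClass$f1),
       perClass = perClass, confusion = conf)
}

.metricsRow <- function(m) {
  data.frame(accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, f1 = m$f1,
             precision0 = m$perClass$precision[1],
             recall0 = m$perClass$recall[1],
             f1_0 = m$perClass$f1[1],
             precision1 = m$perClass$precision[2],
             recall1 = m$perClass$recall[2],
             f1_1 = m$perClass$f1[2])
}

.summarize <- function(df) {
  num <- df[vapply(df, is.numeric, logical(1))]
  data.frame(metric = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, sd, numeric(1)),
             row.names = NULL)
}

#' k-fold cross-validation of the stDNN classifier
#'
#' For each fold, trains on the remaining folds and evaluates on the
#' held-out fold. Each fold's model uses a seed deterministically derived
#' from \code{config@seed} and the fold index, so the whole run is
#' reproducible.
#'
#' @param cohort a normalized \code{\linkS4class{Cohort}}
#' @param config an \code{\linkS4class{StDNNConfig}}
#' @param folds a \code{\linkS4class{FoldAssignment}} for the cohort;
#'   default: stratified folds with \code{k = 5} seeded from the config
#' @return A \code{\linkS4class{CVResult}}.
#' @export
crossValidate <- function(cohort, config = stdnnConfig(nRegions(cohort)),
                          folds = makeFolds(classLabels(cohort),
                                            siteLabels(cohort),
                                            k = 5L, seed = config@seed)) {
  if (length(folds@fold) != nSubjects(cohort))
    .stopf("fold assignment covers %d subjects; cohort has %d",
           length(folds@fold), nSubjects(cohort))
  models <- vector("list", folds@k)
  rows <- vector("list", folds@k)
  for (f in seq_len(folds@k)) {
    trainIdx <- which(folds@fold != f)
    testIdx <- which(folds@fold == f)
    cfg <- config
    cfg@seed <- .deriveSeed(config@seed, f)
    models[[f]] <- tryCatch(trainStDNN(cohort, trainIdx, cfg),
                            error = function(e)
                              .stopf("fold %d: %s", f, conditionMessage(e)))
    pred <- predict(models[[f]], cohort[testIdx])
    m <- computeMetrics(pred$class, classLabels(cohort)[testIdx])
    rows[[f]] <- cbind(fold = f, .metricsRow(m))
  }
  fm <- do.call(rbind, rows)
  new("CVResult", models = models, foldMetrics = fm,
      summary = .summarize(fm[-1]), folds = folds)
}

setMethod("show", "CVResult", function(object) {
  s <- object@summary
  g <- function(m) sprintf("%.3f (s.d. %.3f)", s$mean[s$metric == m],
                           s$sd[s$metric == m])
  cat(sprintf(paste0(
    "CVResult: %d folds\n  accuracy %s\n  precision %s\n",
    "  recall %s\n  F1 %s\n"),
    object@folds@k, g("accuracy"), g("precision"), g("recall"), g("f1")))
})

#' Apply trained models to an external cohort
#'
#' Evaluates each model on the full cohort and reports per-model metrics
#' plus their across-model mean/s.d. This single operation implements
#' both the zero-shot transfer test (same-population cohort, unseen
#' sites, encoded as all-zero site vectors) and the specificity test
#' (different population passed in).
#'
#' @param models list of \code{\linkS4class{TrainedModel}} objects (e.g.
#'   \code{cvResult@models})
#' @param cohort the external \code{\linkS4class{Cohort}}
#' @return list with \code{perModel} (data.frame, one row per model) and
#'   \code{summary} (mean/s.d. per metric).
#' @export
applyModels <- function(models, cohort) {
  if (is(models, "CVResult")) models <- models@models
  rows <- vector("list", length(models))
  for (j in seq_along(models)) {
    pred <- predict(models[[j]], cohort)
    m <- computeMetrics(pred$class, classLabels(cohort))
    rows[[j]] <- cbind(model = j, .metricsRow(m))
  }
  pm <- do.call(rbind, rows)
  list(perModel = pm, summary = .summarize(pm[-1]))
}
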