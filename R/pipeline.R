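## One-command end-to-end run on synthetic cohorts: simulate -> train-cv ->
## transfer -> specificity -> attribute -> associate, with a JSON run
## report. A single master seed fans out deterministically to per-stage
## seeds (fixed derivation rule), so every stage is independently
## re-runnable and the whole run is reproducible.

.pipelineDefaults <- function() {
  list(
    seed = 42L,
    synth = list(),                       # synthConfig() arguments
    model = list(),                       # stdnnConfig() arguments (minus nRegions)
    cv = list(k = 5L),
    transfer = list(nSites = 2L),
    attribution = list(nSteps = 50L, pct = 5, targetClass = 1L),
    association = list(domains = c("rrb", "social", "comm"), alpha = 0.01)
  )
}

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Generates a training cohort, an independent transfer cohort with
#' unseen site names, and a signal-free cohort (the "neurotypical
#' analogue"); trains fivefold cross-validated stDNN models; evaluates
#' transfer and specificity; computes integrated-gradients fingerprints,
#' the median-across-folds consensus and the top-percentile regions; and
#' associates region scores with symptom domains in both groups. Writes
#' all tables as TSV plus a machine-readable \code{report.json}.
#'
#' @param outDir output directory (created if needed)
#' @param config \code{NULL}, a YAML file path, or a nested list
#'   overriding any of: \code{seed}; \code{synth} (arguments of
#'   \code{\link{synthConfig}}); \code{model} (arguments of
#'   \code{\link{stdnnConfig}} except \code{nRegions});
#'   \code{cv$k}; \code{transfer$nSites}; \code{attribution$nSteps},
#'   \code{$pct}, \code{$targetClass}; \code{association$domains},
#'   \code{$alpha}
#' @param seed master seed overriding the config's \code{seed}
#' @return The run report, invisibly (a nested list mirroring
#'   \code{report.json}).
#' @export
runPipeline <- function(outDir, config = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(.pipelineDefaults(), if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = 1L, master_seed = cfg$seed,
                 config = cfg, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), st, units = "secs")))
    val
  }

  ## 1. simulate: training, transfer (unseen sites) and signal-free cohorts
  synthArgs <- cfg$synth
  synthArgs$seed <- .deriveSeed(cfg$seed, 1L)
  scfg <- do.call(synthConfig, synthArgs)
  sim <- stage("simulate", {
    train <- generateCohort(scfg)
    extSites <- sprintf("ext%02d", seq_len(cfg$transfer$nSites))
    transfer <- generateTransferCohort(scfg, extSites)
    nullArgs <- synthArgs
    nullArgs$effectSize <- 0
    nullArgs$symptomNoiseSd <- scfg@symptomNoiseSd
    nullArgs$seed <- .deriveSeed(cfg$seed, 2L)
    nullCohort <- generateCohort(do.call(synthConfig, nullArgs))
    saveCohort(train, file.path(outDir, "cohort_train"))
    saveCohort(transfer, file.path(outDir, "cohort_transfer"))
    saveCohort(nullCohort, file.path(outDir, "cohort_null"))
    list(train = zscoreNormalize(train),
         transfer = zscoreNormalize(transfer),
         nullCohort = zscoreNormalize(nullCohort))
  })

  ## 2-3. fivefold cross-validated training
  modelArgs <- cfg$model
  modelArgs$nRegions <- scfg@nRegions
  modelArgs$seed <- .deriveSeed(cfg$seed, 4L)
  mcfg <- do.call(stdnnConfig, modelArgs)
  folds <- makeFolds(classLabels(sim$train), siteLabels(sim$train),
                     k = cfg$cv$k, seed = .deriveSeed(cfg$seed, 3L))
  cvres <- stage("train_cv", crossValidate(sim$train, mcfg, folds))
  .writeTsv(cvres@foldMetrics, file.path(outDir, "cv_metrics.tsv"))
  .writeTsv(cvres@summary, file.path(outDir, "cv_summary.tsv"))
  for (f in seq_along(cvres@models))
    saveModel(cvres@models[[f]], file.path(outDir, sprintf("model_fold%d.rds", f)))

  ## 4. transfer (same law, unseen sites) and specificity (signal-free)
  transferRes <- stage("transfer", applyModels(cvres, sim$transfer))
  .writeTsv(transferRes$perModel, file.path(outDir, "transfer_metrics.tsv"))
  specRes <- stage("specificity", applyModels(cvres, sim$nullCohort))
  .writeTsv(specRes$perModel, file.path(outDir, "specificity_metrics.tsv"))

  ## 5-6. fingerprints, consensus features, top-percentile regions.
  ## One fingerprint per subject per fold model; the target-group maps
  ## feed the consensus, the temporal means feed symptom association.
  att <- cfg$attribution
  attOut <- stage("attribute", {
    tgt <- as.integer(att$targetClass)
    groupIdx <- which(classLabels(sim$train) == tgt)
    perFoldMaps <- vector("list", length(cvres@models))
    scores <- vector("list", length(cvres@models))
    for (f in seq_along(cvres@models)) {
      mod <- cvres@models[[f]]
      sc <- matrix(NA_real_, nSubjects(sim$train), nRegions(sim$train),
                   dimnames = list(subjectIds(sim$train),
                                   regionNames(sim$train)))
      maps <- list()
      for (i in seq_len(nSubjects(sim$train))) {
        map <- integratedGradients(mod, sim$train, i, targetClass = tgt,
                                   nSteps = att$nSteps)
        sc[i, ] <- subjectRegionScores(map)
        if (i %in% groupIdx) maps[[length(maps) + 1L]] <- map
      }
      perFoldMaps[[f]] <- maps
      scores[[f]] <- sc
    }
    tab <- aggregateGroupFeatures(perFoldMaps)
    tab <- thresholdTopFeatures(tab, pct = att$pct,
                                regionNames = regionNames(sim$train))
    .writeTsv(tab@regionHits, file.path(outDir, "region_hits.tsv"))
    list(table = tab, scores = scores)
  })
  recovered <- intersect(attOut$table@regionHits$region_index,
                         scfg@plantedRegions)

  ## 7. symptom association in both groups
  assoc <- cfg$association
  assocTables <- stage("associate", {
    tabs <- lapply(c(1L, 0L), function(g)
      associateSymptoms(sim$train, attOut$scores, assoc$domains, g,
                        alpha = assoc$alpha))
    .writeTsv(tabs[[1]], file.path(outDir, "association_group1.tsv"))
    .writeTsv(tabs[[2]], file.path(outDir, "association_group0.tsv"))
    tabs
  })
  headline <- do.call(rbind, assocTables)
  headline <- headline[!is.na(headline$q_fdr) & headline$q_fdr < assoc$alpha, ,
                       drop = FALSE]

  summaryOf <- function(s, metric)
    list(mean = s$mean[s$metric == metric], sd = s$sd[s$metric == metric])
  report$cv <- list(accuracy = summaryOf(cvres@summary, "accuracy"),
                    recall_minority = summaryOf(cvres@summary, "recall1"),
                    f1 = summaryOf(cvres@summary, "f1"))
  report$transfer <- list(accuracy = summaryOf(transferRes$summary, "accuracy"))
  report$specificity <- list(accuracy = summaryOf(specRes$summary, "accuracy"))
  report$features <- list(
    n_regions_identified = nrow(attOut$table@regionHits),
    planted_regions = scfg@plantedRegions,
    recovered_planted_regions = recovered)
  report$association_headline <- if (nrow(headline)) headline else NULL
  report$seeds <- list(synth = scfg@seed, folds = folds@seed,
                       model = mcfg@seed)
  report$margins <- cvres@models[[1]]@margins
  report$class_counts <- cvres@models[[1]]@classCounts
  report$outputs <- list(
    cohort_train = "cohort_train/manifest.tsv",
    cv_metrics = "cv_metrics.tsv", transfer_metrics = "transfer_metrics.tsv",
    specificity_metrics = "specificity_metrics.tsv",
    region_hits = "region_hits.tsv",
    association = c("association_group1.tsv", "association_group0.tsv"))
  report$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(report)
}
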