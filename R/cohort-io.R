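## On-disk cohort representation: a TSV manifest plus one TSV numeric
## matrix per subject (regions as rows, timepoints as columns, no header).
## Values are written with %.17g so a save/load round trip is bit-exact.

.MANIFEST_COLS <- c("subject_id", "timeseries_path", "class_label", "site",
                    "score_rrb", "score_social", "score_comm", "mean_fd")

#' Write a cohort to a directory
#'
#' Writes \code{manifest.tsv} (one row per subject), \code{regions.tsv}
#' (region names) and one \code{ts/<subject_id>.tsv} matrix per subject.
#' Numeric values use 17 significant digits so that
#' \code{loadCohort(saveCohort(...))} reproduces the in-memory cohort
#' bit-exactly.
#'
#' @param cohort a \code{\linkS4class{Cohort}}
#' @param dir output directory (created if needed)
#' @return The manifest path, invisibly.
#' @export
saveCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  ph <- cohort@phenotype
  ids <- ph$subject_id
  paths <- file.path("ts", paste0(ids, ".tsv"))
  for (i in seq_along(ids)) {
    m <- cohort@timeseries[[i]]
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(txt, file.path(dir, paths[i]))
  }
  man <- data.frame(subject_id = ids, timeseries_path = paths,
                    class_label = ph$class_label, site = ph$site,
                    stringsAsFactors = FALSE)
  for (col in c("score_rrb", "score_social", "score_comm", "mean_fd")) {
    man[[col]] <- if (col %in% names(ph))
      ifelse(is.na(ph[[col]]), "", sprintf("%.17g", ph[[col]])) else ""
  }
  manPath <- file.path(dir, "manifest.tsv")
  write.table(man, manPath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort@regionNames, file.path(dir, "regions.tsv"))
  invisible(manPath)
}

.readTimeseries <- function(path, id) {
  if (!file.exists(path))
    .stopf("time-series file not found for subject '%s': %s", id, path)
  lines <- readLines(path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nt <- length(rows[[1]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (r in seq_along(vals)) {
    if (length(vals[[r]]) != nt)
      .stopf("ragged matrix in %s (row %d has %d cells, expected %d)",
             path, r, length(vals[[r]]), nt)
    bad <- which(is.na(vals[[r]]) & rows[[r]] != "NA")
    if (length(bad))
      .stopf("non-numeric cell in %s, row %d, column %d ('%s')",
             path, r, bad[1], rows[[r]][bad[1]])
  }
  matrix(unlist(vals), nrow = length(vals), ncol = nt, byrow = TRUE)
}

#' Load a cohort from a manifest
#'
#' The manifest is a TSV with header and columns \code{subject_id},
#' \code{timeseries_path} (relative to the manifest's directory),
#' \code{class_label}, \code{site}, and optional \code{score_rrb},
#' \code{score_social}, \code{score_comm}, \code{mean_fd} (empty cells =
#' missing). Each time-series file is a header-less TSV numeric matrix
#' with regions as rows. Manifest row order is preserved; all subjects
#' must share the same number of regions.
#'
#' @param manifestPath path to \code{manifest.tsv}
#' @return A \code{\linkS4class{Cohort}}.
#' @export
loadCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    .stopf("manifest not found: %s", manifestPath)
  base <- dirname(manifestPath)
  man <- read.delim(manifestPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("subject_id", "timeseries_path", "class_label", "site")
  if (!all(need %in% names(man)))
    .stopf("manifest must contain columns: %s", paste(need, collapse = ", "))
  ts <- vector("list", nrow(man))
  for (i in seq_len(nrow(man)))
    ts[[i]] <- .readTimeseries(file.path(base, man$timeseries_path[i]),
                               man$subject_id[i])
  nc <- vapply(ts, nrow, integer(1))
  if (length(unique(nc)) > 1L) {
    mode <- as.integer(names(sort(table(nc), decreasing = TRUE))[1])
    bad <- man$subject_id[nc != mode]
    .stopf("inconsistent region count: expected %d, offending subjects: %s",
           mode, paste(bad, collapse = ", "))
  }
  ph <- data.frame(subject_id = man$subject_id,
                   class_label = as.integer(man$class_label),
                   site = man$site, stringsAsFactors = FALSE)
  for (col in c("score_rrb", "score_social", "score_comm", "mean_fd")) {
    if (col %in% names(man)) {
      v <- man[[col]]
      v[v == ""] <- NA_character_
      ph[[col]] <- as.numeric(v)
    }
  }
  regPath <- file.path(base, "regions.tsv")
  regions <- if (file.exists(regPath)) readLines(regPath) else NULL
  Cohort(ts, ph, regionNames = regions)
}

#' Z-score each region's time series within each subject
#'
#' Every region row is centred and scaled to unit variance (sample s.d.,
#' denominator n-1) independently per subject. Constant rows map to
#' all-zeros rather than NaN, so degenerate inputs cannot propagate
#' non-finite values into the classifier. Idempotent up to numerical
#' precision.
#'
#' @param cohort a \code{\linkS4class{Cohort}}
#' @return The normalized cohort.
#' @export
zscoreNormalize <- function(cohort) {
  ts <- lapply(cohort@timeseries, function(m) {
    .assertFinite(m, "timeseries")
    mu <- rowMeans(m)
    ctr <- m - mu
    s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
    s[s == 0] <- Inf          # constant row -> zeros
    ctr / s
  })
  out <- cohort
  out@timeseries <- ts
  validObject(out)
  out
}

#' One-hot site encoding
#'
#' Encodes each subject's acquisition site against an ordered vocabulary.
#' In-vocabulary sites get exactly one 1; sites outside the vocabulary
#' (e.g. an independent transfer cohort never seen in training) get an
#' all-zero row, which needs no retraining of the site weights.
#'
#' @param cohort a \code{\linkS4class{Cohort}}, or a character vector of
#'   site labels
#' @param vocabulary ordered site names, no duplicates; defaults to the
#'   cohort's vocabulary
#' @return list with \code{vocabulary} and \code{matrix}
#'   (subjects x vocabulary size).
#' @export
encodeSites <- function(cohort, vocabulary = NULL) {
  sitesVec <- if (is(cohort, "Cohort")) siteLabels(cohort) else as.character(cohort)
  if (is.null(vocabulary)) {
    if (!is(cohort, "Cohort"))
      .stopf("vocabulary is required when encoding a plain site vector")
    vocabulary <- siteVocabulary(cohort)
  }
  if (length(vocabulary) == 0L) .stopf("site vocabulary must be non-empty")
  if (anyDuplicated(vocabulary))
    .stopf("duplicate entries in site vocabulary: %s",
           paste(unique(vocabulary[duplicated(vocabulary)]), collapse = ", "))
  m <- matrix(0, nrow = length(sitesVec), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  hit <- match(sitesVec, vocabulary)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  list(vocabulary = vocabulary, matrix = m)
}
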