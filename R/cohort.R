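## Cohort construction, accessors and subsetting.

#' Construct a Cohort
#'
#' @param timeseries named list of numeric Nc x Nt matrices (names are
#'   subject ids) or an unnamed list ordered as \code{phenotype}.
#' @param phenotype data.frame with columns \code{subject_id},
#'   \code{class_label}, \code{site} and optional \code{score_*} /
#'   \code{mean_fd} columns.
#' @param regionNames character vector of region names; defaults to
#'   \code{R001, R002, ...}.
#' @param siteVocabulary ordered site names; defaults to the sites present,
#'   in order of first appearance.
#' @return A \code{\linkS4class{Cohort}}.
#' @export
Cohort <- function(timeseries, phenotype, regionNames = NULL,
                   siteVocabulary = NULL) {
  phenotype$subject_id <- as.character(phenotype$subject_id)
  phenotype$site <- as.character(phenotype$site)
  phenotype$class_label <- as.integer(phenotype$class_label)
  names(timeseries) <- phenotype$subject_id
  nc <- if (length(timeseries)) nrow(timeseries[[1]]) else 0L
  if (is.null(regionNames)) regionNames <- sprintf("R%03d", seq_len(nc))
  if (is.null(siteVocabulary)) siteVocabulary <- unique(phenotype$site)
  new("Cohort", timeseries = timeseries, phenotype = phenotype,
      regionNames = regionNames, siteVocabulary = siteVocabulary)
}

#' @describeIn Cohort number of subjects
#' @param cohort a \code{Cohort}
#' @export
nSubjects <- function(cohort) nrow(cohort@phenotype)

#' @describeIn Cohort number of regions Nc
#' @export
nRegions <- function(cohort) length(cohort@regionNames)

#' @describeIn Cohort subject identifiers, in order
#' @export
subjectIds <- function(cohort) cohort@phenotype$subject_id

#' @describeIn Cohort integer class labels (0/1), in subject order
#' @export
classLabels <- function(cohort) cohort@phenotype$class_label

#' @describeIn Cohort site label per subject
#' @export
siteLabels <- function(cohort) cohort@phenotype$site

#' @describeIn Cohort ordered site vocabulary
#' @export
siteVocabulary <- function(cohort) cohort@siteVocabulary

#' @describeIn Cohort region names
#' @export
regionNames <- function(cohort) cohort@regionNames

#' @describeIn Cohort the phenotype table
#' @export
phenotype <- function(cohort) cohort@phenotype

#' @describeIn Cohort one subject's regions-by-time matrix, by index or id
#' @param subject subject index or id
#' @export
getTimeseries <- function(cohort, subject) {
  if (is.character(subject)) {
    if (!subject %in% names(cohort@timeseries))
      .stopf("unknown subject id '%s'", subject)
    cohort@timeseries[[subject]]
  } else {
    cohort@timeseries[[subject]]
  }
}

#' @describeIn Cohort the full list of time-series matrices
#' @export
timeseriesList <- function(cohort) cohort@timeseries

#' Subset a cohort by subject
#'
#' Keeps the region names and site vocabulary of the parent cohort, so a
#' subset remains encodable against models trained on the full cohort.
#'
#' @param x a \code{Cohort}
#' @param i subject indices, ids or a logical vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "Cohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, subjectIds(x))
  ph <- x@phenotype[i, , drop = FALSE]
  rownames(ph) <- NULL
  new("Cohort", timeseries = x@timeseries[i], phenotype = ph,
      regionNames = x@regionNames, siteVocabulary = x@siteVocabulary)
})

setMethod("show", "Cohort", function(object) {
  nt <- vapply(object@timeseries, ncol, integer(1))
  cc <- table(factor(classLabels(object), levels = c(0L, 1L)))
  cat(sprintf(paste0(
    "Cohort: %d subjects, %d regions, %d sites\n",
    "  class counts (0/1): %d/%d\n",
    "  timepoints Nt: %s\n"),
    nSubjects(object), nRegions(object), length(object@siteVocabulary),
    cc[1], cc[2],
    if (length(nt)) sprintf("%d-%d", min(nt), max(nt)) else "none"))
})
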