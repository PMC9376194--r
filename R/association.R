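## Brain-behaviour association: Spearman correlation of per-subject region
## attribution scores against symptom-domain scores within a group, with
## Benjamini-Hochberg FDR correction across the regions-by-domains family.

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' n - 2 degrees of freedom. Missing values are dropped pairwise.
#'
#' @param x,y numeric vectors of equal length
#' @return list with \code{rho}, \code{p}, \code{n} (pairs used) and
#'   \code{degenerate} (TRUE when either vector is constant, in which
#'   case rho and p are NA).
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) .stopf("need at least 4 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} p_{(j)} m/j},
#' capped at 1, returned in input order.
#'
#' @param p vector of p-values in [0, 1] (NAs passed through)
#' @return q-values of the same length.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Region-by-domain symptom association within a group
#'
#' For every region and symptom domain, correlates (Spearman) the
#' subjects' region attribution scores — averaged across the fold models —
#' with the domain score, within the requested class only, then adjusts
#' p-values by Benjamini-Hochberg across the full regions-by-domains
#' family. Fold consistency repeats the analysis per fold model and
#' reports the fraction of models in which the row reaches q < alpha.
#'
#' @param cohort the \code{\linkS4class{Cohort}} (symptom scores come
#'   from its phenotype columns \code{score_<domain>})
#' @param regionScores list over fold models of (subjects x regions)
#'   score matrices covering all cohort subjects, as returned by
#'   \code{\link{regionScoreMatrix}}
#' @param domains domain names, e.g. \code{c("rrb", "social", "comm")}
#' @param group class label (0/1) defining the subjects analysed
#' @param alpha significance level for fold consistency (default 0.01,
#'   the headline threshold)
#' @return data.frame with columns group, domain, region, region_index,
#'   rho, p_raw, q_fdr, n, fold_consistency; one row per region x domain.
#' @export
associateSymptoms <- function(cohort, regionScores, domains, group,
                              alpha = 0.01) {
  ph <- phenotype(cohort)
  inGroup <- which(classLabels(cohort) == as.integer(group))
  if (!length(inGroup)) .stopf("no subjects in group %s", group)
  cols <- paste0("score_", domains)
  missing <- setdiff(cols, names(ph))
  if (length(missing))
    .stopf("phenotype lacks domain column(s): %s",
           paste(missing, collapse = ", "))
  k <- length(regionScores)
  avg <- Reduce(`+`, regionScores) / k
  nc <- ncol(avg)
  rn <- regionNames(cohort)

  runOne <- function(scoreMat) {
    rows <- list()
    for (d in seq_along(domains)) {
      yAll <- ph[[cols[d]]][inGroup]
      for (r in seq_len(nc)) {
        sc <- spearmanCor(scoreMat[inGroup, r], yAll)
        rows[[length(rows) + 1L]] <- data.frame(
          group = as.integer(group), domain = domains[d],
          region = rn[r], region_index = r,
          rho = sc$rho, p_raw = sc$p, n = sc$n)
      }
    }
    out <- do.call(rbind, rows)
    out$q_fdr <- bhFdr(out$p_raw)
    out
  }

  main <- runOne(avg)
  perFold <- lapply(regionScores, runOne)
  sig <- vapply(perFold, function(tb) !is.na(tb$q_fdr) & tb$q_fdr < alpha,
                logical(nrow(main)))
  main$fold_consistency <- rowMeans(matrix(sig, nrow = nrow(main)))
  main
}
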