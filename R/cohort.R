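#' Cross-patient Pearson correlation between two global metrics
#'
#' Correlates two imaging metrics across the patients of a cohort table
#' (e.g., SUVmax against ADCmean), with the two-sided t test of
#' [fitAssociation()]. No multiple-testing correction is applied anywhere in
#' the cohort analyses; p values are exploratory.
#'
#' @param cohort Data.frame with one row per patient (see [analyzeCohort()]).
#' @param x,y Column names of the two metrics.
#' @param subset Optional logical vector selecting patients.
#' @return One-row data.frame as from [fitAssociation()].
#' @export
metricCorrelation <- function(cohort, x, y, subset = NULL) {
  for (v in c(x, y))
    if (!v %in% names(cohort)) stop("unknown metric name: ", v)
  if (!is.null(subset)) cohort <- cohort[subset, , drop = FALSE]
  if (nrow(cohort) < 3)
    stop("insufficient patients after subsetting (", nrow(cohort),
         "); need >= 3")
  out <- fitAssociation(cohort[[x]], y = cohort[[y]])
  out$id <- paste(x, "vs", y)
  out
}

#' Two-sided Mann-Whitney U comparison of a metric between two groups
#'
#' Reports U for group A under the convention U_A = number of (a, b) pairs
#' with a < b, plus half of ties (U_B is also returned; U_A + U_B = nA * nB).
#' The p value is exact (null permutation distribution) when
#' \code{min(nA, nB) <= 8} and there are no ties, otherwise a normal
#' approximation with tie and continuity correction is used. Identical
#' all-tied groups return p = 1.
#'
#' @param cohort Data.frame with one row per patient.
#' @param metric Column name of the metric to compare.
#' @param groupA,groupB Logical vectors (over cohort rows) defining two
#'   disjoint non-empty groups.
#' @param exact Override the exact-vs-approximate rule (logical or NULL).
#' @return List: \code{U} (= \code{U_A}), \code{U_A}, \code{U_B}, \code{p},
#'   \code{exact}, \code{nA}, \code{nB}.
#' @export
groupCompare <- function(cohort, metric, groupA, groupB, exact = NULL) {
  if (!metric %in% names(cohort)) stop("unknown metric name: ", metric)
  if (any(groupA & groupB)) stop("groups overlap")
  a <- cohort[[metric]][groupA]
  b <- cohort[[metric]][groupB]
  mannWhitney(a, b, exact = exact)
}

#' @rdname groupCompare
#' @param a,b Numeric samples for the two groups (direct interface).
#' @export
mannWhitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  nA <- length(a); nB <- length(b)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  comb <- c(a, b)
  rk <- rank(comb)
  ties <- any(duplicated(comb))
  # rank-sum form: sum of A-ranks - nA(nA+1)/2 = #{a > b} + ties/2
  uGreater <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
  uA <- nA * nB - uGreater  # #{a < b} + ties/2
  if (is.null(exact)) exact <- min(nA, nB) <= 8 && !ties
  if (exact && ties)
    stop("exact Mann-Whitney p is only available without ties")
  if (all(comb == comb[1])) {
    p <- 1
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    p <- ht$p.value
    if (!is.finite(p)) p <- 1
  }
  list(U = uA, U_A = uA, U_B = uGreater, p = min(p, 1), exact = exact,
       nA = nA, nB = nB)
}

#' Correlation between the per-tumor voxel SUV-ADC relationship and MTV
#'
#' Pearson correlation, across patients, of the per-tumor voxel correlation
#' coefficient r against the metabolic tumor volume.
#'
#' @param cohort Data.frame with columns \code{r} (per-tumor voxel Pearson r)
#'   and \code{MTV} (mL).
#' @param subset Optional logical vector selecting patients.
#' @return One-row data.frame as from [fitAssociation()].
#' @export
correlationVsVolume <- function(cohort, subset = NULL) {
  metricCorrelation(cohort, "MTV", "r", subset = subset)
}

#' Summarize the composition of a clinical cohort table
#'
#' Tabulates categorical clinical variables (histology, grade, treatment when
#' present) as counts and percentages of the cohort, percentages rounded to
#' one decimal.
#'
#' @param clinical Data.frame with one row per patient.
#' @param variables Character vector of columns to summarize; defaults to the
#'   intersection of \code{c("histology", "grade", "treatment")} with the
#'   available columns.
#' @return Data.frame with columns \code{variable}, \code{level}, \code{n},
#'   \code{pct}.
#' @export
summarizeCohort <- function(clinical,
                            variables = intersect(
                              c("histology", "grade", "treatment"),
                              names(clinical))) {
  if (anyDuplicated(clinical$id))
    stop("patient ids must be unique")
  N <- nrow(clinical)
  rows <- lapply(variables, function(v) {
    tab <- table(clinical[[v]])
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / N, 1))
  })
  do.call(rbind, rows)
}
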