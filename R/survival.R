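#' Dichotomize a metric at its cohort median
#'
#' Patients with metric value less than or equal to the median are assigned
#' to \code{"low"}, the rest to \code{"high"}. For even n the median is the
#' midpoint of the two central order statistics, so tied values straddling
#' the median all land in the low group (the tie rule is explicit because it
#' changes group sizes).
#'
#' @param values Numeric vector of a metric, one value per patient (or a
#'   cohort data.frame together with \code{metric}).
#' @param metric Optional column name when \code{values} is a data.frame.
#' @return Factor with levels \code{c("low", "high")}.
#' @examples
#' dichotomizeByMedian(c(1, 2, 2, 3))  # median 2: low, low, low, high
#' @export
dichotomizeByMedian <- function(values, metric = NULL) {
  if (is.data.frame(values)) {
    if (is.null(metric)) stop("supply the metric column name")
    if (!metric %in% names(values)) stop("unknown metric name: ", metric)
    values <- values[[metric]]
  }
  if (anyNA(values)) stop("metric must be present for all patients")
  if (length(unique(values)) == 1L)
    stop("all metric values identical; median split is degenerate")
  med <- stats::median(values)
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around \code{survival::survfit} (subjects censored at t
#' remain at risk for events at t, the standard convention).
#'
#' @param time Follow-up times (months), non-negative.
#' @param event Event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param group Optional grouping factor for stratified curves.
#' @return A \code{survfit} object.
#' @seealso [survivalAt()] to read the curve at a time point.
#' @export
kaplanMeier <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative follow-up times")
  event <- as.integer(as.logical(event))
  if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1)
  } else {
    df <- data.frame(time = time, event = event, group = group)
    survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
}

#' Survival probability of a Kaplan-Meier curve at a time point
#'
#' @param fit A single-group \code{survfit} object from [kaplanMeier()].
#' @param t Time at which to evaluate the step function.
#' @return S(t), with S = 1 before the first event.
#' @export
survivalAt <- function(fit, t) {
  steps <- c(1, fit$surv)[findInterval(t, fit$time) + 1]
  unname(steps)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at every distinct event time the observed
#' number of events in group 1 is compared with its hypergeometric
#' expectation given the risk sets; the squared summed difference over the
#' summed hypergeometric variance is referred to a chi-square distribution
#' with 1 df. Censored subjects remain at risk at their censoring time.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level factor/vector of group labels.
#' @return List: \code{chi2}, \code{p}, \code{observed} and \code{expected}
#'   (per group, in level order).
#' @export
logrankTest <- function(time, event, group) {
  event <- as.logical(event)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly 2 groups required")
  if (any(table(group) == 0)) stop("one group is empty")
  if (any(time < 0)) stop("negative follow-up times")
  g1 <- group == levels(group)[1]
  evTimes <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0; O2 <- 0
  for (t in evTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    O <- O + d1
    O2 <- O2 + (d - d1)
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    chi2 <- 0
  } else {
    chi2 <- (O - E)^2 / V
  }
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p,
       observed = stats::setNames(c(O, O2), levels(group)),
       expected = stats::setNames(c(E, O + O2 - E), levels(group)))
}

#' Univariate Cox proportional hazards for a binary group
#'
#' Partial-likelihood fit via \code{survival::coxph} with Breslow handling of
#' tied event times (Efron available). Hazard ratio is for the second factor
#' level versus the first (high vs low after [dichotomizeByMedian()]), with a
#' 95\% Wald interval and Wald p value. Monotone partial likelihood (all
#' events in one group) is detected as |beta| > 10 and reported as a
#' divergence diagnostic instead of a spurious finite hazard ratio.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level factor/vector (reference level first).
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return List: \code{hr}, \code{ci} (length 2), \code{p}, \code{beta},
#'   \code{se}, \code{scoreChi2} (score test at beta = 0), \code{diverged}.
#' @export
coxUnivariate <- function(time, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  event <- as.integer(as.logical(event))
  if (sum(event) == 0) stop("no events; Cox model undefined")
  group <- factor(group)
  if (nlevels(group) != 2) stop("binary group required")
  df <- data.frame(time = time, event = event, group = group)
  # coxph's infinite-coefficient warning is superseded by our own
  # monotone-likelihood diagnostic below
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = df,
                    ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  score <- unname(fit$score)
  if (!is.finite(beta) || abs(beta) > 10) {
    warning("monotone partial likelihood (all events in one group?); ",
            "hazard ratio diverges")
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                beta = beta, se = se, scoreChi2 = score, diverged = TRUE))
  }
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * 1.96 * se),
       p = 2 * stats::pnorm(-abs(beta / se)),
       beta = beta, se = se, scoreChi2 = score, diverged = FALSE)
}

#' Median-dichotomized survival analysis over several imaging metrics
#'
#' For each metric: dichotomize at the cohort median, fit the univariate Cox
#' model and run the log-rank test, yielding one row per metric (hazard ratio
#' high vs low, 95\% CI, Wald p, log-rank p). This reproduces the shape of a
#' per-endpoint biomarker stratification table.
#'
#' @param cohort Data.frame with the metric columns plus follow-up columns.
#' @param metrics Character vector of metric column names.
#' @param timeCol,eventCol Names of the follow-up time / event columns
#'   (defaults: disease-free survival).
#' @return Data.frame: \code{metric}, \code{hr}, \code{ciLow}, \code{ciHigh},
#'   \code{waldP}, \code{logrankP}, \code{diverged}.
#' @export
survivalTable <- function(cohort,
                          metrics = c("ADCmean", "ADC_TM", "SUVmax", "MTV", "r"),
                          timeCol = "dfs_time", eventCol = "dfs_event") {
  rows <- lapply(metrics, function(m) {
    grp <- dichotomizeByMedian(cohort, m)
    cx <- suppressWarnings(
      coxUnivariate(cohort[[timeCol]], cohort[[eventCol]], grp))
    lr <- logrankTest(cohort[[timeCol]], cohort[[eventCol]], grp)
    data.frame(metric = m, hr = cx$hr, ciLow = cx$ci[1], ciHigh = cx$ci[2],
               waldP = cx$p, logrankP = lr$p, diverged = cx$diverged)
  })
  do.call(rbind, rows)
}
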