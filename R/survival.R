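# Kaplan-Meier curves, two-group log-rank tests, and median-split
# stratification of a cohort by signature expression.

#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#' Subjects censored at an event time are counted at risk for that event
#' (censorings follow events at tied times, the standard convention).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`. The curve starts at 1,
#'   is non-increasing, and equals the empirical survival function when
#'   nothing is censored.
#' @examples
#' km_curve(c(1, 2), c(1, 1))  # S(1) = 0.5, S(2) = 0
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) stopf("km_curve: times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("km_curve: event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time,
             n_risk = fit$n.risk,
             n_event = fit$n.event,
             n_censor = fit$n.censor,
             survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank test: at each distinct event time
#' the observed events per group are compared with their hypergeometric
#' expectation given the at-risk sets. Cohorts with no events at all return
#' statistic 0 and p = 1 with a warning.
#'
#' @param time,event As in [km_curve()].
#' @param group Two-level group labels aligned with `time`.
#' @return A list: `statistic` (chi-square, 1 df), `p_value`, `n` per group,
#'   `observed` and `expected` event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stopf("logrank_test: exactly two groups required")
  if (any(table(group) == 0)) stopf("logrank_test: both groups must be non-empty")
  if (sum(event) == 0) {
    warnf("logrank_test: no events in either group")
    return(list(statistic = 0, p_value = 1,
                n = table(group),
                observed = c(0, 0), expected = c(0, 0)))
  }
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sdf$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = sdf$n,
       observed = sdf$obs,
       expected = sdf$exp)
}

#' Stratify a cohort by mean signature expression
#'
#' Per-subject mean expression over the signature's up-genes, then a median
#' split: strictly above the median is `"high"`, at or below is `"low"`
#' (the same boundary rule as [classify_by_median()]). All-equal means give
#' all-low with a warning.
#'
#' @param expr Gene-by-subject expression matrix.
#' @param sig A [gene_signature()]; only its up-genes are used (the
#'   multi-gene survival grouping operates on a single gene list).
#' @param cohort Data.frame with columns `subject_id`, `time`, `event`.
#' @return The cohort with a `group` column (`"high"`/`"low"`) and a
#'   `signature_mean` column.
#' @export
stratify_by_signature <- function(expr, sig, cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "time", "event") %in% names(cohort)))
  missing <- setdiff(cohort$subject_id, colnames(expr))
  if (length(missing)) stopf("stratify_by_signature: %d subject(s) missing from expression", length(missing))
  genes <- intersect(sig$up_genes, rownames(expr))
  if (!length(genes)) stopf("stratify_by_signature: no signature gene present in expression")
  if (length(genes) < length(sig$up_genes)) {
    warnf("stratify_by_signature: %d signature gene(s) absent from expression",
          length(sig$up_genes) - length(genes))
  }
  mu <- colMeans(expr[genes, cohort$subject_id, drop = FALSE])
  med <- stats::median(mu)
  if (all(mu == mu[1])) warnf("stratify_by_signature: all means identical; every subject labelled low")
  cohort$signature_mean <- as.numeric(mu)
  cohort$group <- ifelse(mu > med, "high", "low")
  cohort
}
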