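#' Median split of a cohort by a predictor
#'
#' Stratifies survival records into a low group (predictor <= median)
#' and a high group (predictor > median); ties at the median go low
#' (deterministic rule). The median is the standard midpoint of the
#' sorted values.
#'
#' @param records data.frame with at least a `predictor` column (e.g.
#'   per-patient MATV in mL); any other columns are carried along.
#' @return list with `low`, `high` (row subsets) and `median`.
#' @export
medianSplit <- function(records) {
  stopifnot(is.data.frame(records), "predictor" %in% names(records),
            nrow(records) >= 2L)
  p <- records$predictor
  if (length(unique(p)) == 1L)
    stop("all predictor values identical; no median split possible")
  med <- stats::median(p)
  list(low = records[p <= med, , drop = FALSE],
       high = records[p > med, , drop = FALSE],
       median = med)
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator over the distinct observed times. Overall
#' survival is the time from baseline PET to death (event = 1) or last
#' follow-up (event = 0, censored).
#'
#' @param time numeric vector of follow-up times (months), >= 0.
#' @param event 0/1 vector; 1 = died.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, starting from 1 before the first
#'   event).
#' @export
kaplanMeier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test with the hypergeometric variance;
#' two-sided p value from a chi-square distribution with 1 df.
#'
#' @param time,event follow-up months and 0/1 death indicators.
#' @param group two-level grouping vector (e.g. "low"/"high" MATV).
#' @return list with `chisq`, `p`, `n_events`.
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (length(unique(group)) != 2L)
    stop("log-rank test needs exactly 2 groups")
  if (sum(event) == 0)
    stop("no events in either group; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ factor(group))
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' ROC curve and AUC of a predictor for vital status
#'
#' Area under the ROC curve of a continuous predictor (e.g. MATV)
#' against the binary vital status at end of follow-up (died vs
#' censored-alive). Ties are handled by midranks, so the AUC equals the
#' normalized Mann-Whitney U statistic and is invariant under strictly
#' monotone transforms of the predictor.
#'
#' @param predictor numeric vector.
#' @param outcome 0/1 vector; 1 = died. Both classes must be present.
#' @return list with `auc` and `roc` (data.frame of `threshold`, `tpr`,
#'   `fpr`, one row per candidate cut at each distinct predictor value,
#'   classifying `predictor >= threshold` as predicted death).
#' @export
rocAuc <- function(predictor, outcome) {
  stopifnot(length(predictor) == length(outcome),
            all(outcome %in% c(0, 1)))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes (died / alive) must be present")
  r <- rank(predictor)  # midranks for ties
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(predictor))
  roc <- do.call(rbind, lapply(cuts, function(ct) {
    pred <- predictor >= ct
    data.frame(threshold = ct,
               tpr = sum(pred & outcome == 1) / n1,
               fpr = sum(pred & outcome == 0) / n0)
  }))
  roc <- rbind(data.frame(threshold = Inf, tpr = 0, fpr = 0), roc)
  list(auc = auc, roc = roc[order(roc$fpr, roc$tpr), ])
}

#' Survival association of a per-patient biomarker
#'
#' The full stratified analysis applied to each segmentation method:
#' median split of the cohort by the predictor, Kaplan-Meier estimates
#' per group, log-rank test between the groups, and ROC/AUC of the
#' predictor for vital status at end of follow-up.
#'
#' @param records data.frame with columns `months`, `event` (0/1) and
#'   `predictor` (e.g. MATV mL).
#' @return list with `median`, `logrank` (see [logrankTest()]), `auc`
#'   (numeric), `km_low`, `km_high` (see [kaplanMeier()]), `roc`.
#' @export
survivalAssociation <- function(records) {
  stopifnot(all(c("months", "event", "predictor") %in% names(records)))
  sp <- medianSplit(records)
  grp <- ifelse(records$predictor <= sp$median, "low", "high")
  lr <- logrankTest(records$months, records$event, grp)
  ra <- rocAuc(records$predictor, records$event)
  list(median = sp$median, logrank = lr, auc = ra$auc,
       km_low = kaplanMeier(sp$low$months, sp$low$event),
       km_high = kaplanMeier(sp$high$months, sp$high$event),
       roc = ra$roc)
}
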