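#' Kaplan-Meier curve for a single group
#'
#' Product-limit estimate (via [survival::survfit()]) with the median
#' reported as the smallest observed time at which the survival function
#' drops to 0.5 or below, `NA` if it never does. All events tied at a time
#' are processed in one risk-set step; subjects censored at that time remain
#' at risk for it.
#'
#' @param time Positive times (months).
#' @param event 1 = event, 0 = censored.
#' @return A list with `curve` (tibble `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`) and `median`.
#' @export
km_curve <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  med <- curve$time[curve$surv <= 0.5]
  list(curve = curve, median = if (length(med)) min(med) else NA_real_)
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' Standard log-rank statistic: the sum over event times of observed minus
#' expected events in the first group, with hypergeometric variance, referred
#' to chi-square on 1 df (via [survival::survdiff()]).
#'
#' @inheritParams km_curve
#' @param group Two-level factor/vector assigning each subject to a group.
#' @return A list with `chi_square`, `p`, `observed`, `expected` (both in
#'   group-level order).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) cx3_abort("`group` must have exactly two levels")
  if (sum(event) == 0) cx3_abort("log-rank test undefined without any events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- sd$chisq
  list(
    chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE),
    observed = unname(sd$obs), expected = unname(sd$exp),
    groups = levels(droplevels(group))
  )
}

#' Mantel-Haenszel hazard ratio from log-rank tables
#'
#' `HR = (O_A / E_A) / (O_B / E_B)` with confidence interval
#' `exp(log HR +/- z * sqrt(1/E_A + 1/E_B))`, where O and E are the log-rank
#' observed and expected event counts. `hr < 1` means the first group level
#' has the lower hazard. This is the log-rank (Mantel-Haenszel) hazard ratio;
#' a Cox model is deliberately not fitted here.
#'
#' @inheritParams logrank_test
#' @param level Confidence level, default 0.95.
#' @return A list with `hr`, `lower`, `upper`, plus the log-rank `p`.
#' @export
mh_hazard_ratio <- function(time, event, group, level = 0.95) {
  lr <- logrank_test(time, event, group)
  ea <- lr$expected[1]; eb <- lr$expected[2]
  if (ea <= 0 || eb <= 0) cx3_abort("zero expected events in a group; hazard ratio undefined")
  hr <- (lr$observed[1] / ea) / (lr$observed[2] / eb)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / ea + 1 / eb)
  list(hr = hr, lower = exp(log(hr) - z * se), upper = exp(log(hr) + z * se),
       p = lr$p, groups = lr$groups)
}

#' Compare survival between score-defined groups
#'
#' Splits patients by their score decision at a landmark (>= `cutoff` is
#' "high") and reports the KM curve and median per group, the log-rank test,
#' and the Mantel-Haenszel hazard ratio of high vs low.
#'
#' @param scores Output of [score_cohort()].
#' @param metadata Cohort metadata with `patient_id` and the endpoint columns.
#' @param endpoint `"pfs"` or `"os"`.
#' @param landmark Landmark week whose decision defines the groups.
#' @param cutoff Used only for labelling; decisions come from `scores`.
#' @param level Confidence level.
#' @return A list with `groups` (named list of [km_curve()] results),
#'   `logrank`, `hazard_ratio`.
#' @export
survival_by_score <- function(scores, metadata, endpoint = c("pfs", "os"),
                              landmark = 12, cutoff = 20, level = 0.95) {
  endpoint <- match.arg(endpoint)
  dec <- scores[scores$landmark == landmark & scores$evaluable, ]
  if (nrow(dec) == 0) cx3_abort(sprintf("no evaluable patients at landmark %s", landmark))
  d <- dplyr::inner_join(dec[, c("patient_id", "decision")], metadata, by = "patient_id")
  time <- d[[paste0(endpoint, "_months")]]
  event <- d[[paste0(endpoint, "_event")]]
  grp <- factor(ifelse(d$decision, "high", "low"), levels = c("high", "low"))
  if (nlevels(droplevels(grp)) < 2) {
    cx3_abort("only one score group present; no comparison possible")
  }
  list(
    endpoint = endpoint, landmark = landmark, cutoff = cutoff,
    groups = lapply(split(seq_along(time), grp), function(ix) {
      km_curve(time[ix], event[ix])
    }),
    logrank = logrank_test(time, event, grp),
    hazard_ratio = mh_hazard_ratio(time, event, grp, level)
  )
}

check_surv <- function(time, event) {
  if (length(time) < 1 || any(!is.finite(time)) || any(time <= 0)) {
    cx3_abort("`time` must be positive and finite")
  }
  if (length(event) != length(time) || !all(event %in% c(0, 1))) {
    cx3_abort("`event` must be 0/1 and match `time`")
  }
  invisible(TRUE)
}
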