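#' Percent change from baseline
#'
#' The elementary quantity behind the CX3CR1 score:
#' `100 * (followup - baseline) / baseline`, on the percent scale the
#' frequencies are reported on. The score is invariant under rescaling all of
#' a patient's frequencies by a positive constant.
#'
#' @param baseline_pct Baseline frequency, percent; must be > 0.
#' @param followup_pct Follow-up frequency, percent.
#' @return Signed percent change (vectorized).
#' @examples
#' percent_change(30, 36) # 20
#' @export
percent_change <- function(baseline_pct, followup_pct) {
  if (any(!is.finite(baseline_pct)) || any(baseline_pct <= 0)) {
    cx3_abort("`baseline_pct` must be positive: percent change from a zero baseline is undefined")
  }
  100 * (followup_pct - baseline_pct) / baseline_pct
}

#' Maximal percent change by a landmark week
#'
#' The largest percent change from baseline over all post-baseline
#' measurements taken at or before `landmark_week` (any sample with
#' `0 < week <= landmark_week` counts). Returns `NA` when the patient has no
#' eligible post-baseline measurement; such patients are unevaluable at that
#' landmark and are excluded from its diagnostics.
#'
#' @param weeks Measurement weeks (must include week 0 exactly once).
#' @param values Frequencies (percent) matching `weeks`.
#' @param landmark_week Positive landmark week.
#' @return The maximal percent change, or `NA_real_` if unevaluable.
#' @examples
#' max_score_by_week(c(0, 3, 6, 9), c(30, 33, 27, 39), 6) # 10
#' @export
max_score_by_week <- function(weeks, values, landmark_week) {
  if (landmark_week <= 0) cx3_abort("`landmark_week` must be positive")
  base_idx <- which(weeks == 0)
  if (length(base_idx) != 1) {
    cx3_abort("`weeks` must contain exactly one baseline (week 0) measurement")
  }
  eligible <- weeks > 0 & weeks <= landmark_week
  if (!any(eligible)) return(NA_real_)
  max(percent_change(values[base_idx], values[eligible]))
}

#' Dichotomize a score at a cutoff
#'
#' Positive iff `score >= cutoff`: the rule is "an increase of at least
#' `cutoff` percent", so the boundary is inclusive.
#'
#' @param score Signed percent score(s).
#' @param cutoff Positivity cutoff, default 20.
#' @return Logical vector (`TRUE` = positive), `NA` where `score` is `NA`.
#' @export
classify_score <- function(score, cutoff = 20) {
  score >= cutoff
}

#' Score a cohort at landmark weeks
#'
#' Computes, for every patient and landmark, the maximal percent change from
#' baseline (the CX3CR1 score), an evaluability flag, and the binary decision
#' at `cutoff`. The maximal change is non-decreasing in the landmark week for
#' every patient.
#'
#' @param cohort A `cx3_cohort` (or any list with a `measurements` tibble
#'   holding `patient_id`, `week`, `cx3cr1_pct`).
#' @param landmarks Landmark weeks, default `c(3, 6, 9, 12)`.
#' @param cutoff Positivity cutoff on the percent-change scale, default 20.
#' @return A tibble with one row per patient and landmark: `patient_id`,
#'   `landmark`, `baseline_pct`, `max_score`, `evaluable`, `decision`.
#' @examples
#' scores <- score_cohort(reference_cohort())
#' dplyr::count(scores, landmark, decision)
#' @export
score_cohort <- function(cohort, landmarks = c(3, 6, 9, 12), cutoff = 20) {
  m <- cohort$measurements
  if (any(landmarks <= 0)) cx3_abort("`landmarks` must be positive weeks")
  split_m <- split(m[, c("week", "cx3cr1_pct")], m$patient_id)
  rows <- lapply(names(split_m), function(pid) {
    dat <- split_m[[pid]]
    base <- dat$cx3cr1_pct[dat$week == 0]
    sc <- vapply(landmarks, function(L) {
      max_score_by_week(dat$week, dat$cx3cr1_pct, L)
    }, numeric(1))
    tibble(
      patient_id = pid, landmark = landmarks, baseline_pct = base,
      max_score = sc, evaluable = !is.na(sc),
      decision = classify_score(sc, cutoff)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$landmark, .data$patient_id)
}
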