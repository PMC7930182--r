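#' Deterministic 36-patient reference classification fixture
#'
#' Reconstructs, as an explicit cohort, the published per-week diagnostic
#' performance of the CX3CR1 score in the 36-patient NSCLC anti-PD-1 cohort
#' the score was developed in: 13 responders and 23 non-responders; week-3
#' samples available for 27 patients (10 responders, 17 non-responders); and
#' per-landmark score positivity whose confusion counts at the >= 20% cutoff
#' are exactly
#'
#' * week 3 (n = 27): TP 5, FP 1, FN 5, TN 16
#' * week 6 (n = 36): TP 8, FP 3, FN 5, TN 20
#' * week 9 (n = 36): TP 11, FP 3, FN 2, TN 20
#' * week 12 (n = 36): TP 12, FP 3, FN 1, TN 20
#'
#' together with a PD-L1 TPS >= 50% baseline rule giving TP 12, FP 19, FN 1,
#' TN 4. Only the marginal counts are published; the patient-to-indicator
#' assignment is non-unique, and is fixed deterministically by sorted patient
#' index (the earliest patients turn positive earliest). All assignments give
#' identical confusion counts. Positivity is monotone non-decreasing in the
#' landmark week by construction: a patient first positive at week `w` has
#' measurements with +30% change from week `w` on and +5% (or -5%) before.
#'
#' The survival columns are synthetic plumbing (patient-level times were never
#' published): deterministic values consistent with rule-positive patients
#' doing better, provided only so the full pipeline runs end to end.
#'
#' @return A `cx3_cohort` list with `measurements` and `metadata`; `metadata`
#'   carries `responder`, `pdl1_tps`, and synthetic survival columns.
#' @export
reference_cohort <- function() {
  n <- 36L
  id <- sprintf("P%02d", seq_len(n))
  responder <- c(rep(TRUE, 13), rep(FALSE, 23))

  # first landmark week at which each patient's score turns positive (Inf = never)
  first_pos <- rep(Inf, n)
  first_pos[1:5] <- 3    # responders positive from week 3
  first_pos[6:8] <- 6
  first_pos[9:11] <- 9
  first_pos[12] <- 12
  first_pos[14] <- 3     # non-responders contributing the false positives
  first_pos[15:16] <- 6

  # week-3 sample availability: 10 responders, 17 non-responders
  wk3_avail <- c(rep(TRUE, 10), rep(FALSE, 3), rep(TRUE, 17), rep(FALSE, 6))

  baseline <- 30
  weeks <- c(3L, 6L, 9L, 12L)
  meas <- lapply(seq_len(n), function(i) {
    w <- if (wk3_avail[i]) weeks else weeks[-1]
    flat <- if (i %% 2 == 0) 0.95 else 1.05  # sub-threshold wiggle, sign varies
    val <- ifelse(w >= first_pos[i], baseline * 1.30, baseline * flat)
    tibble(patient_id = id[i], week = c(0L, w), cx3cr1_pct = c(baseline, val))
  })
  measurements <- dplyr::bind_rows(meas)

  # PD-L1 TPS >= 50% rule: 12/13 responders and 19/23 non-responders high
  pdl1_high <- c(rep(TRUE, 12), FALSE, rep(TRUE, 19), rep(FALSE, 4))

  rule_pos <- is.finite(first_pos)
  metadata <- tibble(
    patient_id = id,
    response = c("CR", rep("PR", 12), rep("SD", 12), rep("PD", 11)),
    responder = responder,
    pdl1_tps = ifelse(pdl1_high, 80, 10),
    pfs_months = ifelse(rule_pos, 20 + seq_len(n) %% 8, 3 + seq_len(n) %% 5),
    pfs_event = ifelse(rule_pos, ifelse(seq_len(n) %% 3 == 0, 1L, 0L), 1L),
    os_months = ifelse(rule_pos, 24 + seq_len(n) %% 10, 6 + seq_len(n) %% 6),
    os_event = ifelse(rule_pos, ifelse(seq_len(n) %% 4 == 0, 1L, 0L), 1L)
  )
  new_cohort(measurements, metadata)
}
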