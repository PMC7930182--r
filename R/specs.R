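#' Specification of a synthetic anti-PD-1 cohort
#'
#' Bundles and validates the parameters of the synthetic clinical cohort
#' generator ([simulate_cohort()]). Defaults describe the 36-patient NSCLC
#' setting the score was developed in: a baseline CX3CR1+ fraction with median
#' 32.3% on the range 6.1--76.3%, a 13/36 responder fraction, the
#' 0/3/6/9/12-week visit schedule with a 27/36 week-3 sample availability, and
#' survival medians of 19.5 vs 5.7 months (PFS) and unreached vs 8.6 months
#' (OS) for rule-positive vs rule-negative patients.
#'
#' `responder_effect` gives the arm centers of the multiplicative trajectory
#' factor: a patient whose factor is `m` ramps linearly from baseline to
#' `baseline * m` at the last visit week, so the expected maximal percent
#' change equals `100 * (m - 1)`. `noise_cv` is the coefficient of variation
#' of the patient-level lognormal spread around the arm center (the dominant,
#' biological variance component); `visit_jitter_cv` is the small per-visit
#' measurement repeatability of the flow assay.
#'
#' @param n_patients Number of patients.
#' @param responder_fraction Probability a patient is a responder (CR/PR).
#' @param baseline_median_pct Target median of the baseline CX3CR1+ percentage.
#' @param baseline_range_pct Length-2 support `(low, high)` of the baseline
#'   percentage, percent scale.
#' @param visit_weeks Strictly increasing non-negative integers starting at 0.
#' @param week3_missing_fraction Probability the first post-baseline visit
#'   sample is missing.
#' @param responder_effect Named list with multiplicative trajectory factor
#'   centers `responder` and `nonresponder`.
#' @param noise_cv Coefficient of variation of the patient-level trajectory
#'   factor around its arm center.
#' @param visit_jitter_cv Per-visit multiplicative measurement jitter (cv).
#' @param median_pfs_months,median_os_months Length-2 `(positive, negative)`
#'   exponential survival medians, in months, indexed by the realized
#'   rule-positive status (maximal percent change at least the 20% cutoff).
#' @param max_followup_months Administrative censoring horizon, months.
#' @param seed Integer seed; identical seeds give identical cohorts.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_patients = 36,
                        responder_fraction = 13 / 36,
                        baseline_median_pct = 32.3,
                        baseline_range_pct = c(6.1, 76.3),
                        visit_weeks = c(0L, 3L, 6L, 9L, 12L),
                        week3_missing_fraction = 1 - 27 / 36,
                        responder_effect = list(responder = 1.35, nonresponder = 1.05),
                        noise_cv = 0.15,
                        visit_jitter_cv = 0.03,
                        median_pfs_months = c(positive = 19.5, negative = 5.7),
                        median_os_months = c(positive = 40, negative = 8.6),
                        max_followup_months = 35.5,
                        seed = 1L) {
  spec <- list(
    n_patients = n_patients, responder_fraction = responder_fraction,
    baseline_median_pct = baseline_median_pct,
    baseline_range_pct = baseline_range_pct, visit_weeks = as.integer(visit_weeks),
    week3_missing_fraction = week3_missing_fraction,
    responder_effect = responder_effect, noise_cv = noise_cv,
    visit_jitter_cv = visit_jitter_cv,
    median_pfs_months = median_pfs_months, median_os_months = median_os_months,
    max_followup_months = max_followup_months, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  chk_count(spec$n_patients, "n_patients")
  chk_prob(spec$responder_fraction, "responder_fraction")
  chk_prob(spec$week3_missing_fraction, "week3_missing_fraction")
  rng <- spec$baseline_range_pct
  if (length(rng) != 2 || !is.numeric(rng) || rng[1] <= 0 || rng[2] > 100 ||
      !(rng[1] < spec$baseline_median_pct && spec$baseline_median_pct < rng[2])) {
    cx3_abort(paste0(
      "`baseline_range_pct` must be (low, high) within (0, 100] with ",
      "low < baseline_median_pct < high"
    ))
  }
  w <- spec$visit_weeks
  if (length(w) < 2 || w[1] != 0L || any(diff(w) <= 0) || any(w < 0)) {
    cx3_abort("`visit_weeks` must be strictly increasing, start at 0, and include a follow-up week")
  }
  eff <- spec$responder_effect
  if (!is.list(eff) || is.null(eff$responder) || is.null(eff$nonresponder) ||
      eff$responder <= 0 || eff$nonresponder <= 0) {
    cx3_abort("`responder_effect` must list positive factors `responder` and `nonresponder`")
  }
  if (!is.numeric(spec$noise_cv) || spec$noise_cv < 0) cx3_abort("`noise_cv` must be >= 0")
  if (!is.numeric(spec$visit_jitter_cv) || spec$visit_jitter_cv < 0) {
    cx3_abort("`visit_jitter_cv` must be >= 0")
  }
  for (fld in c("median_pfs_months", "median_os_months")) {
    m <- spec[[fld]]
    if (length(m) != 2 || any(!is.finite(m)) || any(m <= 0)) {
      cx3_abort(sprintf("`%s` must be two positive medians (positive, negative)", fld))
    }
  }
  if (!is.numeric(spec$max_followup_months) || spec$max_followup_months <= 0) {
    cx3_abort("`max_followup_months` must be > 0")
  }
  if (length(spec$seed) != 1 || is.na(spec$seed)) cx3_abort("`seed` must be a single integer")
  spec
}

#' Specification of a synthetic TCR repertoire
#'
#' Parameters for [simulate_repertoire()]: a clonally expanded repertoire with
#' power-law clone sizes (count of the rank-`r` clone proportional to
#' `r^-power_exponent`), CDR3 amino-acid sequences of the usual
#' `CASS...F` form, and nucleotide sequences obtained by random synonymous
#' reverse translation (so the nucleotide key is unique per clonotype).
#'
#' @param n_clones Number of unique clonotypes (>= 1).
#' @param total_templates Total template count, at least `n_clones`.
#' @param power_exponent Positive power-law exponent of the clone-size decay.
#' @param shared_fraction Fraction of clonotypes shared with a paired
#'   repertoire (used by [simulate_paired_repertoires()]).
#' @param cdr3_length_range Length-2 amino-acid length range, minimum >= 6.
#' @param nonproductive_fraction Fraction of additional non-productive
#'   (status `"Out"`) template mass spiked in, 0 by default.
#' @param seed Integer seed.
#'
#' @return An object of class `repertoire_spec`.
#' @export
repertoire_spec <- function(n_clones = 200,
                            total_templates = 20000,
                            power_exponent = 1.2,
                            shared_fraction = 0,
                            cdr3_length_range = c(12, 17),
                            nonproductive_fraction = 0,
                            seed = 1L) {
  spec <- list(
    n_clones = as.integer(n_clones), total_templates = as.integer(total_templates),
    power_exponent = power_exponent, shared_fraction = shared_fraction,
    cdr3_length_range = as.integer(cdr3_length_range),
    nonproductive_fraction = nonproductive_fraction, seed = as.integer(seed)
  )
  class(spec) <- "repertoire_spec"
  validate_repertoire_spec(spec)
}

validate_repertoire_spec <- function(spec) {
  chk_count(spec$n_clones, "n_clones")
  chk_count(spec$total_templates, "total_templates")
  if (spec$total_templates < spec$n_clones) {
    cx3_abort("`total_templates` must be at least `n_clones`")
  }
  if (!is.numeric(spec$power_exponent) || spec$power_exponent <= 0) {
    cx3_abort("`power_exponent` must be > 0")
  }
  chk_prob(spec$shared_fraction, "shared_fraction")
  chk_prob(spec$nonproductive_fraction, "nonproductive_fraction")
  lr <- spec$cdr3_length_range
  if (length(lr) != 2 || lr[1] < 6 || lr[2] < lr[1]) {
    cx3_abort("`cdr3_length_range` must be (min, max) with min >= 6")
  }
  if (length(spec$seed) != 1 || is.na(spec$seed)) cx3_abort("`seed` must be a single integer")
  spec
}

chk_count <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    cx3_abort(sprintf("`%s` must be a positive integer", name))
  }
  invisible(x)
}

chk_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    cx3_abort(sprintf("`%s` must be a proportion in [0, 1]", name))
  }
  invisible(x)
}
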