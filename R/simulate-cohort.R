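#' Simulate a longitudinal anti-PD-1 biomarker cohort
#'
#' Generates a synthetic cohort with the structure the score analysis assumes:
#' one baseline CX3CR1+ percentage per patient drawn from a logit-normal
#' distribution rescaled to `baseline_range_pct` whose median equals
#' `baseline_median_pct` exactly in distribution; per-patient multiplicative
#' trajectory factors lognormal around the arm center (`responder_effect`,
#' cv `noise_cv`); measured values ramping linearly from baseline toward
#' `baseline * factor` at the last visit, times a small per-visit lognormal
#' jitter, truncated to `[0, 100]`; week-3 samples missing at random; and
#' exponential PFS/OS arms indexed by the realized rule-positive status
#' (maximal percent change >= 20) with independent uniform censoring on
#' `[0, max_followup_months]`.
#'
#' Responders are labelled CR or PR, non-responders SD or PD. With
#' `noise_cv = 0` and `visit_jitter_cv = 0` every responder's maximal percent
#' change equals `100 * (responder_effect$responder - 1)` exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cx3_cohort` with tibbles
#'   `measurements` (`patient_id`, `week`, `cx3cr1_pct`) and `metadata`
#'   (`patient_id`, `response`, `pdl1_tps`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`) plus the logical truth column `responder`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_patients = 20, seed = 7))
#' head(coh$measurements)
#' @export
simulate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  id <- sprintf("P%03d", seq_len(n))
  responder <- runif(n) < spec$responder_fraction

  lo <- spec$baseline_range_pct[1]
  hi <- spec$baseline_range_pct[2]
  mu <- qlogis((spec$baseline_median_pct - lo) / (hi - lo))
  baseline <- lo + (hi - lo) * plogis(rnorm(n, mu, 1))

  centers <- ifelse(responder, spec$responder_effect$responder,
                    spec$responder_effect$nonresponder)
  factor_i <- centers * rlnorm_cv(n, spec$noise_cv)

  weeks <- spec$visit_weeks
  post <- weeks[weeks > 0]
  wk3 <- post[1]
  ramp <- post / max(weeks)

  meas <- vector("list", n)
  max_change <- numeric(n)
  for (i in seq_len(n)) {
    keep <- post
    if (length(post) > 1 && runif(1) < spec$week3_missing_fraction) {
      keep <- setdiff(post, wk3)
    }
    s <- keep / max(weeks)
    truth <- baseline[i] * (1 + (factor_i[i] - 1) * s)
    val <- pmin(100, pmax(0, truth * rlnorm_cv(length(keep), spec$visit_jitter_cv)))
    max_change[i] <- max(100 * (val - baseline[i]) / baseline[i])
    meas[[i]] <- tibble(
      patient_id = id[i],
      week = c(0L, keep),
      cx3cr1_pct = c(baseline[i], val)
    )
  }
  measurements <- dplyr::bind_rows(meas)

  rule_pos <- max_change >= 20
  surv <- function(medians) {
    med <- ifelse(rule_pos, medians[1], medians[2])
    t_true <- rexp(n, rate = log(2) / med)
    cens <- runif(n, 0, spec$max_followup_months)
    list(time = pmin(t_true, cens), event = as.integer(t_true <= cens))
  }
  pfs <- surv(spec$median_pfs_months)
  os <- surv(spec$median_os_months)

  response <- character(n)
  response[responder] <- sample(c("CR", "PR"), sum(responder), TRUE, c(0.2, 0.8))
  response[!responder] <- sample(c("SD", "PD"), sum(!responder), TRUE, c(0.5, 0.5))

  pdl1_high <- runif(n) < 31 / 36
  pdl1_tps <- ifelse(pdl1_high, runif(n, 50, 100), runif(n, 1, 49))

  metadata <- tibble(
    patient_id = id,
    response = response,
    responder = responder,
    pdl1_tps = round(pdl1_tps, 1),
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event
  )
  new_cohort(measurements, metadata)
}

# mean-one lognormal draws with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

new_cohort <- function(measurements, metadata) {
  structure(list(measurements = measurements, metadata = metadata),
            class = "cx3_cohort")
}

#' @export
print.cx3_cohort <- function(x, ...) {
  cat(sprintf(
    "<cx3_cohort> %d patients, %d measurements (weeks %s)\n",
    nrow(x$metadata), nrow(x$measurements),
    paste(sort(unique(x$measurements$week)), collapse = "/")
  ))
  invisible(x)
}
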