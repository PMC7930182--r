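#' Configure a full pipeline run
#'
#' @param measurements_path,metadata_path Input CSVs (see [read_cohort()]).
#' @param landmarks Landmark weeks to evaluate, default `c(3, 6, 9, 12)`.
#' @param cutoff Score positivity cutoff, default 20.
#' @param level Confidence level, default 0.95.
#' @param survival_landmark Landmark whose decision defines survival groups.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @return A validated list of class `cx3_run_config`.
#' @export
run_config <- function(measurements_path, metadata_path,
                       landmarks = c(3, 6, 9, 12), cutoff = 20, level = 0.95,
                       survival_landmark = max(landmarks), out_dir = NULL) {
  if (level <= 0 || level >= 1) cx3_abort("`level` must be in (0, 1)")
  if (any(landmarks <= 0)) cx3_abort("`landmarks` must be positive weeks")
  if (!survival_landmark %in% landmarks) {
    cx3_abort("`survival_landmark` must be one of `landmarks`")
  }
  structure(list(
    measurements_path = measurements_path, metadata_path = metadata_path,
    landmarks = landmarks, cutoff = cutoff, level = level,
    survival_landmark = survival_landmark, out_dir = out_dir
  ), class = "cx3_run_config")
}

#' Run the score -> diagnostics -> survival pipeline
#'
#' Reads and validates the cohort, scores every patient at each landmark,
#' evaluates the decision rule per landmark (confusion metrics, intervals,
#' odds ratio, Fisher p, AUC, Youden cut-point), compares survival between
#' score-high and score-low groups for PFS and OS when the columns are
#' present, and optionally writes `scores.csv`, `report.json` and per-endpoint
#' KM curve CSVs into `out_dir`. The landmarks must be a subset of the visit
#' weeks present in the data.
#'
#' @param config A [run_config()].
#' @return A list of class `cx3_run_bundle` with `scores`, `reports` (one
#'   [diagnostic_report()] per landmark), and `survival` (per endpoint, or
#'   `NULL` with a note when not computable).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "cx3_run_config")) cx3_abort("`config` must come from run_config()")
  cohort <- read_cohort(config$measurements_path, config$metadata_path)
  weeks_present <- unique(cohort$measurements$week)
  missing_lm <- setdiff(config$landmarks, weeks_present)
  if (length(missing_lm)) {
    cx3_abort(sprintf("landmark week(s) %s not among visit weeks in the data",
                      paste(missing_lm, collapse = ", ")))
  }
  scores <- score_cohort(cohort, config$landmarks, config$cutoff)
  meta <- cohort$metadata
  responder <- setNames(meta$responder, meta$patient_id)

  reports <- lapply(config$landmarks, function(L) {
    sl <- scores[scores$landmark == L & scores$evaluable, ]
    diagnostic_report(sl$max_score, unname(responder[sl$patient_id]),
                      cutoff = config$cutoff, level = config$level)
  })
  names(reports) <- paste0("week_", config$landmarks)

  surv <- list()
  for (ep in c("pfs", "os")) {
    cols <- paste0(ep, c("_months", "_event"))
    if (!all(cols %in% names(meta))) {
      surv[[ep]] <- list(note = "endpoint columns absent")
      next
    }
    surv[[ep]] <- tryCatch(
      survival_by_score(scores, meta, ep, landmark = config$survival_landmark,
                        cutoff = config$cutoff, level = config$level),
      error = function(e) list(note = conditionMessage(e))
    )
  }

  bundle <- structure(list(scores = scores, reports = reports, survival = surv,
                           config = config), class = "cx3_run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$scores, file.path(out_dir, "scores.csv"))
  jsonlite::write_json(report_json(bundle), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ep in names(bundle$survival)) {
    sv <- bundle$survival[[ep]]
    if (is.null(sv$groups)) next
    curves <- dplyr::bind_rows(lapply(names(sv$groups), function(g) {
      dplyr::mutate(sv$groups[[g]]$curve, group = g)
    }))
    readr::write_csv(curves, file.path(out_dir, sprintf("km_%s.csv", ep)))
  }
  invisible(out_dir)
}

# plain-list view of the bundle for JSON serialization (stable field order)
report_json <- function(bundle) {
  rep_one <- function(r) {
    list(
      n = r$n, cutoff = r$cutoff,
      confusion = r$confusion[c("tp", "fp", "fn", "tn")],
      rates = as.list(setNames(
        lapply(seq_len(nrow(r$rates)), function(i) {
          list(estimate = r$rates$estimate[i], x = r$rates$x[i], n = r$rates$n[i],
               lower = r$rates$lower[i], upper = r$rates$upper[i])
        }), r$rates$metric
      )),
      odds_ratio = r$odds_ratio, fisher_p = r$fisher_p,
      auc = r$auc[c("auc", "lower", "upper", "degenerate")],
      youden = r$youden,
      logistic = r$logistic[c("separated", "intercept", "slope", "converged")]
    )
  }
  surv_one <- function(sv) {
    if (is.null(sv$groups)) return(list(note = sv$note))
    list(
      medians = lapply(sv$groups, `[[`, "median"),
      logrank = sv$logrank[c("chi_square", "p")],
      hazard_ratio = sv$hazard_ratio[c("hr", "lower", "upper")]
    )
  }
  list(
    cutoff = bundle$config$cutoff, level = bundle$config$level,
    landmarks = bundle$config$landmarks,
    reports = lapply(bundle$reports, rep_one),
    survival = lapply(bundle$survival, surv_one)
  )
}

#' @export
print.cx3_run_bundle <- function(x, ...) {
  cat(sprintf("<cx3_run_bundle> %d landmarks, cutoff %g\n",
              length(x$reports), x$config$cutoff))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    acc <- r$rates[r$rates$metric == "accuracy", ]
    cat(sprintf("  %s: n=%d accuracy %.1f%% (%d/%d)\n", nm, r$n,
                100 * acc$estimate, acc$x, acc$n))
  }
  invisible(x)
}
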