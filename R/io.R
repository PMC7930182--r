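#' Read a longitudinal cohort from CSV files
#'
#' Measurements are long-format (`patient_id`, `week`, `cx3cr1_pct`);
#' metadata is one row per patient with `patient_id`, `response`
#' (CR/PR/SD/PD), and optionally `pdl1_tps` and the survival columns.
#' Validation rejects duplicate (patient, week) rows, frequencies outside
#' `[0, 100]`, patients without a week-0 baseline, and metadata/measurement
#' patient mismatches.
#'
#' @param measurements_path,metadata_path CSV paths.
#' @return A `cx3_cohort` list.
#' @export
read_cohort <- function(measurements_path, metadata_path) {
  for (p in c(measurements_path, metadata_path)) {
    if (!file.exists(p)) cx3_abort(sprintf("file not found: %s", p))
  }
  meas <- readr::read_csv(measurements_path, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  need_m <- c("patient_id", "week", "cx3cr1_pct")
  if (!all(need_m %in% names(meas))) {
    cx3_abort(paste0("measurements must have columns ", paste(need_m, collapse = ", ")))
  }
  if (!all(c("patient_id", "response") %in% names(meta))) {
    cx3_abort("metadata must have columns patient_id, response")
  }
  if (!is.numeric(meas$cx3cr1_pct)) {
    bad <- which(is.na(suppressWarnings(as.numeric(meas$cx3cr1_pct))))
    cx3_abort(sprintf("malformed numeric cx3cr1_pct at data row(s) %s",
                      paste(head(bad, 5), collapse = ", ")))
  }
  out_of_range <- which(meas$cx3cr1_pct < 0 | meas$cx3cr1_pct > 100 | is.na(meas$cx3cr1_pct))
  if (length(out_of_range)) {
    cx3_abort(sprintf("cx3cr1_pct outside [0, 100] at data row(s) %s",
                      paste(head(out_of_range, 5), collapse = ", ")))
  }
  dup <- duplicated(meas[, c("patient_id", "week")])
  if (any(dup)) {
    cx3_abort(sprintf("duplicate (patient_id, week) rows: %s",
                      paste(head(unique(meas$patient_id[dup]), 5), collapse = ", ")))
  }
  base_count <- tapply(meas$week == 0, meas$patient_id, sum)
  missing_base <- names(base_count)[base_count != 1]
  if (length(missing_base)) {
    cx3_abort(sprintf("patients without exactly one week-0 baseline: %s",
                      paste(missing_base, collapse = ", ")))
  }
  if (anyDuplicated(meta$patient_id)) cx3_abort("duplicate patient_id in metadata")
  bad_resp <- !meta$response %in% c("CR", "PR", "SD", "PD")
  if (any(bad_resp)) {
    cx3_abort(sprintf("invalid response class for: %s",
                      paste(meta$patient_id[bad_resp], collapse = ", ")))
  }
  unknown <- setdiff(unique(meas$patient_id), meta$patient_id)
  if (length(unknown)) {
    cx3_abort(sprintf("measurements for patients absent from metadata: %s",
                      paste(unknown, collapse = ", ")))
  }
  if (!"responder" %in% names(meta)) {
    meta$responder <- meta$response %in% c("CR", "PR")
  }
  new_cohort(as_tibble(meas), as_tibble(meta))
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]; round-trips losslessly on generated data.
#'
#' @param cohort A `cx3_cohort`.
#' @inheritParams read_cohort
#' @return The paths, invisibly.
#' @export
write_cohort <- function(cohort, measurements_path, metadata_path) {
  readr::write_csv(cohort$measurements, measurements_path)
  readr::write_csv(cohort$metadata, metadata_path)
  invisible(c(measurements_path, metadata_path))
}

# default ImmunoSEQ-style header names; several aliases accepted per field
immunoseq_aliases <- list(
  nucleotide = c("nucleotide", "rearrangement"),
  amino_acid = c("aminoAcid", "amino_acid", "aa_sequence"),
  count = c("count (templates/reads)", "count", "templates", "reads"),
  frequency = c("frequencyCount", "frequencyCount (%)", "frequency"),
  v_gene = c("vGeneName", "v_gene"),
  j_gene = c("jGeneName", "j_gene"),
  status = c("sequenceStatus", "status", "frame_type")
)

#' Read an ImmunoSEQ-style rearrangement TSV
#'
#' Parses a tab-separated rearrangement table into the package's repertoire
#' layout. Default column names follow the ImmunoSEQ export conventions
#' (`nucleotide`, `aminoAcid`, `count (templates/reads)`, `frequencyCount`,
#' `vGeneName`, `jGeneName`, `sequenceStatus`), with common aliases accepted;
#' `column_map` overrides individual fields. A missing frequency column is
#' recomputed as `count / sum(count)`; a present one is checked against the
#' counts (relative tolerance 1e-6, after normalizing percent-scale
#' frequencies).
#'
#' @param tsv_path Path to the TSV file.
#' @param column_map Optional named list overriding column names, with any of
#'   the names `nucleotide`, `amino_acid`, `count`, `frequency`, `v_gene`,
#'   `j_gene`, `status`.
#' @return A repertoire tibble (`nucleotide`, `amino_acid`, `count`,
#'   `frequency`, `v_gene`, `j_gene`, `status`).
#' @export
read_repertoire <- function(tsv_path, column_map = NULL) {
  if (!file.exists(tsv_path)) cx3_abort(sprintf("file not found: %s", tsv_path))
  raw <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  pick <- function(field) {
    if (!is.null(column_map[[field]])) {
      nm <- column_map[[field]]
      if (!nm %in% names(raw)) cx3_abort(sprintf("mapped column `%s` not in file", nm))
      return(nm)
    }
    hit <- intersect(immunoseq_aliases[[field]], names(raw))
    if (length(hit)) hit[1] else NA_character_
  }
  nt_col <- pick("nucleotide"); cnt_col <- pick("count")
  if (is.na(nt_col) || is.na(cnt_col)) {
    cx3_abort("repertoire file must provide nucleotide and count columns")
  }
  count <- raw[[cnt_col]]
  if (any(is.na(count)) || any(count <= 0) || any(count != floor(count))) {
    cx3_abort("counts must be positive integers")
  }
  freq_col <- pick("frequency")
  frequency <- count / sum(count)
  if (!is.na(freq_col)) {
    given <- raw[[freq_col]]
    if (max(given) > 1.5) given <- given / 100  # percent-scale export
    if (max(abs(given - frequency)) > 1e-6) {
      cx3_abort("frequency column inconsistent with counts (tolerance 1e-6)")
    }
  }
  opt <- function(field, default) {
    col <- pick(field)
    if (is.na(col)) rep(default, nrow(raw)) else raw[[col]]
  }
  tibble(
    nucleotide = raw[[nt_col]],
    amino_acid = opt("amino_acid", ""),
    count = as.integer(count),
    frequency = frequency,
    v_gene = opt("v_gene", NA_character_),
    j_gene = opt("j_gene", NA_character_),
    status = opt("status", "In")
  )
}

#' Write a repertoire as an ImmunoSEQ-style TSV
#'
#' @param rep A repertoire tibble.
#' @param tsv_path Output path.
#' @return The path, invisibly.
#' @export
write_repertoire <- function(rep, tsv_path) {
  check_repertoire(rep)
  out <- tibble(
    nucleotide = rep$nucleotide,
    aminoAcid = rep$amino_acid,
    count = rep$count,
    frequencyCount = rep$frequency,
    vGeneName = rep$v_gene,
    jGeneName = rep$j_gene,
    sequenceStatus = rep$status
  )
  readr::write_tsv(out, tsv_path)
  invisible(tsv_path)
}
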