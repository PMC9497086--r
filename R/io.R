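#' Write a synthetic cohort to a directory of delimited text files
#'
#' Writes `cohort.csv`, `markers.csv`, `reference.csv` and `truth.json`
#' (the generating parameter record) so a cohort can be regenerated,
#' shared, and re-analysed from plain text.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$patients, file.path(dir, "cohort.csv"))
  marker_cols <- c("patient_id", is_markers, "staining_intensity_au",
                   "ct_available", "im_available")
  readr::write_csv(cohort$markers[, marker_cols],
                   file.path(dir, "markers.csv"))
  readr::write_csv(cohort$reference, file.path(dir, "reference.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `cohort.csv`, `markers.csv`,
#'   `reference.csv` and (optionally) `truth.json`.
#' @return a `synthetic_cohort` list.
#' @export
read_cohort <- function(dir) {
  patients <- readr::read_csv(file.path(dir, "cohort.csv"),
                              show_col_types = FALSE)
  markers <- readr::read_csv(file.path(dir, "markers.csv"),
                             show_col_types = FALSE)
  if (!"damaged_slide" %in% names(markers)) markers$damaged_slide <- FALSE
  if (!"attempts_antigen_retrieval" %in% names(markers)) {
    markers$attempts_antigen_retrieval <- 0L
  }
  reference <- readr::read_csv(file.path(dir, "reference.csv"),
                               show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(patients = patients, markers = markers,
                 reference = reference, truth = truth),
            class = "synthetic_cohort")
}

#' Write scoring outputs (Immunoscore table and QC report)
#'
#' @param scores tibble from [compute_immunoscore()].
#' @param qc `qc_report` from [apply_qc()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scores <- function(scores, qc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scores, file.path(dir, "immunoscore.csv"))
  readr::write_csv(qc, file.path(dir, "qc_report.csv"))
  invisible(dir)
}

#' Write analysis outputs (bivariable table, multivariable model, KM curves)
#'
#' @param table bivariable table from [bivariable_table()].
#' @param multivariable an `is_multivariable` from [multivariable_model()],
#'   or `NULL`.
#' @param km per-group KM step functions from [km_by_group()], or `NULL`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(table, multivariable = NULL, km = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(table, file.path(dir, "bivariable_table.csv"))
  if (!is.null(multivariable)) {
    payload <- list(
      table = multivariable$table,
      lrt = multivariable$lrt,
      importance = multivariable$importance,
      n = multivariable$n, n_events = multivariable$n_events
    )
    jsonlite::write_json(payload, file.path(dir, "multivariable.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(km)) readr::write_csv(km, file.path(dir, "km_curves.csv"))
  invisible(dir)
}
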