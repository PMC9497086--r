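#' Mid-rank percentile of a density against a reference distribution
#'
#' Converts a cell density (cells/mm2) into a percentile of a reference
#' distribution using the mid-rank convention: reference values strictly
#' below the query count fully, ties count half. The result is bounded in
#' \[0, 100\] and monotone nondecreasing in the density.
#'
#' @param density numeric vector of densities (cells/mm2), `NA` allowed.
#' @param reference numeric vector of reference densities (length >= 2);
#'   need not be pre-sorted.
#' @return numeric vector of percentiles in \[0, 100\]; `NA` where the
#'   density is missing.
#' @examples
#' density_percentile(c(0, 50, 1e6), reference = 1:100)
#' @export
density_percentile <- function(density, reference) {
  if (length(reference) < 2) {
    abort("`reference` must contain at least 2 values per (marker, region).")
  }
  if (anyNA(reference)) abort("`reference` must not contain missing values.")
  if (any(density < 0, na.rm = TRUE)) abort("`density` must be nonnegative.")
  r <- sort(reference)
  n_less <- findInterval(density, r, left.open = TRUE)
  n_leq <- findInterval(density, r)
  100 * (n_less + 0.5 * (n_leq - n_less)) / length(r)
}

#' Bin mean percentiles into consensus Immunoscore categories
#'
#' The consensus cut-points put the boundary value in the lower bin:
#' three categories Lo \[0, 25\], Int (25, 70\], Hi (70, 100\]; two
#' categories Lo \[0, 25\] vs Int+Hi (25, 100\]; five categories
#' I0 \[0, 10\], I1 (10, 25\], I2 (25, 70\], I3 (70, 95\], I4 (95, 100\].
#'
#' @param mean_percentile numeric vector in \[0, 100\].
#' @param scheme one of `"two"`, `"three"`, `"five"`.
#' @return factor with the scheme's ordered levels (`NA` propagated).
#' @examples
#' categorize_immunoscore(c(25, 25.01, 70, 95, 95.01), "five")
#' @export
categorize_immunoscore <- function(mean_percentile,
                                   scheme = c("three", "two", "five")) {
  scheme <- match.arg(scheme)
  x <- mean_percentile
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    abort("`mean_percentile` must lie in [0, 100].")
  }
  cuts <- switch(scheme,
    two   = list(breaks = c(0, 25, 100), labels = c("Lo", "Int+Hi")),
    three = list(breaks = c(0, 25, 70, 100), labels = c("Lo", "Int", "Hi")),
    five  = list(breaks = c(0, 10, 25, 70, 95, 100),
                 labels = c("I0", "I1", "I2", "I3", "I4"))
  )
  cut(x, breaks = cuts$breaks, labels = cuts$labels,
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Quality control of marker measurements
#'
#' Applies the consensus exclusion rules to a marker table: a measurement
#' is excluded if either tumor region is unavailable, if the staining
#' intensity is at or below the intensity threshold (default 152 AU), if
#' the slide is flagged damaged, or if antigen retrieval failed more than
#' 3 times. When several rules match, the recorded reason follows the
#' fixed priority order `missing_region`, `low_intensity`, `damaged_slide`,
#' `retrieval_failures`.
#'
#' @param markers data frame with columns `patient_id`, `cd3_ct`, `cd3_im`,
#'   `cd8_ct`, `cd8_im`, `staining_intensity_au`, `ct_available`,
#'   `im_available`; optional `damaged_slide` and
#'   `attempts_antigen_retrieval` (assumed `FALSE` / `0` when absent).
#' @param intensity_threshold_au nonnegative intensity cutoff in arbitrary
#'   units; intensities `<=` the cutoff are excluded.
#' @return a tibble of class `qc_report` with columns `patient_id`,
#'   `retained` (logical) and `reason` (`NA` for retained patients);
#'   retained and excluded rows partition the input.
#' @examples
#' m <- tibble::tibble(
#'   patient_id = c("a", "b"), cd3_ct = c(100, 200), cd3_im = c(50, 60),
#'   cd8_ct = c(10, 20), cd8_im = c(5, 6),
#'   staining_intensity_au = c(300, 152),
#'   ct_available = TRUE, im_available = TRUE
#' )
#' apply_qc(m)
#' @export
apply_qc <- function(markers, intensity_threshold_au = 152) {
  stopifnot(is.data.frame(markers))
  if (intensity_threshold_au < 0) {
    abort("`intensity_threshold_au` must be >= 0.")
  }
  if (anyDuplicated(markers$patient_id)) {
    abort("duplicate `patient_id` in `markers`.")
  }
  damaged <- if ("damaged_slide" %in% names(markers)) {
    isTRUE_v(markers$damaged_slide)
  } else rep(FALSE, nrow(markers))
  attempts <- if ("attempts_antigen_retrieval" %in% names(markers)) {
    tidyr::replace_na(markers$attempts_antigen_retrieval, 0)
  } else rep(0L, nrow(markers))

  missing_region <- !isTRUE_v(markers$ct_available) |
    !isTRUE_v(markers$im_available)
  low_intensity <- markers$staining_intensity_au <= intensity_threshold_au
  low_intensity <- tidyr::replace_na(low_intensity, TRUE)
  retrieval <- attempts > 3

  reason <- dplyr::case_when(
    missing_region ~ "missing_region",
    low_intensity ~ "low_intensity",
    damaged ~ "damaged_slide",
    retrieval ~ "retrieval_failures",
    .default = NA_character_
  )
  out <- tibble::tibble(
    patient_id = markers$patient_id,
    retained = is.na(reason),
    reason = reason
  )
  class(out) <- c("qc_report", class(out))
  out
}

# treat NA flags as FALSE
isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Compute the consensus Immunoscore for QC-passed measurements
#'
#' For every patient, the four densities (CD3 and CD8 in tumor core CT and
#' invasive margin IM) are converted to mid-rank percentiles against the
#' matching reference vector, averaged, and binned into the two-, three-
#' and five-category consensus schemes.
#'
#' @param markers data frame with columns `patient_id`, `cd3_ct`, `cd3_im`,
#'   `cd8_ct`, `cd8_im` (cells/mm2), typically already filtered to
#'   QC-passed patients (see [apply_qc()]).
#' @param reference a reference distribution: either a data frame with
#'   columns `marker_region` (values `cd3_ct`, `cd3_im`, `cd8_ct`,
#'   `cd8_im`) and `density`, or a named list of numeric vectors with
#'   those names. Pass the analysis cohort's own densities to score a
#'   cohort against itself.
#' @return tibble with columns `patient_id`, `p_cd3_ct`, `p_cd3_im`,
#'   `p_cd8_ct`, `p_cd8_im`, `mean_percentile`, `is2`, `is3`, `is5`.
#' @examples
#' ref <- tibble::tibble(
#'   marker_region = rep(c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im"), each = 50),
#'   density = rep(seq(10, 500, length.out = 50), 4)
#' )
#' m <- tibble::tibble(patient_id = "a", cd3_ct = 450, cd3_im = 480,
#'                     cd8_ct = 490, cd8_im = 500)
#' compute_immunoscore(m, ref)
#' @export
compute_immunoscore <- function(markers, reference) {
  stopifnot(is.data.frame(markers))
  ref <- as_reference_list(reference)
  for (mr in is_markers) {
    if (!mr %in% names(markers)) {
      abort(paste0("`markers` lacks density column `", mr, "`."))
    }
  }
  pct <- purrr::map(is_markers,
                    ~ density_percentile(markers[[.x]], ref[[.x]]))
  names(pct) <- paste0("p_", is_markers)
  mean_pct <- Reduce(`+`, pct) / 4
  tibble::tibble(
    patient_id = markers$patient_id,
    !!!pct,
    mean_percentile = mean_pct,
    is2 = categorize_immunoscore(mean_pct, "two"),
    is3 = categorize_immunoscore(mean_pct, "three"),
    is5 = categorize_immunoscore(mean_pct, "five")
  )
}

as_reference_list <- function(reference) {
  if (is.data.frame(reference)) {
    if (!all(c("marker_region", "density") %in% names(reference))) {
      abort("`reference` data frame needs columns `marker_region`, `density`.")
    }
    reference <- split(reference$density, reference$marker_region)
  }
  if (!is.list(reference)) abort("`reference` must be a data frame or list.")
  for (mr in is_markers) {
    v <- reference[[mr]]
    if (is.null(v) || length(v) < 2) {
      abort(paste0("reference vector for `", mr,
                   "` is missing or has fewer than 2 values."))
    }
  }
  reference[is_markers]
}

#' Score a cohort end to end: QC then Immunoscore
#'
#' Convenience wrapper chaining [apply_qc()] and [compute_immunoscore()].
#'
#' @inheritParams apply_qc
#' @inheritParams compute_immunoscore
#' @return list with elements `qc` (the [apply_qc()] report) and `scores`
#'   (Immunoscore tibble for retained patients).
#' @export
score_cohort <- function(markers, reference, intensity_threshold_au = 152) {
  qc <- apply_qc(markers, intensity_threshold_au)
  kept <- markers[qc$retained, , drop = FALSE]
  list(qc = qc, scores = compute_immunoscore(kept, reference))
}
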