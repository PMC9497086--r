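#' Derive the three time-to-event endpoints from a clinical table
#'
#' Builds the long endpoint table from per-patient recurrence and death
#' observations, all measured in months from surgery:
#' * **OS** (overall survival): time to death from any cause; censored at
#'   end of observation.
#' * **TTR** (time to recurrence): time to disease recurrence; death
#'   without recurrence censors TTR at the death time.
#' * **DFS** (disease-free survival): time to recurrence or death from
#'   any cause, whichever comes first.
#'
#' @param cohort data frame with columns `patient_id`, `recurrence_months`
#'   (`NA` when no recurrence observed), `recurrence_event` (logical),
#'   `death_months` (end of observation, always present), `death_event`
#'   (logical).
#' @return tibble with columns `patient_id`, `endpoint`
#'   (factor TTR/OS/DFS), `time_months`, `event` (logical); three rows per
#'   patient.
#' @examples
#' p <- tibble::tibble(patient_id = "a", recurrence_months = 12,
#'                     recurrence_event = TRUE, death_months = 20,
#'                     death_event = TRUE)
#' derive_endpoints(p)
#' @export
derive_endpoints <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("patient_id", "recurrence_months", "recurrence_event",
            "death_months", "death_event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) abort(paste0("`cohort` lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyNA(cohort$death_months)) {
    abort("`death_months` (end of observation) must be present for every patient.")
  }
  if (any(cohort$death_months < 0) ||
      any(cohort$recurrence_months < 0, na.rm = TRUE)) {
    abort("times must be nonnegative.")
  }
  rec_ev <- isTRUE_v(cohort$recurrence_event)
  if (any(rec_ev & is.na(cohort$recurrence_months))) {
    abort("`recurrence_event` is TRUE but `recurrence_months` is missing.")
  }
  if (any(rec_ev & cohort$recurrence_months > cohort$death_months,
          na.rm = TRUE)) {
    abort("recurrence time exceeds death/censoring time.")
  }
  death_ev <- isTRUE_v(cohort$death_event)

  ttr_time <- ifelse(rec_ev, cohort$recurrence_months, cohort$death_months)
  dfs_time <- ifelse(rec_ev,
                     pmin(cohort$recurrence_months, cohort$death_months),
                     cohort$death_months)
  out <- dplyr::bind_rows(
    tibble::tibble(patient_id = cohort$patient_id, endpoint = "TTR",
                   time_months = ttr_time, event = rec_ev),
    tibble::tibble(patient_id = cohort$patient_id, endpoint = "OS",
                   time_months = cohort$death_months, event = death_ev),
    tibble::tibble(patient_id = cohort$patient_id, endpoint = "DFS",
                   time_months = dfs_time, event = rec_ev | death_ev)
  )
  out$endpoint <- factor(out$endpoint, levels = is_endpoints)
  dplyr::arrange(out, .data$patient_id, .data$endpoint)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Swaps the event and censoring indicators and reports the Kaplan-Meier
#' median of the censoring distribution with a log(-log) 95% confidence
#' interval — the standard estimate of median follow-up.
#'
#' @param endpoints endpoint table as returned by [derive_endpoints()]
#'   (columns `endpoint`, `time_months`, `event`); a single-endpoint table
#'   is also accepted.
#' @return tibble with one row per endpoint: `endpoint`, `n`,
#'   `median_months`, `conf_low`, `conf_high`.
#' @export
median_follow_up <- function(endpoints) {
  stopifnot(is.data.frame(endpoints))
  if (!"endpoint" %in% names(endpoints)) endpoints$endpoint <- "all"
  endpoints |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::group_modify(function(d, key) {
      if (all(d$event)) {
        abort(paste0("no censored observations for endpoint ", key$endpoint,
                     "; median follow-up is undefined."))
      }
      fit <- survival::survfit(
        survival::Surv(d$time_months, !d$event) ~ 1, conf.type = "log-log")
      q <- quantile(fit, probs = 0.5)
      tibble::tibble(n = nrow(d),
                     median_months = unname(q$quantile),
                     conf_low = unname(q$lower),
                     conf_high = unname(q$upper))
    }) |>
    dplyr::ungroup()
}

#' Assign histopathology risk groups for stage II analyses
#'
#' Partitions patients into three disjoint risk groups from the extent of
#' the primary tumor and the VELIPI flag (vascular emboli, lymphatic
#' invasion or perineural invasion): `very_high` when both T4 and VELIPI+,
#' `high` when exactly one of the two, `low` otherwise.
#'
#' @param t_stage character/factor vector with levels among T1-T4.
#' @param velipi logical vector; `NA` yields an `NA` group (such patients
#'   are omitted from risk-group analyses).
#' @return factor with ordered levels `low`, `high`, `very_high`.
#' @examples
#' assign_risk_group(c("T4", "T3", "T4"), c(TRUE, FALSE, FALSE))
#' @export
assign_risk_group <- function(t_stage, velipi) {
  t4 <- as.character(t_stage) == "T4"
  vel <- as.logical(velipi)
  lab <- dplyr::case_when(
    is.na(vel) | is.na(t4) ~ NA_character_,
    t4 & vel ~ "very_high",
    t4 | vel ~ "high",
    .default = "low"
  )
  if (anyNA(lab)) {
    warn(paste0(sum(is.na(lab)),
                " patient(s) with missing T-stage/VELIPI omitted from risk groups."))
  }
  factor(lab, levels = c("low", "high", "very_high"), ordered = TRUE)
}
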