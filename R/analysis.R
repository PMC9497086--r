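#' Bivariable (one variable at a time) survival table
#'
#' Reproduces the structure of a stage I-III bivariable analysis table:
#' for each clinical variable and each Immunoscore scheme, per-level
#' patient counts and percentages (complete-case denominator per
#' variable), Kaplan-Meier landmark rates, the unadjusted
#' (center-stratified by default) Cox hazard ratio against the reference
#' level with Wald p-value, the variable-level Harrell C-index, and the
#' restricted-mean-survival-time difference against the RMST reference
#' level. Levels with zero events are reported with `HR = Inf`,
#' CI `(0, Inf)` and `p = NA`.
#'
#' @param cohort clinical table (one row per patient, see
#'   [generate_cohort()] for the column contract).
#' @param scores Immunoscore table from [compute_immunoscore()].
#' @param endpoints endpoint table from [derive_endpoints()].
#' @param endpoint which endpoint to analyse: `"TTR"`, `"OS"` or `"DFS"`.
#' @param landmarks landmark times in months for the rate columns.
#' @param stratify_center stratify all Cox fits by `center` (default) or
#'   fit unstratified models.
#' @param variables which variable rows to compute; `"all"` or a subset
#'   of the table's variable names (e.g. `c("is2", "is3", "is5")`).
#' @param n_boot bootstrap resamples for the C-index interval.
#' @param seed seed for the bootstrap.
#' @return tibble with one row per variable level: `variable`, `level`,
#'   `n`, `pct`, `rate_<t>`/`rate_<t>_low`/`rate_<t>_high` per landmark,
#'   `hr`, `hr_low`, `hr_high`, `hr_p`, `reference`, `c_index`,
#'   `c_low`, `c_high`, `rmst_diff`, `rmst_low`, `rmst_high`, `rmst_p`.
#' @export
bivariable_table <- function(cohort, scores, endpoints, endpoint = "TTR",
                             landmarks = c(36, 60), stratify_center = TRUE,
                             variables = "all", n_boot = 200, seed = 1) {
  df <- analysis_frame(cohort, scores, endpoints, endpoint)
  age_levels <- c("<60", ">=60-70", ">=70-85", ">85")
  high_risk <- as.character(df$t_stage) == "T4" & isTRUE_v(df$velipi)
  is2_risk <- factor(
    ifelse(is.na(df$is2) | is.na(high_risk), NA_character_, paste0(
      ifelse(df$is2 == "Lo", "0-25%", "25-100%"),
      ifelse(high_risk, " High Risk", " Low Risk"))),
    levels = c("0-25% High Risk", "0-25% Low Risk",
               "25-100% High Risk", "25-100% Low Risk"))
  defs <- list(
    age_group = list(values = cut(df$age_years, c(0, 60, 70, 85, Inf),
                                  labels = age_levels, right = FALSE),
                     ref = "<60"),
    gender = list(values = factor(df$gender, c("Male", "Female")),
                  ref = "Male"),
    t_stage = list(values = factor(df$t_stage, paste0("T", 1:4)),
                   ref = "T1"),
    n_stage = list(values = factor(df$n_stage, paste0("N", 0:2)),
                   ref = "N0"),
    tnm_stage = list(values = factor(df$tnm_stage, c("I", "II", "III")),
                     ref = "I"),
    differentiation = list(
      values = factor(df$differentiation,
                      c("Well", "Moderate", "Poor-undiff")),
      ref = "Well"),
    sidedness = list(values = factor(df$sidedness,
                                     c("Proximal", "Distal")),
                     ref = "Proximal"),
    velipi = list(values = factor(ifelse(df$velipi, "YES", "NO"),
                                  c("NO", "YES")), ref = "NO"),
    mucinous = list(values = factor(ifelse(df$mucinous, "YES", "NO"),
                                    c("NO", "YES")), ref = "NO"),
    msi_status = list(values = factor(df$msi_status, c("MSS", "MSI-H")),
                      ref = "MSS"),
    chemo = list(values = factor(ifelse(df$chemo, "YES", "NO"),
                                 c("NO", "YES")), ref = "NO"),
    is2 = list(values = df$is2, ref = "Int+Hi"),
    is3 = list(values = df$is3, ref = "Hi"),
    is5 = list(values = df$is5, ref = "I3", rmst_ref = "I4"),
    is2_risk = list(values = is2_risk, ref = "25-100% Low Risk")
  )
  if (!identical(variables, "all")) {
    missing_vars <- setdiff(variables, names(defs))
    if (length(missing_vars)) {
      warn(paste0("unknown variable(s) skipped: ",
                  paste(missing_vars, collapse = ", ")))
    }
    defs <- defs[intersect(variables, names(defs))]
  }
  purrr::imap_dfr(defs, function(def, var) {
    analyze_variable(df, var, def$values, def$ref,
                     rmst_ref = def$rmst_ref %||% def$ref,
                     landmarks = landmarks,
                     strata = if (stratify_center) "center" else NULL,
                     n_boot = n_boot, seed = seed)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analysis_frame <- function(cohort, scores, endpoints, endpoint) {
  ep <- match.arg(endpoint, is_endpoints)
  e <- endpoints[endpoints$endpoint == ep, ]
  cohort |>
    dplyr::inner_join(scores, by = "patient_id") |>
    dplyr::inner_join(e[, c("patient_id", "time_months", "event")],
                      by = "patient_id")
}

analyze_variable <- function(df, var, values, ref, rmst_ref, landmarks,
                             strata, n_boot, seed) {
  keep <- !is.na(values) & !is.na(df$time_months) & !is.na(df$event)
  lv_all <- levels(factor(values))
  v <- as.character(values[keep])
  d <- tibble::tibble(time = df$time_months[keep], event = df$event[keep],
                      center = df$center[keep],
                      value = factor(v, levels = lv_all[lv_all %in% v]))
  if (nrow(d) == 0 || nlevels(d$value) < 1) {
    warn(paste0("variable `", var, "` has no usable levels; row skipped."))
    return(tibble::tibble())
  }
  lv <- levels(d$value)
  if (!ref %in% lv) ref <- lv[1]
  if (!rmst_ref %in% lv) rmst_ref <- ref
  total <- nrow(d)
  tau <- min(tapply(d$time, d$value, max))

  # unadjusted (optionally center-stratified) Cox fit on the factor
  d$value <- stats::relevel(d$value, ref)
  fit <- tryCatch(
    if (nlevels(d$value) >= 2)
      cox_fit(d, "time", "event", "value", strata = strata) else NULL,
    error = function(e) NULL)
  ws <- if (!is.null(fit)) wald_summary(fit) else NULL
  cidx <- if (!is.null(fit)) {
    lp <- stats::predict(fit$model, type = "lp")
    tryCatch(harrell_c(lp, d$time, d$event, n_boot = n_boot, seed = seed),
             error = function(e) NULL)
  } else NULL

  purrr::map_dfr(lv, function(g) {
    i <- d$value == g
    cv <- km_estimate(d$time[i], d$event[i])
    rates <- km_rate_at(cv, landmarks)
    rate_cols <- purrr::imap(
      setNames(seq_along(landmarks), landmarks), function(j, t) {
        setNames(list(rates$rate[j], rates$conf_low[j], rates$conf_high[j]),
                 paste0("rate_", t, c("", "_low", "_high")))
      }) |> purrr::flatten()
    hr_row <- if (!is.null(ws)) ws[ws$term == paste0("value", g), ] else NULL
    has_hr <- !is.null(hr_row) && nrow(hr_row) == 1
    rm <- if (g != rmst_ref) {
      sub <- d$value %in% c(rmst_ref, g)
      tryCatch(rmst_compare(d$time[sub], d$event[sub],
                            factor(d$value[sub], c(rmst_ref, g)), tau = tau),
               error = function(e) NULL)
    } else NULL
    tibble::tibble(
      variable = var, level = g, n = sum(i), pct = 100 * sum(i) / total,
      !!!rate_cols,
      hr = if (g == ref) 1 else if (has_hr) hr_row$hr else NA_real_,
      hr_low = if (has_hr && g != ref) hr_row$conf_low else NA_real_,
      hr_high = if (has_hr && g != ref) hr_row$conf_high else NA_real_,
      hr_p = if (has_hr && g != ref) hr_row$p_value else NA_real_,
      reference = g == ref,
      c_index = if (!is.null(cidx)) cidx$c_index else NA_real_,
      c_low = if (!is.null(cidx)) cidx$conf_low else NA_real_,
      c_high = if (!is.null(cidx)) cidx$conf_high else NA_real_,
      rmst_diff = if (is.null(rm)) 0 else rm$difference,
      rmst_low = if (is.null(rm)) NA_real_ else rm$conf_low,
      rmst_high = if (is.null(rm)) NA_real_ else rm$conf_high,
      rmst_p = if (is.null(rm)) NA_real_ else rm$p_value
    )
  })
}

#' Center-stratified multivariable Cox model with Immunoscore
#'
#' Fits the multivariable model (Immunoscore in two categories plus age,
#' gender, T-stage with T1-2 pooled, N-stage, sidedness and MSI,
#' stratified by center) on complete cases, together with the
#' clinical-only nested model, the likelihood ratio test for the added
#' value of Immunoscore, and the chi-squared relative importance of each
#' variable.
#'
#' @inheritParams bivariable_table
#' @return list of class `is_multivariable`: `fit` (full model `cox_fit`),
#'   `clinical_fit`, `lrt`, `importance`, `table` (tidy hazard ratios),
#'   `n`, `n_events`, `dropped_strata`.
#' @export
multivariable_model <- function(cohort, scores, endpoints, endpoint = "TTR") {
  df <- analysis_frame(cohort, scores, endpoints, endpoint)
  d <- tibble::tibble(
    time = df$time_months, event = df$event, center = df$center,
    immunoscore = factor(as.character(df$is2), c("Int+Hi", "Lo")),
    age = df$age_years,
    gender = factor(df$gender, c("Male", "Female")),
    t_stage = factor(ifelse(df$t_stage %in% c("T1", "T2"), "T1-2",
                            as.character(df$t_stage)),
                     c("T1-2", "T3", "T4")),
    n_stage = factor(df$n_stage, paste0("N", 0:2)),
    sidedness = factor(df$sidedness, c("Proximal", "Distal")),
    msi = factor(df$msi_status, c("MSS", "MSI-H"))
  )
  d <- d[complete.cases(d), ]
  ev_by_stratum <- tapply(d$event, d$center, sum)
  dropped <- names(ev_by_stratum)[is.na(ev_by_stratum) | ev_by_stratum == 0]
  if (length(dropped)) {
    warn(paste0("stratum(s) with zero events dropped: ",
                paste(dropped, collapse = ", ")))
    d <- d[!d$center %in% dropped, ]
  }
  clinical <- c("age", "gender", "t_stage", "n_stage", "sidedness", "msi")
  fit_clin <- cox_fit(d, "time", "event", clinical, strata = "center")
  fit_full <- cox_fit(d, "time", "event", c("immunoscore", clinical),
                      strata = "center")
  structure(list(
    fit = fit_full, clinical_fit = fit_clin,
    lrt = likelihood_ratio_test(fit_clin, fit_full),
    importance = if (fit_full$converged) chi2_importance(fit_full) else NULL,
    table = wald_summary(fit_full),
    n = nrow(d), n_events = sum(d$event), dropped_strata = dropped
  ), class = "is_multivariable")
}

#' @export
print.is_multivariable <- function(x, ...) {
  cat("<is_multivariable> n = ", x$n, ", events = ", x$n_events, "\n", sep = "")
  print(x$table)
  cat("LRT for adding Immunoscore: chi2 = ",
      round(x$lrt$statistic, 3), " (df ", x$lrt$df, "), p = ",
      format.pval(x$lrt$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Immunoscore analysis on a cohort subgroup
#'
#' Runs the Immunoscore bivariable machinery and per-category
#' Kaplan-Meier curves on a filtered subset of the cohort: MSS patients,
#' stage II patients, or the stage II histopathology risk groups (see
#' [assign_risk_group()]).
#'
#' @inheritParams bivariable_table
#' @param subgroup one of `"none"`, `"mss"`, `"stage2"`, `"stage2_low"`,
#'   `"stage2_high"`, `"stage2_very_high"`.
#' @param scheme Immunoscore scheme for the KM curves.
#' @return list: `subgroup`, `n`, `table` (Immunoscore rows of the
#'   bivariable table on the subset), `km` (per-category step functions).
#' @export
subgroup_analysis <- function(cohort, scores, endpoints,
                              subgroup = c("none", "mss", "stage2",
                                           "stage2_low", "stage2_high",
                                           "stage2_very_high"),
                              endpoint = "TTR",
                              scheme = c("two", "three", "five"),
                              n_boot = 200, seed = 1) {
  subgroup <- match.arg(subgroup)
  scheme <- match.arg(scheme)
  risk <- assign_risk_group(cohort$t_stage, cohort$velipi)
  keep <- switch(subgroup,
    none = rep(TRUE, nrow(cohort)),
    mss = !is.na(cohort$msi_status) & cohort$msi_status == "MSS",
    stage2 = cohort$tnm_stage == "II",
    stage2_low = cohort$tnm_stage == "II" & !is.na(risk) & risk == "low",
    stage2_high = cohort$tnm_stage == "II" & !is.na(risk) & risk == "high",
    stage2_very_high = cohort$tnm_stage == "II" & !is.na(risk) &
      risk == "very_high")
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("subgroup filter `", subgroup, "` matches no patients."))
  }
  df <- analysis_frame(sub, scores, endpoints, endpoint)
  cat_col <- c(two = "is2", three = "is3", five = "is5")[[scheme]]
  tab <- table(df[[cat_col]])
  if (sum(df$event) < 1 || any(tab[tab > 0] < 2 & sum(tab > 0) > 1)) {
    warn(paste0("subgroup `", subgroup,
                "` is thin (<2 patients in a category or no events); ",
                "estimates may be degenerate."))
  }
  list(
    subgroup = subgroup, n = nrow(df),
    table = bivariable_table(sub, scores, endpoints, endpoint = endpoint,
                             variables = c("is2", "is3", "is5"),
                             n_boot = n_boot, seed = seed),
    km = km_by_group(df$time_months, df$event, df[[cat_col]])
  )
}

#' Association of immune densities and Immunoscore with age
#'
#' Bins patients into the age groups \[0,60), \[60,70), \[70,85),
#' \[85,Inf), tests each of the four densities across bins with
#' Kruskal-Wallis, and tests the two-category Immunoscore against age
#' bin with a chi-square test. Empty bins are dropped (logged).
#'
#' @param cohort clinical table with `patient_id` and `age_years`.
#' @param markers marker table with the four density columns.
#' @param scores Immunoscore table from [compute_immunoscore()].
#' @return tibble: `test`, `statistic`, `df`, `p_value`, `kind`.
#' @export
age_association <- function(cohort, markers, scores) {
  if (anyNA(cohort$age_years)) abort("`age_years` must be present.")
  bins <- cut(cohort$age_years, c(0, 60, 70, 85, Inf),
              labels = c("<60", ">=60-70", ">=70-85", ">=85"), right = FALSE)
  if (any(table(bins) == 0)) {
    warn("empty age bin(s) merged away.")
    bins <- droplevels(bins)
  }
  ages <- tibble::tibble(patient_id = cohort$patient_id, age_bin = bins)
  md <- dplyr::inner_join(markers, ages, by = "patient_id")
  density_tests <- purrr::map_dfr(is_markers, function(mr) {
    kw <- kruskal.test(md[[mr]], md$age_bin)
    test_result(unname(kw$statistic), unname(kw$parameter), kw$p.value,
                "kruskal") |>
      dplyr::mutate(test = mr, .before = 1)
  })
  sd <- dplyr::inner_join(scores, ages, by = "patient_id")
  ct <- chisq.test(table(sd$is2, sd$age_bin))
  dplyr::bind_rows(
    density_tests,
    test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                "chisq_assoc") |>
      dplyr::mutate(test = "immunoscore2_by_age_bin", .before = 1)
  )
}

#' Compare the covariate distributions of two cohorts
#'
#' Continuous variables (age) are compared by Welch two-sample t-test;
#' categorical variables by chi-square test, falling back to Fisher's
#' exact test when any expected cell is below 5 in a 2x2 table.
#'
#' @param cohort_a,cohort_b two clinical tables sharing the column schema.
#' @return tibble: `variable`, `statistic`, `df`, `p_value`, `kind`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b) {
  cat_vars <- c("center", "gender", "t_stage", "n_stage", "tnm_stage",
                "sidedness", "differentiation", "mucinous", "velipi",
                "msi_status", "chemo")
  shared <- intersect(intersect(names(cohort_a), names(cohort_b)),
                      c("age_years", cat_vars))
  if (length(shared) == 0) abort("cohorts share no comparable columns.")
  purrr::map_dfr(shared, function(v) {
    if (v == "age_years") {
      tt <- t.test(cohort_a[[v]], cohort_b[[v]])
      return(tibble::tibble(variable = v, statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p_value = tt$p.value,
                            kind = "ttest"))
    }
    x <- factor(c(as.character(cohort_a[[v]]), as.character(cohort_b[[v]])))
    g <- rep(c("A", "B"), c(nrow(cohort_a), nrow(cohort_b)))
    keep <- !is.na(x)
    tab <- table(x[keep], g[keep])
    ct <- suppressWarnings(chisq.test(tab))
    if (all(dim(tab) == 2) && any(ct$expected < 5)) {
      ft <- fisher.test(tab)
      tibble::tibble(variable = v, statistic = NA_real_, df = NA_real_,
                     p_value = ft$p.value, kind = "fisher")
    } else {
      tibble::tibble(variable = v, statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p_value = ct$p.value,
                     kind = "chisq_assoc")
    }
  })
}
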