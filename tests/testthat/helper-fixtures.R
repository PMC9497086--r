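# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk.

# a reference distribution with integer grid 1..100 for each marker/region
ref_grid <- function(n = 100) {
  setNames(rep(list(as.numeric(seq_len(n))), 4),
           c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im"))
}

# scores tibble with prescribed mean percentiles (all four percentiles equal)
scores_from_mp <- function(mp, ids = sprintf("P%04d", seq_along(mp))) {
  tibble::tibble(
    patient_id = ids,
    p_cd3_ct = mp, p_cd3_im = mp, p_cd8_ct = mp, p_cd8_im = mp,
    mean_percentile = mp,
    is2 = categorize_immunoscore(mp, "two"),
    is3 = categorize_immunoscore(mp, "three"),
    is5 = categorize_immunoscore(mp, "five")
  )
}

# A 423-patient cohort encoding the category counts, covariate counts and
# event counts printed for the Asian stage I-III cohort:
#   Immunoscore I0/I1/I2/I3/I4 = 71/87/197/62/6 (Lo 158, Int 197, Hi 68),
#   MSS 246 (94 Lo / 152 Int+Hi), MSI-H 26, undetermined 151,
#   VELIPI 301, chemotherapy 265 yes / 146 no / 12 missing,
#   T4&VELIPI+ "high risk" split 11/147/16/249 against Lo/Int+Hi,
#   65 recurrences and 62 deaths.
printed_counts_fixture <- function() {
  n <- 423
  mp <- c(rep(5, 71), rep(20, 87), rep(50, 197), rep(80, 62), rep(99, 6))
  # order: patients 1..158 are Lo, 159..423 Int+Hi
  scores <- scores_from_mp(mp)
  msi <- rep(NA_character_, n)
  msi[1:94] <- "MSS"; msi[159:310] <- "MSS"
  msi[95:110] <- "MSI-H"; msi[311:320] <- "MSI-H"
  velipi <- rep(FALSE, n)
  velipi[c(1:11, 159:174)] <- TRUE          # the T4 & VELIPI+ "high risk"
  velipi[c(12:158, 175:301)] <- TRUE        # bring VELIPI+ to 301 total
  t_stage <- rep("T3", n)
  t_stage[c(1:11, 159:174)] <- "T4"
  chemo <- rep(NA, n)
  chemo[1:146] <- FALSE; chemo[147:411] <- TRUE
  rec_event <- seq_len(n) <= 65
  death_event <- seq_len(n) <= 62
  cohort <- tibble::tibble(
    patient_id = scores$patient_id,
    center = rep(c("AHM", "SAP", "TOK", "XIA"), length.out = n),
    age_years = 64, gender = rep(c("Male", "Female"), length.out = n),
    t_stage = t_stage, n_stage = "N0", tnm_stage = "II",
    sidedness = "Distal", differentiation = "Moderate",
    mucinous = FALSE, velipi = velipi, msi_status = msi, chemo = chemo,
    recurrence_months = ifelse(rec_event, 12, NA_real_),
    recurrence_event = rec_event,
    death_months = ifelse(death_event, 20, 60),
    death_event = death_event
  )
  list(cohort = cohort, scores = scores,
       endpoints = derive_endpoints(cohort))
}

# small survival fixture without ties, for Cox/log-rank oracles
tiefree_fixture <- function() {
  list(
    time = c(3, 5, 7, 9, 12, 14, 18, 22, 25, 31, 34, 40),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 0, 0) == 1,
    x = c(1, 1, 1, 0, 1, 0, 1, 0, 1, 0, 0, 0)
  )
}

# independent Breslow partial log-likelihood for one binary covariate,
# written directly from the definition (used as grid-search oracle)
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in sort(time[event])) {
    i <- which(time == t0 & event)
    risk <- time >= t0
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# one row per patient with the TTR endpoint and the scored two-category
# indicator, for parameter-recovery fits
analysis_frame_test <- function(patients, scores, endpoints) {
  ttr <- endpoints[endpoints$endpoint == "TTR", ]
  patients |>
    dplyr::inner_join(scores[, c("patient_id", "is2")], by = "patient_id") |>
    dplyr::inner_join(ttr[, c("patient_id", "time_months", "event")],
                      by = "patient_id") |>
    dplyr::mutate(lo = as.integer(is2 == "Lo"))
}

# independent k-group log-rank statistic by direct risk-set counting
logrank_stat_direct <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  ev_times <- sort(unique(time[event]))
  o <- e <- numeric(k)
  v <- matrix(0, k, k)
  for (t0 in ev_times) {
    at_risk <- time >= t0
    n_t <- sum(at_risk)
    d_t <- sum(time == t0 & event)
    n_g <- tapply(at_risk, group, sum); n_g[is.na(n_g)] <- 0
    d_g <- tapply(time == t0 & event, group, sum); d_g[is.na(d_g)] <- 0
    o <- o + d_g
    e <- e + d_t * n_g / n_t
    if (n_t > 1) {
      for (a in 1:k) for (b in 1:k) {
        v[a, b] <- v[a, b] + d_t * (n_t - d_t) / (n_t - 1) *
          (n_g[a] * ((a == b) * n_t - n_g[b]) / n_t^2)
      }
    }
  }
  u <- (o - e)[-1]
  drop(t(u) %*% solve(v[-1, -1, drop = FALSE]) %*% u)
}
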