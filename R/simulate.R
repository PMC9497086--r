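#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the generator. Defaults
#' reproduce the structure of a multicenter Asian stage I-III colon
#' cancer cohort: four centers, n = 423, stage mix ~16/59/25%, 54.6%
#' male, age 64.7 +/- 12.1 years, right-skewed correlated CD3/CD8
#' densities, a proportional-hazards outcome model in which a Low
#' Immunoscore carries HR 1.9 for recurrence, ~15% recurrence over ~6
#' years of follow-up, and administrative censoring with staggered entry.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param center_weights,stage_weights named probability vectors over
#'   centers (AHM, SAP, TOK, XIA) and stages (I, II, III); must sum to 1.
#' @param density_log_mean,density_log_sd named numeric vectors (names
#'   `cd3_ct`, `cd3_im`, `cd8_ct`, `cd8_im`): mean and sd of log density
#'   (cells/mm2) per marker and region.
#' @param marker_correlation exchangeable correlation in (-1, 1) between
#'   the four log densities (Gaussian copula).
#' @param reference_log_shift amount added to the log-mean when drawing
#'   the reference distribution; a positive shift emulates scoring the
#'   cohort against a reference population with higher densities, pushing
#'   the cohort toward Low Immunoscore.
#' @param reference_size reference values drawn per (marker, region).
#' @param log_hr_immunoscore log hazard ratio of recurrence for Low vs
#'   Int+Hi (two-category scheme) in the generating model.
#' @param log_hr_clinical named numeric vector of clinical log hazard
#'   ratios; recognized names: `T2`, `T3`, `T4`, `N1`, `N2`, `velipi`,
#'   `msi_h`, `chemo`, `male`, `age_per_10`.
#' @param baseline_hazard_rate recurrence events per month at the
#'   reference level of all covariates.
#' @param background_death_rate,death_after_recurrence_rate hazards per
#'   month of death without recurrence and of death following recurrence.
#' @param admin_censor_months administrative censoring horizon (months).
#' @param entry_stagger_months uniform entry staggering; follow-up is
#'   `admin_censor_months - U(0, entry_stagger_months)`.
#' @param qc_failure_rate probability a marker measurement is degraded by
#'   [inject_qc_failures()].
#' @param msi_h_rate MSI-H probability among patients with determined MSI.
#' @param msi_missing_rate probability MSI status is undetermined.
#' @param velipi_rate,chemo_rate,mucinous_rate,male_rate,distal_rate
#'   marginal probabilities of the respective flags (chemotherapy is
#'   restricted to stage II/III and rescaled to hit the marginal rate).
#' @param age_mean,age_sd age distribution (years), truncated to 20-100.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 423,
                       seed = 1,
                       center_weights = c(AHM = 0.27, SAP = 0.28,
                                          TOK = 0.23, XIA = 0.22),
                       stage_weights = c(I = 0.158, II = 0.594, III = 0.248),
                       density_log_mean = c(cd3_ct = log(480), cd3_im = log(650),
                                            cd8_ct = log(180), cd8_im = log(320)),
                       density_log_sd = c(cd3_ct = 1, cd3_im = 0.9,
                                          cd8_ct = 1.1, cd8_im = 1),
                       marker_correlation = 0.72,
                       reference_log_shift = 0.42,
                       reference_size = 500,
                       log_hr_immunoscore = log(1.9),
                       log_hr_clinical = c(T4 = log(3), N2 = log(4)),
                       baseline_hazard_rate = 0.00112,
                       background_death_rate = 0.0007,
                       death_after_recurrence_rate = 0.030,
                       admin_censor_months = 84,
                       entry_stagger_months = 20,
                       qc_failure_rate = 0.05,
                       msi_h_rate = 0.096,
                       msi_missing_rate = 0.357,
                       velipi_rate = 0.712,
                       chemo_rate = 0.627,
                       mucinous_rate = 0.047,
                       male_rate = 0.546,
                       distal_rate = 0.558,
                       age_mean = 64.7,
                       age_sd = 12.1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob_vec <- function(x, field, nm) {
    if (!setequal(names(x), nm) || abs(sum(x) - 1) > 1e-9 || any(x < 0)) {
      abort(paste0("`", field, "` must be a probability vector over {",
                   paste(nm, collapse = ", "), "} summing to 1."))
    }
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", field, "` must be a probability in [0, 1]."))
    }
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    abort("`n_patients` must be >= 1.")
  }
  chk_prob_vec(cfg$center_weights, "center_weights", is_centers)
  chk_prob_vec(cfg$stage_weights, "stage_weights", c("I", "II", "III"))
  for (f in c("density_log_mean", "density_log_sd")) {
    if (!setequal(names(cfg[[f]]), is_markers)) {
      abort(paste0("`", f, "` must be named over {",
                   paste(is_markers, collapse = ", "), "}."))
    }
  }
  if (any(cfg$density_log_sd <= 0)) abort("`density_log_sd` must be positive.")
  if (abs(cfg$marker_correlation) >= 1) {
    abort("`marker_correlation` must lie in (-1, 1).")
  }
  for (f in c("qc_failure_rate", "msi_h_rate", "msi_missing_rate",
              "velipi_rate", "chemo_rate", "mucinous_rate", "male_rate",
              "distal_rate")) chk_rate(f)
  for (f in c("baseline_hazard_rate", "background_death_rate",
              "death_after_recurrence_rate")) {
    if (cfg[[f]] < 0) abort(paste0("`", f, "` must be nonnegative."))
  }
  if (cfg$reference_size < 2) abort("`reference_size` must be >= 2.")
  if (cfg$admin_censor_months <= cfg$entry_stagger_months) {
    abort("`admin_censor_months` must exceed `entry_stagger_months`.")
  }
  known <- c("T2", "T3", "T4", "N1", "N2", "velipi", "msi_h", "chemo",
             "male", "age_per_10")
  bad <- setdiff(names(cfg$log_hr_clinical), known)
  if (length(bad)) {
    abort(paste0("`log_hr_clinical` has unrecognized term(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Generate a reference density distribution
#'
#' Draws, for each marker and region, a sorted vector of log-normal
#' densities from the configured distribution shifted by
#' `reference_log_shift`. This stands in for the (unpublished) consensus
#' training reference against which cohort percentiles are computed.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `marker_region`, `density`, sorted
#'   ascending within each `marker_region`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  purrr::map_dfr(is_markers, function(mr) {
    d <- exp(rnorm(config$reference_size,
                   config$density_log_mean[[mr]] + config$reference_log_shift,
                   config$density_log_sd[[mr]]))
    tibble::tibble(marker_region = mr, density = sort(d))
  })
}

#' Generate a synthetic cohort with known outcome model
#'
#' Produces a full cohort (clinical table, marker table, reference
#' distribution, and the generating truth) whose recurrence hazard
#' follows a proportional-hazards model on the patient's true
#' two-category Immunoscore (computed against the generated reference)
#' and the configured clinical covariates. Death combines an exponential
#' post-recurrence process and small background mortality; censoring is
#' administrative with uniform entry staggering. The same configuration
#' (including seed) always yields a bit-identical cohort.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `patients`,
#'   `markers`, `reference` (tibbles) and `truth` (list of generating
#'   parameter values and per-category counts).
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' head(cohort$patients)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  reference <- generate_reference(config)
  cfg <- config
  n <- as.integer(cfg$n_patients)
  set.seed(cfg$seed + 1L)

  id <- sprintf("P%04d", seq_len(n))
  center <- sample(is_centers, n, replace = TRUE, prob = cfg$center_weights)
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = cfg$stage_weights)
  t_stage <- character(n)
  n_stage <- character(n)
  for (i in seq_len(n)) {
    if (stage[i] == "I") {
      t_stage[i] <- sample(c("T1", "T2"), 1, prob = c(0.3, 0.7))
      n_stage[i] <- "N0"
    } else if (stage[i] == "II") {
      t_stage[i] <- sample(c("T3", "T4"), 1, prob = c(0.82, 0.18))
      n_stage[i] <- "N0"
    } else {
      t_stage[i] <- sample(c("T2", "T3", "T4"), 1, prob = c(0.1, 0.7, 0.2))
      n_stage[i] <- sample(c("N1", "N2"), 1, prob = c(0.63, 0.37))
    }
  }
  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 20), 100)
  gender <- ifelse(runif(n) < cfg$male_rate, "Male", "Female")
  sidedness <- ifelse(runif(n) < cfg$distal_rate, "Distal", "Proximal")
  differentiation <- sample(c("Well", "Moderate", "Poor-undiff"), n,
                            replace = TRUE, prob = c(0.282, 0.624, 0.094))
  mucinous <- runif(n) < cfg$mucinous_rate
  velipi <- runif(n) < cfg$velipi_rate
  msi_status <- ifelse(runif(n) < cfg$msi_missing_rate, NA_character_,
                       ifelse(runif(n) < cfg$msi_h_rate, "MSI-H", "MSS"))
  # chemo only in stage II/III, conditional rate rescaled to the marginal
  p23 <- sum(cfg$stage_weights[c("II", "III")])
  chemo <- stage != "I" & runif(n) < min(1, cfg$chemo_rate / p23)

  # correlated log-normal densities via Gaussian copula
  rho <- cfg$marker_correlation
  sigma <- matrix(rho, 4, 4); diag(sigma) <- 1
  z <- matrix(rnorm(n * 4), n, 4) %*% chol(sigma)
  dens <- purrr::imap(setNames(is_markers, is_markers), function(mr, nm) {
    j <- match(mr, is_markers)
    exp(cfg$density_log_mean[[mr]] + cfg$density_log_sd[[mr]] * z[, j])
  })
  staining <- pmax(round(rnorm(n, 300, 35), 1), 160)

  markers <- tibble::tibble(
    patient_id = id, cd3_ct = dens$cd3_ct, cd3_im = dens$cd3_im,
    cd8_ct = dens$cd8_ct, cd8_im = dens$cd8_im,
    staining_intensity_au = staining,
    ct_available = TRUE, im_available = TRUE,
    damaged_slide = FALSE, attempts_antigen_retrieval = 0L
  )

  # true Immunoscore category against the generated reference
  scores <- compute_immunoscore(markers, reference)
  true_lo <- scores$is2 == "Lo"

  lp <- cfg$log_hr_immunoscore * as.numeric(true_lo)
  terms <- cfg$log_hr_clinical
  ind <- list(
    T2 = t_stage == "T2", T3 = t_stage == "T3", T4 = t_stage == "T4",
    N1 = n_stage == "N1", N2 = n_stage == "N2",
    velipi = velipi, msi_h = !is.na(msi_status) & msi_status == "MSI-H",
    chemo = chemo, male = gender == "Male", age_per_10 = (age - 65) / 10
  )
  for (nm in names(terms)) lp <- lp + terms[[nm]] * as.numeric(ind[[nm]])

  r_time <- rexp(n, cfg$baseline_hazard_rate * exp(lp))
  b_time <- if (cfg$background_death_rate > 0) {
    rexp(n, cfg$background_death_rate)
  } else rep(Inf, n)
  d_after <- if (cfg$death_after_recurrence_rate > 0) {
    rexp(n, cfg$death_after_recurrence_rate)
  } else rep(Inf, n)
  cens <- cfg$admin_censor_months - runif(n, 0, cfg$entry_stagger_months)

  latent_death <- ifelse(r_time < b_time, r_time + d_after, b_time)
  death_months <- pmin(latent_death, cens)
  death_event <- latent_death <= cens
  rec_event <- r_time <= b_time & r_time <= cens
  recurrence_months <- ifelse(rec_event, r_time, NA_real_)

  patients <- tibble::tibble(
    patient_id = id, center = center, age_years = round(age, 1),
    gender = gender, t_stage = t_stage, n_stage = n_stage,
    tnm_stage = stage, sidedness = sidedness,
    differentiation = differentiation, mucinous = mucinous,
    velipi = velipi, msi_status = msi_status, chemo = chemo,
    recurrence_months = round(recurrence_months, 2),
    recurrence_event = rec_event,
    death_months = round(death_months, 2), death_event = death_event
  )

  truth <- list(
    config = cfg[setdiff(names(cfg), "")],
    true_category2 = setNames(as.character(scores$is2), id),
    true_mean_percentile = setNames(scores$mean_percentile, id),
    n_low = sum(true_lo), n_int_hi = sum(!true_lo),
    n_recurrence = sum(rec_event), n_death = sum(death_event),
    qc_failed_ids = character(0)
  )
  structure(list(patients = patients, markers = markers,
                 reference = reference, truth = truth),
            class = "synthetic_cohort")
}

#' Degrade a random subset of marker measurements so they fail QC
#'
#' With probability `qc_failure_rate` per patient, the measurement is
#' damaged: half of the failures get a staining intensity at or below
#' 152 AU, the other half lose the invasive-margin region. Flagged ids
#' are recorded in `truth$qc_failed_ids`. A rate of 0 returns the cohort
#' unchanged; the draw is a deterministic function of the configuration
#' seed.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param config the [sim_config()] providing `qc_failure_rate` and seed.
#' @return the modified `synthetic_cohort`.
#' @export
inject_qc_failures <- function(cohort, config) {
  validate_sim_config(config)
  rate <- config$qc_failure_rate
  if (rate == 0) return(cohort)
  set.seed(config$seed + 2L)
  n <- nrow(cohort$markers)
  fail <- runif(n) < rate
  mode_intensity <- runif(n) < 0.5
  m <- cohort$markers
  hit_int <- fail & mode_intensity
  hit_reg <- fail & !mode_intensity
  m$staining_intensity_au[hit_int] <- round(runif(sum(hit_int), 60, 152), 1)
  m$im_available[hit_reg] <- FALSE
  m$cd3_im[hit_reg] <- NA_real_
  m$cd8_im[hit_reg] <- NA_real_
  cohort$markers <- m
  cohort$truth$qc_failed_ids <- m$patient_id[fail]
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$patients), " patients, ",
      x$truth$n_recurrence, " recurrences, ", x$truth$n_death, " deaths; ",
      "Lo/Int+Hi = ", x$truth$n_low, "/", x$truth$n_int_hi, "\n", sep = "")
  invisible(x)
}
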