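# one moderately sized scored cohort reused across the blocks below
co <- generate_cohort(sim_config(n_patients = 423, seed = 19))
sc <- score_cohort(co$markers, co$reference)
ep <- derive_endpoints(co$patients)

test_that("bivariable level counts conserve the categorize output", {
  tab <- suppressWarnings(
    bivariable_table(co$patients, sc$scores, ep,
                     variables = c("is2", "is3", "is5"), n_boot = 10))
  expect_equal(setNames(tab$n[tab$variable == "is3"],
                        tab$level[tab$variable == "is3"]),
               c(Lo = sum(sc$scores$is3 == "Lo"),
                 Int = sum(sc$scores$is3 == "Int"),
                 Hi = sum(sc$scores$is3 == "Hi")))
  # two-category row is the three-category row with Int and Hi pooled
  n3 <- setNames(tab$n[tab$variable == "is3"], tab$level[tab$variable == "is3"])
  n2 <- setNames(tab$n[tab$variable == "is2"], tab$level[tab$variable == "is2"])
  expect_equal(unname(n2["Lo"]), unname(n3["Lo"]))
  expect_equal(unname(n2["Int+Hi"]), unname(n3["Int"] + n3["Hi"]))
  # percentages recompute from n within 0.05
  expect_true(all(abs(tab$pct - 100 * tab$n /
    tapply(tab$n, tab$variable, sum)[tab$variable]) < 0.05))
  # reference levels carry HR exactly 1 and empty p
  refs <- tab[tab$reference, ]
  expect_true(all(refs$hr == 1))
  expect_true(all(is.na(refs$hr_p)))
})

test_that("complete-case denominators are applied per variable", {
  tab <- suppressWarnings(
    bivariable_table(co$patients, sc$scores, ep,
                     variables = c("msi_status", "gender"), n_boot = 5))
  n_msi <- sum(tab$n[tab$variable == "msi_status"])
  expect_equal(n_msi, sum(!is.na(co$patients$msi_status)))
  expect_lt(n_msi, sum(tab$n[tab$variable == "gender"]))
  expect_equal(sum(tab$n[tab$variable == "gender"]), nrow(co$patients))
})

test_that("the multivariable model adjusts, tests, and ranks the variables", {
  mv <- multivariable_model(co$patients, sc$scores, ep)
  expect_s3_class(mv$fit, "cox_fit")
  expect_true("immunoscoreLo" %in% mv$table$term)
  expect_equal(mv$lrt$df, 1L)
  # dropping Immunoscore never increases the partial likelihood
  expect_gte(mv$fit$loglik_fitted, mv$clinical_fit$loglik_fitted - 1e-8)
  expect_equal(sum(mv$importance$proportion), 1, tolerance = 1e-9)
  expect_setequal(mv$importance$variable,
                  c("immunoscore", "age", "gender", "t_stage", "n_stage",
                    "sidedness", "msi"))
})

test_that("subgroup filters subset the machinery consistently", {
  all_tab <- suppressWarnings(
    subgroup_analysis(co$patients, sc$scores, ep, "none", n_boot = 5))
  direct <- suppressWarnings(
    bivariable_table(co$patients, sc$scores, ep,
                     variables = c("is2", "is3", "is5"), n_boot = 5))
  expect_equal(all_tab$table, direct)
  expect_equal(all_tab$n, nrow(co$patients))

  mss <- suppressWarnings(
    subgroup_analysis(co$patients, sc$scores, ep, "mss", n_boot = 5))
  n_mss <- sum(co$patients$msi_status == "MSS", na.rm = TRUE)
  expect_equal(mss$n, n_mss)
  expect_equal(sum(mss$table$n[mss$table$variable == "is2"]), n_mss)

  # the three risk groups partition the stage II subset
  s2 <- co$patients[co$patients$tnm_stage == "II", ]
  rg <- assign_risk_group(s2$t_stage, s2$velipi)
  sizes <- vapply(c("stage2_low", "stage2_high", "stage2_very_high"),
                  function(s) suppressWarnings(
                    subgroup_analysis(co$patients, sc$scores, ep, s,
                                      n_boot = 2))$n,
                  numeric(1))
  expect_equal(unname(sum(sizes)), sum(!is.na(rg)))
  expect_equal(unname(sizes),
               unname(as.vector(table(rg))))
  expect_error(
    subgroup_analysis(co$patients[0, ], sc$scores, ep, "mss"),
    "no patients")
})

test_that("age bins are left-closed and age tests cover densities and score", {
  res <- suppressWarnings(age_association(co$patients, co$markers, sc$scores))
  expect_equal(res$test, c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im",
                           "immunoscore2_by_age_bin"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$kind, c(rep("kruskal", 4), "chisq_assoc"))
  # age exactly 60 falls in the >=60-70 bin
  one <- tibble::tibble(patient_id = "x", age_years = 60)
  bins <- cut(one$age_years, c(0, 60, 70, 85, Inf),
              labels = c("<60", ">=60-70", ">=70-85", ">=85"), right = FALSE)
  expect_equal(as.character(bins), ">=60-70")
  # densities shifted only below age 60 are detected at large n
  big <- generate_cohort(sim_config(n_patients = 2000, seed = 23))
  mk <- big$markers
  young <- big$patients$age_years < 60
  mk[young, c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")] <-
    mk[young, c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")] * 1.8
  sc_big <- compute_immunoscore(mk, big$reference)
  res_big <- suppressWarnings(age_association(big$patients, mk, sc_big))
  expect_lt(res_big$p_value[res_big$test == "cd3_ct"], 1e-4)
})

test_that("cohort comparison picks t-test, chi-square, or Fisher correctly", {
  cc <- compare_cohorts(co$patients, co$patients)
  expect_true(all(cc$p_value > 1 - 1e-9))
  expect_equal(cc$kind[cc$variable == "age_years"], "ttest")

  # 2x2 with small expected counts falls back to Fisher's exact test
  a <- tibble::tibble(gender = c("Male", "Male", "Male", "Female"))
  b <- tibble::tibble(gender = c("Male", "Female", "Female", "Female"))
  ft <- compare_cohorts(a, b)
  expect_equal(ft$kind, "fisher")
  expect_equal(ft$p_value, 0.4857, tolerance = 1e-4)

  # cohorts differing only in chemotherapy use: chemo has the smallest p
  alt <- generate_cohort(sim_config(n_patients = 423, seed = 29,
                                    chemo_rate = 0.28))
  cc2 <- compare_cohorts(co$patients, alt$patients)
  expect_equal(cc2$variable[which.min(cc2$p_value)], "chemo")
  expect_error(compare_cohorts(tibble::tibble(zzz = 1), co$patients),
               "no comparable")
})
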