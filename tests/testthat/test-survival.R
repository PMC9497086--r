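test_that("Kaplan-Meier matches hand product-limit and counting oracles", {
  # hand product-limit: 5 (event), 10 (censored), 15 (event)
  cv <- km_estimate(c(5, 10, 15), c(TRUE, FALSE, TRUE))
  expect_equal(cv$surv[cv$time == 5], 2 / 3)
  expect_equal(cv$surv[cv$time == 10], 2 / 3)
  expect_equal(cv$surv[cv$time == 15], 0)

  # no events: survival identically 1
  cv1 <- km_estimate(c(4, 8, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(cv1$surv == 1))

  # no censoring: S(t) equals the empirical fraction surviving beyond t
  set.seed(2)
  t <- rexp(60, 0.1)
  cv2 <- km_estimate(t, rep(TRUE, 60))
  for (tq in quantile(t, c(0.2, 0.5, 0.8))) {
    i <- max(which(cv2$time <= tq))
    expect_equal(cv2$surv[i], mean(t > cv2$time[i]))
  }
  # survival starts at 1 and is nonincreasing
  expect_true(all(diff(cv2$surv) <= 1e-12))
  expect_error(km_estimate(numeric(0), logical(0)), "at least one")
})

test_that("landmark rates use left steps, log-log CIs, extrapolation flag", {
  cv <- km_estimate(c(36, 40), c(TRUE, FALSE))
  r <- km_rate_at(cv, c(0, 36, 38, 50))
  expect_equal(r$rate, c(100, 50, 50, 50))
  expect_equal(r$extrapolated, c(FALSE, FALSE, FALSE, TRUE))

  set.seed(3)
  t <- rexp(80, 0.01); e <- runif(80) < 0.3
  cv2 <- km_estimate(t, e)
  rr <- km_rate_at(cv2, c(1, 12, 36, 60))
  ok <- !is.na(rr$conf_low)
  expect_true(all(rr$conf_low[ok] >= 0 & rr$conf_high[ok] <= 100))
})

test_that("log-rank equals direct counting and exhaustive permutation", {
  time <- c(3, 5, 8, 10, 12, 15, 20, 26)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  group <- c("a", "a", "a", "b", "a", "b", "b", "b")
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, logrank_stat_direct(time, event, group),
               tolerance = 1e-8)
  expect_equal(res$df, 1L)

  # exhaustive relabelling (choose(8,4) = 70 assignments)
  perms <- utils::combn(8, 4)
  stats <- apply(perms, 2, function(idx) {
    g <- rep("b", 8); g[idx] <- "a"
    logrank_stat_direct(time, event, g)
  })
  p_perm <- mean(stats >= res$statistic - 1e-12)
  expect_lt(abs(res$p_value - p_perm), 0.15)

  # identical groups give statistic 0
  t2 <- rep(c(2, 4, 6), 2); e2 <- rep(c(TRUE, TRUE, FALSE), 2)
  expect_equal(logrank_test(t2, e2, rep(c("x", "y"), each = 3))$statistic, 0,
               tolerance = 1e-12)

  # collapsing three groups onto two labels reduces to the 2-group test
  set.seed(4)
  t3 <- rexp(30, 0.05); e3 <- runif(30) < 0.7
  g3 <- rep(c("a", "b", "c"), each = 10)
  merged <- ifelse(g3 == "a", "a", "bc")
  expect_equal(logrank_test(t3, e3, merged)$statistic,
               logrank_stat_direct(t3, e3, merged), tolerance = 1e-8)
  expect_equal(logrank_test(t3, e3, merged)$df, 1L)
  expect_error(logrank_test(t3, e3, rep("a", 30)), "2 nonempty")
})

test_that("two-group log-rank equals the squared Cox score z (Breslow, tie-free)", {
  f <- tiefree_fixture()
  lr <- logrank_test(f$time, f$event, f$x)
  cx <- survival::coxph(survival::Surv(f$time, f$event) ~ f$x,
                        ties = "breslow")
  expect_equal(lr$statistic, unname(cx$score), tolerance = 1e-6)
})

test_that("trend test is score-symmetric and beats shuffled ordering on average", {
  set.seed(9)
  n <- 60
  g <- rep(c("g0", "g1", "g2"), each = n / 3)
  haz <- c(g0 = 0.02, g1 = 0.05, g2 = 0.12)[g]
  t <- rexp(n, haz); e <- t < 40; t <- pmin(t, 40)
  fwd <- logrank_trend_test(t, e, factor(g, c("g0", "g1", "g2")))
  rev <- logrank_trend_test(t, e, factor(g, c("g2", "g1", "g0")))
  expect_equal(fwd$statistic, rev$statistic, tolerance = 1e-10)
  expect_equal(fwd$df, 1L)
  # monotone ordering concentrates the trend: the ordered statistic should
  # (usually) dominate a non-monotone permutation of the group scores
  perm <- logrank_trend_test(t, e, factor(g, c("g1", "g0", "g2")))
  expect_gt(fwd$statistic, perm$statistic)
  expect_error(logrank_trend_test(t, e, ifelse(g == "g0", "a", "b")),
               ">= 3")
})

test_that("RMST equals the truncated-time average when uncensored", {
  set.seed(5)
  ta <- rexp(40, 0.04); tb <- rexp(40, 0.08)
  time <- c(ta, tb); event <- rep(TRUE, 80)
  group <- factor(rep(c("A", "B"), each = 40), c("A", "B"))
  tau <- min(max(ta), max(tb))
  res <- rmst_compare(time, event, group, tau = tau)
  expect_equal(res$rmst_ref, mean(pmin(ta, tau)), tolerance = 1e-10)
  expect_equal(res$rmst_cmp, mean(pmin(tb, tau)), tolerance = 1e-10)
  expect_equal(res$difference, res$rmst_cmp - res$rmst_ref)

  # a group with no events up to tau has RMST = tau
  res2 <- rmst_compare(c(10, 20, 30, 5, 9, 31), c(0, 0, 0, 1, 1, 0) == 1,
                       factor(rep(c("A", "B"), each = 3)), tau = 9)
  expect_equal(res2$rmst_ref, 9)

  # identical groups: difference 0, p = 1
  res3 <- rmst_compare(rep(c(3, 6, 9, 12), 2), rep(c(1, 1, 0, 1), 2) == 1,
                       factor(rep(c("A", "B"), each = 4)))
  expect_equal(res3$difference, 0, tolerance = 1e-12)
  expect_equal(res3$p_value, 1, tolerance = 1e-9)

  expect_error(rmst_compare(time, event, group, tau = max(time) + 1),
               "exceeds")
})

test_that("Harrell's C matches the O(n^2) pair enumeration", {
  set.seed(6)
  n <- 30
  time <- round(rexp(n, 0.05), 3) + seq_len(n) * 1e-4  # distinct times
  event <- runif(n) < 0.6
  score <- -time + rnorm(n, 0, 6)
  res <- harrell_c(score, time, event, n_boot = 50, seed = 2)
  conc <- disc <- ties <- 0; pairs <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i]) {
      pairs <- pairs + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) ties <- ties + 1
      else disc <- disc + 1
    }
  }
  expect_equal(res$n_comparable_pairs, pairs)
  expect_equal(res$c_index, (conc + 0.5 * ties) / pairs, tolerance = 1e-12)

  # all-tied scores give exactly 1/2; score = -time ranks perfectly
  expect_equal(harrell_c(rep(1, n), time, event, n_boot = 0)$c_index, 0.5)
  expect_equal(harrell_c(-time, time, rep(TRUE, n), n_boot = 0)$c_index, 1)

  # bootstrap CI deterministic under a fixed seed
  r1 <- harrell_c(score, time, event, n_boot = 40, seed = 9)
  r2 <- harrell_c(score, time, event, n_boot = 40, seed = 9)
  expect_identical(r1, r2)
})
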