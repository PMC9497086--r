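#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimate of the survival function with the Greenwood
#' variance and a log(-log) 95% confidence interval (which keeps the
#' band inside \[0, 1\] even near S = 1).
#'
#' @param times positive event/censoring times (months).
#' @param events logical (or 0/1) event indicators.
#' @return a tibble of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `greenwood_var`, `conf_low`, `conf_high`. The attribute `max_time`
#'   carries the largest observed time.
#' @examples
#' km_estimate(c(5, 10, 15), c(TRUE, FALSE, TRUE))
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("`times` must contain at least one observation.")
  if (any(times <= 0)) abort("`times` must be positive.")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  d <- fit$n.event
  nr <- fit$n.risk
  incr <- ifelse(nr > d, d / (nr * (nr - d)), 0)
  gvar <- fit$surv^2 * cumsum(incr)
  out <- tibble::tibble(
    time = fit$time, n_risk = nr, n_event = d, n_censor = fit$n.censor,
    surv = fit$surv, greenwood_var = gvar,
    conf_low = ifelse(is.na(fit$lower), NA_real_, fit$lower),
    conf_high = ifelse(is.na(fit$upper), NA_real_, fit$upper)
  )
  attr(out, "max_time") <- max(times)
  class(out) <- c("km_curve", class(out))
  out
}

#' Landmark survival rate from a Kaplan-Meier curve
#'
#' Evaluates 100 * S(t) at a landmark time (e.g. 36 or 60 months) with
#' the log(-log) 95% confidence interval. Times between steps use the
#' value of the step to the left; a query beyond the last observed time
#' returns the last value flagged `extrapolated`.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t landmark time(s) in months, >= 0.
#' @return tibble with columns `time`, `rate`, `conf_low`, `conf_high`
#'   (percent) and `extrapolated`.
#' @export
km_rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  idx <- findInterval(t, curve$time)
  pick <- function(col, default) {
    ifelse(idx == 0, default, col[pmax(idx, 1)])
  }
  tibble::tibble(
    time = t,
    rate = 100 * pick(curve$surv, 1),
    conf_low = 100 * pick(curve$conf_low, 1),
    conf_high = 100 * pick(curve$conf_high, 1),
    extrapolated = t > attr(curve, "max_time")
  )
}

#' k-group log-rank test
#'
#' @param time,event observation times and event indicators.
#' @param group group labels (>= 2 nonempty groups).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `kind`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) abort("`group` must contain at least 2 nonempty groups.")
  sd <- survival::survdiff(survival::Surv(time, as.logical(event)) ~ group)
  df <- nlevels(group) - 1L
  test_result(sd$chisq, df, pchisq(sd$chisq, df, lower.tail = FALSE),
              "logrank")
}

#' Log-rank trend test across ordered groups
#'
#' Score test for a monotone trend in hazard across >= 3 ordered groups,
#' using equally spaced integer scores 0, 1, 2, ...: the statistic is
#' `(c'(O - E))^2 / (c' V c)` where `O - E` and `V` are the log-rank
#' observed-minus-expected vector and its covariance, on 1 df. The
#' statistic is invariant to reversing the score direction.
#'
#' @param time,event observation times and event indicators.
#' @param group ordered factor (or values coercible to one); the factor
#'   level order defines the scores.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `kind`.
#' @export
logrank_trend_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 3) abort("trend test needs >= 3 ordered groups; use logrank_test().")
  sd <- survival::survdiff(survival::Surv(time, as.logical(event)) ~ group)
  sc <- seq_len(k) - 1
  u <- sum(sc * (sd$obs - sd$exp))
  v <- drop(t(sc) %*% sd$var %*% sc)
  stat <- u^2 / v
  test_result(stat, 1L, pchisq(stat, 1, lower.tail = FALSE), "trend")
}

test_result <- function(statistic, df, p_value, kind) {
  tibble::tibble(statistic = statistic, df = as.integer(df),
                 p_value = p_value, kind = kind)
}

#' Restricted mean survival time comparison between two groups
#'
#' RMST is the area under the Kaplan-Meier curve up to the truncation
#' time `tau`; the difference (level minus reference, "relative months")
#' is reported with a large-sample variance-based 95% confidence interval
#' and a two-sided normal p-value. `tau` defaults to the smaller of the
#' two groups' largest observed times and may not exceed it.
#'
#' @param time,event observation times and event indicators.
#' @param group a factor with exactly 2 levels; the first level is the
#'   reference.
#' @param tau truncation time in months.
#' @return one-row tibble: `tau`, `rmst_ref`, `rmst_cmp`, `difference`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
rmst_compare <- function(time, event, group, tau = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) abort("`group` must have exactly 2 levels.")
  maxes <- tapply(time, group, max)
  if (is.null(tau)) tau <- min(maxes)
  over <- names(maxes)[maxes < tau]
  if (length(over)) {
    abort(paste0("`tau` exceeds the follow-up of group(s): ",
                 paste(over, collapse = ", ")))
  }
  per <- lapply(levels(group), function(g) {
    i <- group == g
    rmst_one(time[i], as.logical(event)[i], tau)
  })
  diff <- per[[2]]$rmst - per[[1]]$rmst
  se <- sqrt(per[[1]]$var + per[[2]]$var)
  z <- if (se > 0) diff / se else 0
  tibble::tibble(
    tau = tau, rmst_ref = per[[1]]$rmst, rmst_cmp = per[[2]]$rmst,
    difference = diff,
    conf_low = diff - qnorm(0.975) * se,
    conf_high = diff + qnorm(0.975) * se,
    p_value = 2 * pnorm(-abs(z))
  )
}

# RMST of one sample: area under KM up to tau, with the standard
# large-sample variance over KM increments.
rmst_one <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- c(0, fit$time[fit$time <= tau], tau)
  ss <- c(1, fit$surv[fit$time <= tau])
  rmst <- sum(ss * diff(tt))
  # event times up to tau
  keep <- fit$time <= tau & fit$n.event > 0
  if (!any(keep)) return(list(rmst = rmst, var = 0))
  et <- fit$time[keep]; d <- fit$n.event[keep]; nr <- fit$n.risk[keep]
  # area from each event time to tau
  area_after <- vapply(et, function(t0) {
    tt2 <- c(t0, fit$time[fit$time > t0 & fit$time <= tau], tau)
    ss2 <- c(fit$surv[max(which(fit$time <= t0))],
             fit$surv[fit$time > t0 & fit$time <= tau])
    sum(ss2 * diff(tt2))
  }, numeric(1))
  denom <- nr * (nr - d)
  v <- sum(ifelse(denom > 0, area_after^2 * d / denom, 0))
  list(rmst = rmst, var = v)
}

#' Harrell's concordance index with bootstrap confidence interval
#'
#' Probability that, of a pair of patients comparable under right
#' censoring, the one with the higher risk score fails first; score ties
#' count one half. The point estimate uses `survival::concordance`
#' (higher score = higher risk); the 95% CI is a seeded percentile
#' bootstrap over patients.
#'
#' @param risk_score numeric risk scores (higher = worse prognosis).
#' @param time,event observation times and event indicators.
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed integer seed making the bootstrap deterministic.
#' @return one-row tibble: `c_index`, `conf_low`, `conf_high`,
#'   `n_comparable_pairs`.
#' @export
harrell_c <- function(risk_score, time, event, n_boot = 200, seed = 1) {
  stopifnot(length(risk_score) == length(time), length(time) == length(event))
  event <- as.logical(event)
  cc <- survival::concordance(survival::Surv(time, event) ~ risk_score,
                              reverse = TRUE)
  counts <- cc$count
  n_pairs <- unname(counts["concordant"] + counts["discordant"] +
                    counts["tied.x"])
  if (n_pairs == 0) abort("no comparable pairs under censoring.")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(time)
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (!any(event[i])) return(NA_real_)
      survival::concordance(survival::Surv(time[i], event[i]) ~ risk_score[i],
                            reverse = TRUE)$concordance
    }, numeric(1))
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  tibble::tibble(c_index = unname(cc$concordance),
                 conf_low = ci[1], conf_high = ci[2],
                 n_comparable_pairs = n_pairs)
}

#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- tibble::tibble(time = c(0, object$time),
                          surv = c(1, object$surv))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from surgery", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Step-function Kaplan-Meier curves per group, ready for plotting
#'
#' @param time,event observation times and event indicators.
#' @param group group labels.
#' @return tibble with `group`, `time`, `surv`, `conf_low`, `conf_high`.
#' @export
km_by_group <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  purrr::map_dfr(levels(group), function(g) {
    i <- group == g
    cv <- km_estimate(time[i], event[i])
    dplyr::bind_cols(tibble::tibble(group = g), tibble::as_tibble(cv))
  })
}

#' Plot Kaplan-Meier curves by group
#'
#' @param km a tibble from [km_by_group()].
#' @return a ggplot object.
#' @export
plot_km_groups <- function(km) {
  start <- km |> dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  dat <- dplyr::bind_rows(start, km[, c("group", "time", "surv")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from surgery", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
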