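#' Fit a (center-)stratified Cox proportional-hazards model
#'
#' Maximizes the stratified partial likelihood (each stratum contributes
#' its own risk sets) for the listed model terms. Monotone likelihood —
#' e.g. a covariate level with zero events — is detected via coefficient
#' divergence (|coef| > 15) and reported as an infinite hazard ratio with
#' `NA` p-value rather than an error.
#'
#' @param data data frame holding the model variables.
#' @param time,event column names (strings) of the observation time and
#'   event indicator.
#' @param terms character vector of covariate column names; factors enter
#'   as dummy-coded blocks against their first level.
#' @param strata optional column name used as stratification factor.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: coefficients, covariance, null and
#'   fitted partial log-likelihoods, per-variable coefficient blocks,
#'   strata labels, convergence/infinite-term flags, `n`, `n_events`.
#' @examples
#' d <- data.frame(t = c(3, 5, 7, 2, 9, 11), e = c(1, 1, 0, 1, 0, 1),
#'                 x = c(1, 1, 1, 0, 0, 0))
#' cox_fit(d, "t", "e", "x")
#' @export
cox_fit <- function(data, time, event, terms, strata = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(time, event, terms, strata), names(data))
  if (length(miss)) abort(paste0("`data` lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (sum(as.logical(data[[event]])) < 1) abort("need at least 1 event.")
  rhs <- paste(paste0("`", terms, "`"), collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(`", strata, "`)")
  fml <- as.formula(paste0("survival::Surv(`", time, "`, `", event,
                           "`) ~ ", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties, x = FALSE,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- coef(fit)
  infinite <- is.na(beta) | abs(beta) > 15
  assign_blocks <- fit$assign
  # map block indices to the user's term names
  names(assign_blocks) <- vapply(names(assign_blocks), function(lbl) {
    hit <- terms[vapply(terms, function(tm) {
      lbl == tm | lbl == paste0("`", tm, "`")
    }, logical(1))]
    if (length(hit)) hit[1] else lbl
  }, character(1))
  structure(list(
    coefficients = beta,
    covariance = fit$var,
    loglik_null = fit$loglik[1],
    loglik_fitted = fit$loglik[2],
    assign = assign_blocks,
    terms = terms,
    strata_labels = if (is.null(strata)) character(0) else
      sort(unique(as.character(data[[strata]][!is.na(data[[strata]])]))),
    strata_var = strata,
    ties_method = ties,
    converged = !any(infinite) && fit$iter <= 50,
    infinite_terms = names(beta)[infinite],
    n = fit$n, n_events = fit$nevent,
    model = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ", length(x$coefficients), " term(s), n = ", x$n,
      ", events = ", x$n_events,
      if (length(x$strata_labels)) paste0(", strata = ",
        paste(x$strata_labels, collapse = "/")) else "",
      if (!x$converged) " [not converged]" else "", "\n", sep = "")
  print(wald_summary(x))
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals and p-values
#'
#' `HR = exp(coef)`, `CI = exp(coef +/- 1.96 SE)`, two-sided normal
#' p-value. Terms flagged infinite (monotone likelihood) are reported as
#' `HR = Inf`, CI `(0, Inf)`, `p = NA`.
#'
#' @param fit a [cox_fit()].
#' @param term optional coefficient name(s) to restrict to.
#' @return tibble: `term`, `estimate` (log HR), `se`, `hr`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
wald_summary <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  beta <- fit$coefficients
  se <- sqrt(diag(as.matrix(fit$covariance)))
  nm <- names(beta)
  inf <- nm %in% fit$infinite_terms
  z <- qnorm(0.975)
  out <- tibble::tibble(
    term = nm,
    estimate = ifelse(inf, Inf * sign(ifelse(is.na(beta), 1, beta)), beta),
    se = ifelse(inf, NA_real_, se),
    hr = ifelse(inf, Inf, exp(beta)),
    conf_low = ifelse(inf, 0, exp(beta - z * se)),
    conf_high = ifelse(inf, Inf, exp(beta + z * se)),
    p_value = ifelse(inf, NA_real_, 2 * pnorm(-abs(beta / se)))
  )
  if (!is.null(term)) out <- out[out$term %in% term, , drop = FALSE]
  out
}

#' @export
tidy.cox_fit <- function(x, ...) wald_summary(x)

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik_null = x$loglik_null,
                 loglik_fitted = x$loglik_fitted,
                 df = length(x$coefficients),
                 ties_method = x$ties_method,
                 converged = x$converged)
}

#' Likelihood ratio test between nested Cox models
#'
#' `statistic = 2 (loglik_full - loglik_nested)` on `df` equal to the
#' difference in coefficient count. Both fits must come from the same
#' data (same `n`, event count, strata, and ties handling) and the
#' nested model's terms must be a subset of the full model's.
#'
#' @param nested,full two [cox_fit()] objects.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `kind`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  if (nested$n != full$n || nested$n_events != full$n_events ||
      !identical(nested$strata_labels, full$strata_labels) ||
      !identical(nested$ties_method, full$ties_method)) {
    abort("models were not fitted on the same data/strata/ties.")
  }
  if (!all(nested$terms %in% full$terms)) {
    abort("`nested` terms are not a subset of `full` terms.")
  }
  df <- length(full$coefficients) - length(nested$coefficients)
  if (df < 0) abort("`full` has fewer coefficients than `nested`.")
  stat <- max(0, 2 * (full$loglik_fitted - nested$loglik_fitted))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  test_result(stat, df, p, "lrt")
}

#' Relative importance of model variables by chi-squared proportion
#'
#' For each variable (coefficient block) of a converged multivariable
#' fit, computes the Wald chi-square `b' V^-1 b` of its block and the
#' proportion of the total across variables; proportions sum to 1.
#' Singular blocks are flagged `NA` and proportions renormalized over
#' the rest.
#'
#' @param fit a converged multivariable [cox_fit()].
#' @return tibble of class `importance_result`: `variable`, `chisq`,
#'   `df`, `proportion`.
#' @export
chi2_importance <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) abort("`fit` did not converge; importance undefined.")
  blocks <- fit$assign
  rows <- purrr::imap_dfr(blocks, function(idx, var) {
    b <- fit$coefficients[idx]
    v <- as.matrix(fit$covariance)[idx, idx, drop = FALSE]
    chi <- tryCatch(drop(t(b) %*% solve(v) %*% b), error = function(e) NA_real_)
    tibble::tibble(variable = var, chisq = chi, df = length(idx))
  })
  if (anyNA(rows$chisq)) {
    warn("singular covariance block(s); proportions renormalized over the rest.")
  }
  total <- sum(rows$chisq, na.rm = TRUE)
  rows$proportion <- rows$chisq / total
  class(rows) <- c("importance_result", class(rows))
  rows
}

#' @export
autoplot.importance_result <- function(object, ...) {
  d <- dplyr::arrange(object, .data$proportion)
  d$variable <- factor(d$variable, levels = d$variable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Share of model chi-square", y = NULL) +
    ggplot2::theme_minimal()
}
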