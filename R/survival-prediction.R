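# Cox proportional hazards machinery for 5-year mortality risk prediction.
# Fitting and the Breslow baseline hazard are delegated to the survival
# package (coxph with ties = "breslow", so the tie handling matches the
# baseline used for absolute risk).

#' Administrative censoring at a horizon
#'
#' Follow-up beyond `horizon` years is censored at the horizon (deaths after
#' the horizon become censored observations at the horizon).
#'
#' @param times follow-up times in years.
#' @param events 0/1 event indicators.
#' @param horizon censoring horizon (default 5 years).
#' @return data.frame with `time`, `event`.
#' @export
censor_at_horizon <- function(times, events, horizon = 5) {
  over <- times > horizon
  data.frame(time = pmin(times, horizon),
             event = as.integer(events == 1 & !over))
}

#' Fit a Cox proportional hazards model with Breslow baseline hazard
#'
#' Thin wrapper around `survival::coxph` (Breslow tie handling) that also
#' stores the Breslow cumulative baseline hazard for absolute-risk
#' prediction. Covariates with no variation are dropped (coefficient fixed at
#' 0) and flagged rather than returned as `NA`.
#'
#' @param covariates data.frame or matrix of numeric covariates.
#' @param times follow-up times (> 0), already administratively censored.
#' @param events 0/1 event indicators.
#' @return a `cox_fit`: list with `coef`, `basehaz` (step function data:
#'   `time`, `hazard`), `covariate_names`, `n`, `events`, `dropped`
#'   (zero-variance covariates), and the underlying `coxph` object.
#' @export
fit_cox <- function(covariates, times, events) {
  X <- as.data.frame(covariates)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  keep <- vapply(X, function(v) stats::var(v) > 0, TRUE)
  dropped <- names(X)[!keep]
  if (length(dropped))
    warning("covariate(s) with no variation dropped (coefficient 0): ",
            paste(dropped, collapse = ", "))
  coefs <- stats::setNames(rep(0, ncol(X)), names(X))
  if (any(keep)) {
    dat <- cbind(X[, keep, drop = FALSE], .time = times, .event = events)
    fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                           data = dat, ties = "breslow",
                           control = survival::coxph.control(iter.max = 50))
    if (any(is.na(stats::coef(fit))))
      stop("Cox model did not converge (possible perfect separation)",
           call. = FALSE)
    if (any(abs(stats::coef(fit)) > 15))
      warning("very large Cox coefficient: possible monotone likelihood ",
              "(perfect separation)")
    coefs[names(stats::coef(fit))] <- stats::coef(fit)
    bh <- survival::basehaz(fit, centered = FALSE)
  } else {
    # null model: Breslow baseline = Nelson-Aalen
    fit <- NULL
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    bh <- data.frame(hazard = cumsum(sf$n.event / sf$n.risk), time = sf$time)
  }
  structure(list(coef = coefs,
                 basehaz = data.frame(time = bh$time, hazard = bh$hazard),
                 covariate_names = names(X), n = length(times),
                 events = sum(events), dropped = dropped, coxph = fit),
            class = "cox_fit")
}

# internal: cumulative baseline hazard at time t (right-continuous step fn,
# 0 before the first event time)
baseline_cumhaz_at <- function(fit, t) {
  bh <- fit$basehaz
  if (t > max(bh$time))
    warning("horizon beyond last observed time; using last baseline value")
  idx <- findInterval(t, bh$time)
  if (idx == 0) 0 else bh$hazard[idx]
}

#' Predicted probability of death by a horizon
#'
#' `1 - exp(-H0(t) * exp(x'beta))` with the Breslow cumulative baseline
#' hazard `H0`; monotone increasing in the linear predictor.
#'
#' @param fit a [fit_cox()] object.
#' @param covariates data.frame/matrix of covariates (same columns as the
#'   fit).
#' @param horizon prediction horizon in years (default 5).
#' @return vector of probabilities in \[0, 1\].
#' @export
predicted_risk <- function(fit, covariates, horizon = 5) {
  X <- as.matrix(as.data.frame(covariates)[, fit$covariate_names, drop = FALSE])
  lp <- as.vector(X %*% fit$coef)
  H0 <- baseline_cumhaz_at(fit, horizon)
  1 - exp(-H0 * exp(lp))
}

#' Harrell's c-index for censored outcomes
#'
#' Over usable pairs -- one subject observed to fail strictly before the
#' other's time (ties on time are unusable) -- the fraction in which the
#' higher predicted risk accompanies the shorter survival; ties in predicted
#' risk score 0.5. Reported on the percent scale (0-100).
#'
#' @param risks predicted risks (higher = worse prognosis).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return concordance percentage.
#' @export
harrell_c_index <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  conc <- 0; usable <- 0
  for (i in which(events == 1)) {
    comp <- which(times > times[i])          # i fails strictly first
    if (!length(comp)) next
    usable <- usable + length(comp)
    conc <- conc + sum(risks[i] > risks[comp]) + 0.5 * sum(risks[i] == risks[comp])
  }
  if (usable == 0) stop("no usable pairs", call. = FALSE)
  100 * conc / usable
}

#' Summary of a predicted-risk distribution
#'
#' Range, nearest-rank 10/25/50/75/90th percentiles, mean and SD on the
#' percent scale.
#'
#' @param risks vector of predicted probabilities.
#' @return one-row data.frame (`min`, `max`, `p10`, `p25`, `p50`, `p75`,
#'   `p90`, `mean`, `sd`), all in percent.
#' @export
risk_distribution_summary <- function(risks) {
  if (!length(risks)) stop("empty risk vector", call. = FALSE)
  pct <- nearest_rank_percentile(risks, c(0.10, 0.25, 0.50, 0.75, 0.90))
  data.frame(min = 100 * min(risks), max = 100 * max(risks),
             p10 = 100 * pct[1], p25 = 100 * pct[2], p50 = 100 * pct[3],
             p75 = 100 * pct[4], p90 = 100 * pct[5],
             mean = 100 * mean(risks),
             sd = 100 * stats::sd(risks))
}
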