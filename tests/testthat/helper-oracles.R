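# Independent oracles used across tests.  These deliberately re-derive each
# quantity by brute force / closed form, sharing no code with the package
# internals they check.

# conditional-independence pattern probability, direct product form
oracle_ci_pattern_prob <- function(pattern, prevalence, se, sp) {
  p1 <- prod(ifelse(pattern == 1, se, 1 - se))
  p0 <- prod(ifelse(pattern == 1, 1 - sp, sp))
  prevalence * p1 + (1 - prevalence) * p0
}

# Monte-Carlo integration of the dependent-pattern probability over z;
# returns estimate and its standard error
oracle_mc_pattern_prob <- function(pattern, prevalence, a, c, n_draws = 1e6,
                                   seed = 99) {
  set.seed(seed)
  z <- rnorm(n_draws)
  per_class <- function(d) {
    acc <- rep(1, n_draws)
    for (j in 1:3) {
      pj <- pnorm(a[d, j] + c[d, j] * z)
      acc <- acc * if (pattern[j] == 1) pj else 1 - pj
    }
    acc
  }
  vals <- prevalence * per_class(2) + (1 - prevalence) * per_class(1)
  list(estimate = mean(vals), se = sd(vals) / sqrt(n_draws))
}

# exhaustive pair enumeration c-index (percent)
oracle_c_index <- function(risks, times, events) {
  conc <- 0; usable <- 0
  n <- length(risks)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # order so the earlier time is first
    a <- i; b <- j
    if (times[j] < times[i]) { a <- j; b <- i }
    if (times[a] == times[b]) next
    if (events[a] != 1) next
    usable <- usable + 1
    if (risks[a] > risks[b]) conc <- conc + 1
    else if (risks[a] == risks[b]) conc <- conc + 0.5
  }
  100 * conc / usable
}

# explicit Breslow log partial likelihood for one binary/continuous covariate
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk_set <- which(times >= times[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk_set])))
  }
  ll
}

# quick small synthetic cohort for reclassification tests
toy_reclass_data <- function(n = 60, seed = 5) {
  set.seed(seed)
  data.frame(time = pmin(rexp(n, 0.15), 5),
             event = rbinom(n, 1, 0.5),
             ln = rbinom(n, 1, 0.4),
             ri = rbinom(n, 1, 0.15),
             marker = runif(n))
}

# spec'd 188-subject printed stage distribution
printed_stage_distribution <- function() {
  data.frame(
    stage = c(rep("local", 99), rep("regional", 66), rep("distant", 23)),
    n_stage = c(rep("not_applicable", 165),
                rep("N0", 3), rep("N1orN2", 11), rep("unknown", 9)))
}

# small fully-valid cohort data.frame
toy_cohort_df <- function() {
  data.frame(subject_id = c("a", "b", "c"),
             stage = c("I", "III", "IV"),
             n_stage = c("not_applicable", "not_applicable", "N0"),
             marker_score = c(0.4, 1.2, 2.8),
             followup_time_years = c(5, 2.5, 0.7),
             death = c(0, 1, 1))
}
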