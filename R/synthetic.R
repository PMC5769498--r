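# Synthetic cohorts with known latent truth.  The generator is the exact
# generative counterpart of the latent class analysis model: latent status
# D ~ Bernoulli(pi), shared random effect Z ~ N(0,1), tests positive with
# probability Phi(a_Dj + c_Dj Z), a continuous marker from class-conditional
# truncated normals (consistent with the EMT test at the configured cut
# point), and exponential survival whose hazard depends on D only.

# truncated-normal CDF on [lo, hi]
trunc_norm_cdf <- function(x, mean, sd, lo = 0, hi = 3) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  pmin(1, pmax(0, (stats::pnorm(x, mean, sd) - plo) / (phi - plo)))
}

# draw from N(mean, sd) truncated to [lo, hi] by inverse CDF
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd); b <- stats::pnorm(hi, mean, sd)
  if (any(b - a < 1e-12))
    stop("truncation interval has negligible mass", call. = FALSE)
  stats::qnorm(a + stats::runif(n) * (b - a), mean, sd)
}

#' Configuration of the synthetic-cohort generator
#'
#' The defaults are the CanCORS-like stated world (see
#' [cancors_like_preset()]). EMT sensitivity/specificity may be left `NA`, in
#' which case they are derived from the marker emission distributions and cut
#' point (guaranteeing consistency); if supplied they are checked against the
#' emission-implied values.
#'
#' @param n cohort size.
#' @param prevalence latent-positive prevalence in (0, 1).
#' @param se,sp length-3 named (emt, ln, ri) marginal accuracies; `se[1]`,
#'   `sp[1]` may be `NA` (derived from the emission).
#' @param c 2x3 matrix of nonnegative dependence loadings (rows class 0 /
#'   class 1).
#' @param marker_mean length-2 `c(d0, d1)` emission means on the 0-3 scale
#'   (class 1 = detached, low for an epithelial marker).
#' @param marker_sd common emission SD.
#' @param cut_point marker cut point defining the EMT test.
#' @param direction marker direction (see [cohort_table()]).
#' @param hazard length-2 `c(d0, d1)` exponential death hazards per year.
#' @param censor_rate exponential censoring hazard (0 = administrative
#'   censoring at the horizon only).
#' @param horizon administrative follow-up horizon in years.
#' @param consistency_tol maximum allowed gap between supplied EMT accuracy
#'   and the emission-implied value.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n = 188,
                             prevalence = 89 / 188,
                             se = c(emt = NA, ln = 0.933, ri = 0.247),
                             sp = c(emt = NA, ln = 0.970, ri = 0.990),
                             c = matrix(0, 2, 3),
                             marker_mean = c(d0 = 1.8, d1 = 0.6),
                             marker_sd = 0.6,
                             cut_point = 0.85,
                             direction = c("epithelial", "mesenchymal_or_inducer"),
                             hazard = c(d0 = 0.039, d1 = 0.139),
                             censor_rate = 0,
                             horizon = 5,
                             consistency_tol = 0.02) {
  direction <- match.arg(direction)
  stopifnot(n >= 1, prevalence > 0, prevalence < 1, marker_sd > 0,
            all(hazard > 0), censor_rate >= 0, horizon > 0,
            cut_point > 0, cut_point <= 3)
  c <- matrix(as.numeric(c), 2, 3, dimnames = list(c("d0", "d1"), TESTS))
  if (any(c < 0)) stop("loadings must be nonnegative", call. = FALSE)
  # emission-implied EMT accuracy: P(test positive | class)
  pos_prob <- function(mu) {
    p_below <- trunc_norm_cdf(cut_point, mu, marker_sd)
    if (direction == "epithelial") p_below else 1 - p_below
  }
  se_emt_emit <- pos_prob(marker_mean["d1"])
  sp_emt_emit <- 1 - pos_prob(marker_mean["d0"])
  se <- stats::setNames(as.numeric(se), TESTS)
  sp <- stats::setNames(as.numeric(sp), TESTS)
  if (is.na(se["emt"])) se["emt"] <- se_emt_emit
  if (is.na(sp["emt"])) sp["emt"] <- sp_emt_emit
  if (abs(se["emt"] - se_emt_emit) > consistency_tol ||
      abs(sp["emt"] - sp_emt_emit) > consistency_tol)
    stop(sprintf(paste0("marker emission inconsistent with EMT test: emission ",
                        "implies Se %.3f / Sp %.3f, config requests %.3f / %.3f"),
                 se_emt_emit, sp_emt_emit, se["emt"], sp["emt"]), call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence, se = se, sp = sp,
                 c = c, marker_mean = marker_mean, marker_sd = marker_sd,
                 cut_point = cut_point, direction = direction,
                 hazard = hazard, censor_rate = censor_rate, horizon = horizon),
            class = "synthetic_config")
}

#' Solve marker emission means for target EMT test accuracies
#'
#' Finds class-conditional truncated-normal means such that thresholding the
#' emitted score at `cut_point` yields the requested marker sensitivity and
#' specificity (epithelial direction: positive below the cut point).
#'
#' @param se,sp target marker sensitivity and specificity.
#' @param cut_point marker cut point.
#' @param marker_sd common emission SD.
#' @return length-2 named vector `c(d0, d1)` of emission means.
#' @export
calibrate_marker_emission <- function(se, sp, cut_point = 0.85, marker_sd = 0.6) {
  # bracket the mean within +/- 4 SD of the cut point; outside that range the
  # truncated-normal CDF at the cut point is numerically 0 or 1 anyway
  lo <- cut_point - 4 * marker_sd
  hi <- cut_point + 4 * marker_sd
  solve_mu <- function(p_below) {
    f <- function(mu) trunc_norm_cdf(cut_point, mu, marker_sd) - p_below
    if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0)
      stop(sprintf("target accuracy %.3f not achievable at cut point %.2f with SD %.2f",
                   p_below, cut_point, marker_sd), call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  c(d0 = solve_mu(1 - sp), d1 = solve_mu(se))
}

#' CanCORS-like synthetic preset
#'
#' A 188-subject stated world calibrated so the expected test margins and
#' death count match the printed cohort: prevalence 89/188 (the
#' regional-or-distant fraction), LN accuracy Se 0.933 / Sp 0.97 and RI
#' accuracy Se 0.247 / Sp 0.99 (solving the margin equations for expected
#' LN+ = 86 and RI+ = 23 exactly), and class death hazards giving 5-year
#' death probabilities 0.50 / 0.177 (expected deaths 62). Conditionally
#' independent tests; marker emission means 0.6 (detached) / 1.8 with SD 0.6,
#' cut point 0.85.
#'
#' @return a `synthetic_config`.
#' @export
cancors_like_preset <- function() {
  pi0 <- 89 / 188
  se_ln <- (86 / 188 - (1 - pi0) * (1 - 0.97)) / pi0
  se_ri <- (23 / 188 - (1 - pi0) * (1 - 0.99)) / pi0
  synthetic_config(
    n = 188, prevalence = pi0,
    se = c(emt = NA, ln = se_ln, ri = se_ri),
    sp = c(emt = NA, ln = 0.97, ri = 0.99),
    hazard = c(d0 = -log(1 - 0.177) / 5, d1 = -log(1 - 0.50) / 5))
}

# internal: latent_class_params equivalent of a synthetic_config
config_params <- function(config) {
  latent_class_params(config$prevalence, config$se, config$sp, config$c)
}

#' Generate a synthetic cohort with known latent truth
#'
#' See [synthetic_config()] for the generative model. The observable part is
#' a valid [cohort_table()] (with `ln_test`/`ri_test` columns and a stage
#' assignment consistent with them, so stage-based imputation reproduces the
#' generated tests); the latent truth (D, Z, per-test error indicators) is
#' attached as the `"truth"` attribute and never leaks into the table itself.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return a `cohort_table` with attribute `truth` (data.frame) and
#'   `config`.
#' @export
generate_cohort <- function(config, seed = 1) {
  set.seed(seed)
  n <- config$n
  params <- config_params(config)
  D <- stats::rbinom(n, 1, config$prevalence)
  Z <- stats::rnorm(n)
  a <- params$a; cc <- params$c
  row <- ifelse(D == 1, 2L, 1L)   # d0 = row 1, d1 = row 2
  tests <- sapply(1:3, function(j) {
    p <- stats::pnorm(a[row, j] + cc[row, j] * Z)
    as.integer(stats::runif(n) < p)
  })
  colnames(tests) <- TESTS
  # marker consistent with the generated EMT test: draw from the class
  # emission restricted to the side of the cut point the test implies
  mu <- config$marker_mean[row]
  pos_below <- config$direction == "epithelial"
  lo <- ifelse(tests[, "emt"] == 1L,
               if (pos_below) 0 else config$cut_point,
               if (pos_below) config$cut_point else 0)
  hi <- ifelse(tests[, "emt"] == 1L,
               if (pos_below) config$cut_point else 3,
               if (pos_below) 3 else config$cut_point)
  marker <- rtrunc_norm(n, mu, config$marker_sd, lo, hi)
  # keep strict-inequality side of the cut point open despite FP rounding
  open_hi <- hi == config$cut_point & hi < 3
  marker[open_hi & marker >= config$cut_point] <- config$cut_point - 1e-9
  marker <- pmin(pmax(marker, 0), 3)
  # survival: exponential by class, independent censoring, admin horizon
  T_death <- stats::rexp(n, config$hazard[row])
  C <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else Inf
  time <- pmin(T_death, C, config$horizon)
  death <- as.integer(T_death <= pmin(C, config$horizon))
  # stage consistent with the generated tests
  stage <- ifelse(tests[, "ri"] == 1L, "distant",
                  ifelse(tests[, "ln"] == 1L, "regional", "local"))
  n_stage <- ifelse(stage == "distant",
                    ifelse(tests[, "ln"] == 1L, "N1orN2", "N0"),
                    "not_applicable")
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    stage = stage, n_stage = n_stage,
    marker_score = marker,
    followup_time_years = time, death = death,
    ln_test = tests[, "ln"], ri_test = tests[, "ri"])
  cohort <- cohort_table(df, config$direction)
  attr(cohort, "truth") <- data.frame(
    subject_id = df$subject_id, D = D, z = Z,
    err_emt = as.integer(tests[, "emt"] != D),
    err_ln = as.integer(tests[, "ln"] != D),
    err_ri = as.integer(tests[, "ri"] != D))
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- seed
  cohort
}

#' Exact test-pattern probabilities of a synthetic configuration
#'
#' The 8 (emt, ln, ri) pattern probabilities implied by the configuration,
#' computed by Gauss-Hermite quadrature; they sum to 1 and match the
#' empirical frequencies of [generate_cohort()] in large samples.
#'
#' @param config a [synthetic_config()].
#' @param quad_order quadrature order.
#' @return named vector of 8 probabilities (names like `"101"` for
#'   emt+, ln-, ri+).
#' @export
theoretical_pattern_probs <- function(config, quad_order = 60) {
  params <- config_params(config)
  gh <- gauss_hermite(quad_order)
  grid <- pattern_grid()
  Y <- as.matrix(grid[, TESTS]); storage.mode(Y) <- "double"
  p <- all_pattern_probs(params, gh, Y)
  stats::setNames(p, paste0(grid$emt, grid$ln, grid$ri))
}
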