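# Bayesian 3-test latent class model with probit-link conditional dependence.
#
# Subject i has latent detachment status D_i ~ Bernoulli(pi) and a shared
# standard-normal random effect Z_i.  Test j is positive with probability
# Phi(a_dj + c_dj z) given D = d; the loading c_dj induces within-class
# correlation of test errors.  Marginalizing Z gives the accuracy of test j:
# Se_j = Phi(a_1j / sqrt(1 + c_1j^2)), 1 - Sp_j = Phi(a_0j / sqrt(1 + c_0j^2)).

DEPENDENCE_MODELS <- c("fully_independent", "fully_dependent",
                       paste0("PDM", 1:6))

#' Conditional probability of a positive test result
#'
#' `Phi(a + c z)`: probability test j is positive for a subject in latent
#' class d with random effect `z`, where `a`, `c` are the class's probit
#' intercept and dependence loading for that test.
#'
#' @param a probit intercept.
#' @param c dependence loading.
#' @param z random-effect value.
#' @return probability in (0, 1); vectorized.
#' @export
conditional_positive_prob <- function(a, c, z) stats::pnorm(a + c * z)

#' Marginal test accuracy implied by probit coefficients
#'
#' Integrates `Phi(a + c z)` over `z ~ N(0, 1)` in closed form:
#' `Phi(a / sqrt(1 + c^2))`. For class 1 this is the sensitivity of the test;
#' for class 0 it is 1 - specificity.
#'
#' @param a probit intercept (finite).
#' @param c dependence loading (>= 0).
#' @return probability in (0, 1); vectorized.
#' @export
marginal_accuracy <- function(a, c) {
  if (any(c < 0)) stop("loading c must be >= 0", call. = FALSE)
  stats::pnorm(a / sqrt(1 + c^2))
}

# internal: probit intercept giving marginal accuracy p at loading c
intercept_for_accuracy <- function(p, c) stats::qnorm(p) * sqrt(1 + c^2)

#' Latent class model parameters
#'
#' Builds the full parameter set from the marginal-accuracy scale: the probit
#' intercepts `a` are recovered as `qnorm(acc) * sqrt(1 + c^2)` so that the
#' requested sensitivities/specificities hold exactly whatever the loadings.
#'
#' @param prevalence latent-positive prevalence, in (0, 1).
#' @param se,sp length-3 sensitivities / specificities for tests
#'   (emt, ln, ri).
#' @param c 2x3 matrix of nonnegative loadings, rows = class 0 / class 1,
#'   columns = tests; defaults to all zero (conditional independence).
#' @return a `latent_class_params` list with elements `prevalence`, `a`, `c`,
#'   `se`, `sp`.
#' @export
latent_class_params <- function(prevalence, se, sp, c = matrix(0, 2, 3)) {
  stopifnot(length(se) == 3, length(sp) == 3,
            prevalence > 0, prevalence < 1,
            all(se > 0 & se < 1), all(sp > 0 & sp < 1))
  c <- matrix(as.numeric(c), 2, 3,
              dimnames = list(c("d0", "d1"), TESTS))
  if (any(c < 0)) stop("loadings must be nonnegative", call. = FALSE)
  a <- rbind(d0 = intercept_for_accuracy(1 - sp, c["d0", ]),
             d1 = intercept_for_accuracy(se, c["d1", ]))
  colnames(a) <- TESTS
  structure(list(prevalence = prevalence, a = a, c = c,
                 se = stats::setNames(se, TESTS),
                 sp = stats::setNames(sp, TESTS)),
            class = "latent_class_params")
}

#' Conditional dependence structure
#'
#' Each structure names the set of loadings constrained to zero:
#' `fully_independent` constrains all six, `fully_dependent` none, and the six
#' partial dependence models constrain the Se & Sp loadings of one test
#' (PDM1 = EMT, PDM2 = LN, PDM3 = RI) or of a pair of tests (PDM4 = EMT+LN,
#' PDM5 = EMT+RI, PDM6 = LN+RI).
#'
#' @param name one of `r paste(DEPENDENCE_MODELS, collapse=", ")`.
#' @return a `dependence_spec`: list with `name` and 2x3 logical matrix
#'   `free` (TRUE where the loading is estimated).
#' @export
dependence_spec <- function(name = DEPENDENCE_MODELS) {
  name <- match.arg(name)
  constrained_tests <- switch(name,
    fully_independent = TESTS,
    fully_dependent   = character(0),
    PDM1 = "emt", PDM2 = "ln", PDM3 = "ri",
    PDM4 = c("emt", "ln"), PDM5 = c("emt", "ri"), PDM6 = c("ln", "ri"))
  free <- matrix(TRUE, 2, 3, dimnames = list(c("d0", "d1"), TESTS))
  free[, constrained_tests] <- FALSE
  structure(list(name = name, free = free), class = "dependence_spec")
}

#' Uniform prior specification on the accuracy scale
#'
#' Defaults follow the analysis design: lymph node evaluation and radiologic
#' imaging each get sensitivity uniform(0.60, 0.70) and specificity
#' uniform(0.95, 0.99) from external literature; the marker under evaluation
#' gets uninformative uniform(0, 1) priors; prevalence is uniform(0, 1) and
#' each unconstrained loading uniform(0, 3).
#'
#' @param emt_se,emt_sp,ln_se,ln_sp,ri_se,ri_sp length-2 `c(lo, hi)` supports.
#' @param prevalence length-2 support for the prevalence.
#' @param c_support length-2 support for each free loading.
#' @return a `prior_spec` list with 3x2 matrices `se` and `sp` (rows = tests),
#'   plus `prevalence` and `c_support`.
#' @export
build_priors <- function(emt_se = c(0, 1), emt_sp = c(0, 1),
                         ln_se = c(0.60, 0.70), ln_sp = c(0.95, 0.99),
                         ri_se = c(0.60, 0.70), ri_sp = c(0.95, 0.99),
                         prevalence = c(0, 1), c_support = c(0, 3)) {
  check <- function(iv, nm, hi_max = 1) {
    if (length(iv) != 2 || !(iv[1] < iv[2]) || iv[1] < 0 || iv[2] > hi_max)
      stop(sprintf("invalid prior interval for %s: (%g, %g)", nm, iv[1], iv[2]),
           call. = FALSE)
    iv
  }
  se <- rbind(emt = check(emt_se, "emt Se"), ln = check(ln_se, "ln Se"),
              ri = check(ri_se, "ri Se"))
  sp <- rbind(emt = check(emt_sp, "emt Sp"), ln = check(ln_sp, "ln Sp"),
              ri = check(ri_sp, "ri Sp"))
  structure(list(se = se, sp = sp,
                 prevalence = check(prevalence, "prevalence"),
                 c_support = check(c_support, "c", hi_max = Inf)),
            class = "prior_spec")
}

# internal: per-class probabilities of the 8 patterns.
# If every loading of a class is zero the integrand is constant in z and the
# conditional-independence product form is used; otherwise Gauss-Hermite
# quadrature over the random effect.  Y is the 8x3 0/1 pattern matrix.
class_pattern_probs <- function(a_row, c_row, gh, Y) {
  if (all(c_row == 0)) {
    lp <- stats::pnorm(a_row, log.p = TRUE)
    lq <- stats::pnorm(a_row, lower.tail = FALSE, log.p = TRUE)
    as.vector(exp(Y %*% pmax(lp, -700) + (1 - Y) %*% pmax(lq, -700)))
  } else {
    arg <- outer(gh$z, c_row) + rep(a_row, each = length(gh$z))  # Q x 3
    lp <- pmax(stats::pnorm(arg, log.p = TRUE), -700)
    lq <- pmax(stats::pnorm(arg, lower.tail = FALSE, log.p = TRUE), -700)
    as.vector(exp(Y %*% t(lp) + (1 - Y) %*% t(lq)) %*% gh$w)
  }
}

# internal: all 8 pattern probabilities for a parameter set
all_pattern_probs <- function(params, gh, Y) {
  p1 <- class_pattern_probs(params$a["d1", ], params$c["d1", ], gh, Y)
  p0 <- class_pattern_probs(params$a["d0", ], params$c["d0", ], gh, Y)
  params$prevalence * p1 + (1 - params$prevalence) * p0
}

#' Probability of one test-result pattern under the latent class model
#'
#' Mixture over the two latent classes of the within-class joint probability
#' of the (emt, ln, ri) results, the random effect integrated out by
#' deterministic Gauss-Hermite quadrature.
#'
#' @param pattern length-3 0/1 vector (emt, ln, ri).
#' @param params a [latent_class_params()] object.
#' @param quad_order Gauss-Hermite order (>= 2; default 30).
#' @return probability in (0, 1).
#' @export
pattern_likelihood <- function(pattern, params, quad_order = 30) {
  stopifnot(length(pattern) == 3, all(pattern %in% c(0, 1)))
  gh <- gauss_hermite(quad_order)
  Y <- matrix(as.numeric(pattern), 1, 3)
  integrand <- function(a_row, c_row) {
    arg <- outer(gh$z, c_row) + rep(a_row, each = quad_order)
    lp <- pmax(stats::pnorm(arg, log.p = TRUE), -700)
    lq <- pmax(stats::pnorm(arg, lower.tail = FALSE, log.p = TRUE), -700)
    sum(gh$w * exp(as.vector(Y %*% t(lp) + (1 - Y) %*% t(lq))))
  }
  params$prevalence * integrand(params$a["d1", ], params$c["d1", ]) +
    (1 - params$prevalence) * integrand(params$a["d0", ], params$c["d0", ])
}

#' Multinomial log-likelihood of observed pattern counts
#'
#' @param counts a [pattern_counts()] object (or data.frame with `emt`, `ln`,
#'   `ri`, `count`).
#' @param params a [latent_class_params()] object.
#' @param quad_order Gauss-Hermite order.
#' @return log-likelihood; `-Inf` (with a warning) if a pattern with nonzero
#'   count has underflowed probability.
#' @export
log_likelihood <- function(counts, params, quad_order = 30) {
  gh <- gauss_hermite(quad_order)
  Y <- as.matrix(counts[, TESTS])
  storage.mode(Y) <- "double"
  p <- all_pattern_probs(params, gh, Y)
  if (any(p <= 0 & counts$count > 0)) {
    warning("pattern probability underflow with nonzero count")
    return(-Inf)
  }
  keep <- counts$count > 0
  sum(counts$count[keep] * log(p[keep]))
}
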