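test_that("generate_cohort is seed-deterministic and hides truth from the table", {
  cfg <- cancors_like_preset()
  c1 <- generate_cohort(cfg, seed = 3)
  c2 <- generate_cohort(cfg, seed = 3)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "truth"), attr(c2, "truth"))
  expect_false(identical(as.data.frame(c1),
                         as.data.frame(generate_cohort(cfg, seed = 4))))
  expect_false(any(c("D", "z") %in% names(c1)))
  expect_s3_class(c1, "cohort_table")
  # stage assignment is consistent with the generated tests
  imp <- impute_tests_from_stage(c1$stage, c1$n_stage)
  expect_equal(imp$ln_test, c1$ln_test)
  expect_equal(imp$ri_test, c1$ri_test)
  # cohort CSV written by the generator is readable by the data module
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, path)
  expect_equal(nrow(read_cohort(path)), 188)
})

test_that("degenerate prevalence gives a single class with test rates near Se", {
  cfg <- synthetic_config(n = 4000, prevalence = 0.999)
  coh <- generate_cohort(cfg, seed = 9)
  truth <- attr(coh, "truth")
  expect_gt(mean(truth$D), 0.99)
  cfgp <- attr(coh, "config")
  in1 <- truth$D == 1
  for (j in c("ln", "ri")) {
    phat <- mean(coh[[paste0(j, "_test")]][in1])
    se_j <- cfgp$se[j]
    expect_lt(abs(phat - se_j), 3 * sqrt(se_j * (1 - se_j) / sum(in1)))
  }
})

test_that("empirical test accuracies match the closed form at large n (c = 0)", {
  cfg <- synthetic_config(n = 1e5, prevalence = 0.45,
                          se = c(emt = NA, ln = 0.65, ri = 0.65),
                          sp = c(emt = NA, ln = 0.97, ri = 0.97),
                          marker_mean = c(d0 = 1.35, d1 = 0.72))
  coh <- generate_cohort(cfg, seed = 21)
  truth <- attr(coh, "truth")
  emt <- dichotomize_marker(coh$marker_score, cfg$cut_point)
  tests <- cbind(emt = emt, ln = coh$ln_test, ri = coh$ri_test)
  for (j in 1:3) {
    for (d in 0:1) {
      sel <- truth$D == d
      p_true <- if (d == 1) cfg$se[j] else 1 - cfg$sp[j]
      phat <- mean(tests[sel, j])
      expect_lt(abs(phat - p_true),
                3 * sqrt(p_true * (1 - p_true) / sum(sel)))
    }
  }
})

test_that("theoretical pattern probabilities: normalization, closed form, simulation", {
  cfg <- synthetic_config()
  p <- theoretical_pattern_probs(cfg)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # c = 0: equals the conditional-independence closed form
  grid <- expand.grid(emt = 0:1, ln = 0:1, ri = 0:1)
  for (i in 1:8) {
    y <- unlist(grid[i, ])
    expect_equal(unname(p[paste0(y[1], y[2], y[3])]),
                 oracle_ci_pattern_prob(y, cfg$prevalence, cfg$se, cfg$sp),
                 tolerance = 1e-10)
  }
  # dependent case agrees with large-sample pattern frequencies
  cfg2 <- synthetic_config(n = 1e5,
                           c = matrix(c(0.8, 1.2, 0.5, 0.9, 0, 0.7), 2, 3))
  p2 <- theoretical_pattern_probs(cfg2)
  cnt <- pattern_counts(generate_cohort(cfg2, seed = 31), cfg2$cut_point)
  key <- paste0(cnt$emt, cnt$ln, cnt$ri)
  for (i in 1:8) {
    se_mult <- sqrt(p2[key[i]] * (1 - p2[key[i]]) / 1e5)
    expect_lt(abs(cnt$count[i] / 1e5 - p2[key[i]]), 3 * se_mult + 1e-9)
  }
})

test_that("inconsistent marker emission vs requested EMT accuracy is refused", {
  expect_error(synthetic_config(se = c(emt = 0.9, ln = 0.65, ri = 0.65),
                                sp = c(emt = 0.9, ln = 0.97, ri = 0.97)),
               "inconsistent")
})

test_that("the CanCORS-like preset is calibrated to the printed margins", {
  cfg <- cancors_like_preset()
  expect_equal(cfg$n, 188L)
  p <- theoretical_pattern_probs(cfg)
  grid <- expand.grid(emt = 0:1, ln = 0:1, ri = 0:1)
  key <- paste0(grid$emt, grid$ln, grid$ri)
  expect_equal(188 * sum(p[key][grid$ln == 1]), 86, tolerance = 1e-6)
  expect_equal(188 * sum(p[key][grid$ri == 1]), 23, tolerance = 1e-6)
  # Monte-Carlo check over 200 seeds: mean LN+ within 5 of 86, deaths within 6 of 62
  stats <- vapply(1:200, function(s) {
    coh <- generate_cohort(cfg, seed = s)
    c(ln = sum(coh$ln_test), ri = sum(coh$ri_test),
      deaths = sum(coh$death == 1 & coh$followup_time_years <= 5))
  }, c(ln = 0, ri = 0, deaths = 0))
  expect_lt(abs(mean(stats["ln", ]) - 86), 5)
  expect_lt(abs(mean(stats["ri", ]) - 23), 5)
  expect_lt(abs(mean(stats["deaths", ]) - 62), 6)
})

test_that("five-year death fraction matches the exponential expectation", {
  cfg <- cancors_like_preset()
  p_die <- cfg$prevalence * (1 - exp(-5 * cfg$hazard["d1"])) +
    (1 - cfg$prevalence) * (1 - exp(-5 * cfg$hazard["d0"]))
  big <- synthetic_config(n = 2e4, prevalence = cfg$prevalence,
                          se = cfg$se, sp = cfg$sp, hazard = cfg$hazard)
  coh <- generate_cohort(big, seed = 12)
  frac <- mean(coh$death == 1)
  expect_lt(abs(frac - p_die), 3 * sqrt(p_die * (1 - p_die) / 2e4))
})

test_that("marker monotonicity holds in generated cohorts", {
  coh <- generate_cohort(cancors_like_preset(), seed = 2)
  cuts <- seq(0.2, 2.8, by = 0.2)
  pos <- vapply(cuts, function(cp) sum(dichotomize_marker(coh$marker_score, cp)), 0L)
  expect_true(all(diff(pos) >= 0))
})

test_that("calibrate_marker_emission inverts the emission-accuracy map", {
  mu <- calibrate_marker_emission(se = 0.55, sp = 0.40, cut_point = 0.85)
  cfg <- synthetic_config(marker_mean = mu)
  expect_equal(unname(cfg$se["emt"]), 0.55, tolerance = 1e-6)
  expect_equal(unname(cfg$sp["emt"]), 0.40, tolerance = 1e-6)
})
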