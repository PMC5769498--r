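# End-to-end orchestration: diagnostic-accuracy pipeline (Table-2 shape),
# prediction-increment pipeline (Table-3/4 shapes), and the exhaustive
# cut-point scan.

#' Assemble a run configuration
#'
#' @param cohort a [cohort_table()], or NULL to use `preset`.
#' @param preset name of a synthetic preset (`"cancors_like"`), used when no
#'   cohort is supplied.
#' @param seed master seed; drives cohort simulation, MCMC and bootstrap.
#' @param cut_points marker cut points to evaluate (default 0.52, 0.60, 0.85).
#' @param marker_forms forms of the marker variable for prediction models:
#'   `"continuous"` and/or numeric cut points; default continuous plus
#'   `cut_points`.
#' @param models dependence structures for the accuracy pipeline.
#' @param priors a [build_priors()] object.
#' @param mcmc list with `burn_in`, `iterations` (seed is derived from
#'   `seed`).
#' @param risk_cuts risk category cut points (default 0.20/0.30/0.40).
#' @param bootstrap_B bootstrap replicates for CIs (default 1000).
#' @param horizon prediction horizon in years.
#' @param quad_order Gauss-Hermite order.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = NULL, preset = "cancors_like", seed = 1,
                       cut_points = c(0.52, 0.60, 0.85),
                       marker_forms = NULL,
                       models = DEPENDENCE_MODELS,
                       priors = build_priors(),
                       mcmc = list(burn_in = 5000, iterations = 50000),
                       risk_cuts = c(0.20, 0.30, 0.40),
                       bootstrap_B = 1000, horizon = 5, quad_order = 30) {
  if (is.null(marker_forms)) marker_forms <- c(list("continuous"), as.list(cut_points))
  if (!length(marker_forms)) stop("at least one marker form required", call. = FALSE)
  structure(list(cohort = cohort, preset = preset, seed = as.integer(seed),
                 cut_points = cut_points, marker_forms = marker_forms,
                 models = models, priors = priors, mcmc = mcmc,
                 risk_cuts = risk_cuts, bootstrap_B = bootstrap_B,
                 horizon = horizon, quad_order = quad_order),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Recognized fields mirror the arguments of [run_config()]; `cohort_csv`
#' (and optional `cores_csv`) name input files, `priors` is a list of
#' interval pairs.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- NULL
  if (!is.null(cfg$cohort_csv))
    cohort <- read_cohort(cfg$cohort_csv, cfg$cores_csv,
                          cfg$marker_direction %||% "epithelial")
  priors <- if (is.null(cfg$priors)) build_priors()
            else do.call(build_priors, lapply(cfg$priors, as.numeric))
  args <- list(cohort = cohort, priors = priors)
  for (f in c("preset", "seed", "cut_points", "marker_forms", "models",
              "mcmc", "risk_cuts", "bootstrap_B", "horizon", "quad_order"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(args$marker_forms)) args$marker_forms <- as.list(args$marker_forms)
  if (!is.null(args$mcmc)) args$mcmc <- as.list(args$mcmc)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: materialize the cohort named by a config
resolve_cohort <- function(config) {
  if (!is.null(config$cohort)) return(config$cohort)
  preset <- switch(config$preset,
                   cancors_like = cancors_like_preset(),
                   stop("unknown preset: ", config$preset, call. = FALSE))
  generate_cohort(preset, seed = config$seed)
}

#' Run the diagnostic-accuracy pipeline
#'
#' For each marker cut point, cross-classifies the cohort into the 8 test
#' patterns and fits all requested conditional-dependence structures,
#' reporting marker sensitivity and specificity (percent, with 95% credible
#' intervals) per cut point and model.
#'
#' @param config a [run_config()].
#' @return an `accuracy_report`: list with `table` (cut_point x model rows),
#'   `provenance` (seed, priors, schedule), and the per-cut-point suites.
#' @export
run_accuracy_pipeline <- function(config = run_config()) {
  cohort <- resolve_cohort(config)
  mcmc <- list(burn_in = config$mcmc$burn_in,
               iterations = config$mcmc$iterations,
               seed = config$seed)
  suites <- lapply(config$cut_points, function(cp) {
    counts <- pattern_counts(cohort, cp)
    dependence_model_suite(counts, config$priors, mcmc,
                           models = config$models,
                           quad_order = config$quad_order)
  })
  names(suites) <- as.character(config$cut_points)
  table <- do.call(rbind, lapply(seq_along(suites), function(i) {
    cbind(cut_point = config$cut_points[i], suites[[i]]$table)
  }))
  rownames(table) <- NULL
  structure(list(table = table, suites = suites,
                 provenance = list(seed = config$seed, mcmc = mcmc,
                                   priors = config$priors,
                                   models = config$models,
                                   cut_points = config$cut_points,
                                   n = nrow(cohort))),
            class = "accuracy_report")
}

# internal: covariate data.frame for a marker form
marker_covariate <- function(cohort, form, direction) {
  if (identical(form, "continuous")) {
    data.frame(marker = cohort$marker_score)
  } else {
    data.frame(marker = dichotomize_marker(cohort$marker_score,
                                           as.numeric(form), direction))
  }
}

form_label <- function(form) {
  if (identical(form, "continuous")) "continuous"
  else sprintf("cut_%g", as.numeric(form))
}

# internal: calibration that degrades to NA (with a warning) when the
# cross-classified table collapses below 3 usable cells
safe_calibration <- function(...) {
  tryCatch(reclassification_calibration(...), error = function(e) {
    warning("calibration statistic unavailable: ", conditionMessage(e))
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
         cells = NULL)
  })
}

# internal: full reclassification comparison of base vs base+marker on one
# data.frame (refits both models; used directly and inside the bootstrap)
compare_models <- function(dat, horizon, cats) {
  base_fit <- fit_cox(dat[, c("ln", "ri")], dat$time, dat$event)
  new_fit <- fit_cox(dat[, c("ln", "ri", "marker")], dat$time, dat$event)
  base_risk <- predicted_risk(base_fit, dat, horizon)
  new_risk <- predicted_risk(new_fit, dat, horizon)
  status <- five_year_status(dat$time, dat$event, horizon)
  bc <- assign_risk_category(base_risk, cats)
  nc <- assign_risk_category(new_risk, cats)
  list(base_fit = base_fit, new_fit = new_fit,
       base_risk = base_risk, new_risk = new_risk, status = status,
       base_cat = bc, new_cat = nc,
       c_base = harrell_c_index(base_risk, dat$time, dat$event),
       c_new = harrell_c_index(new_risk, dat$time, dat$event),
       event_nri = event_nri(bc, nc, status),
       nonevent_nri = nonevent_nri(bc, nc, status),
       idi = idi(base_risk, new_risk, status))
}

#' Run the prediction-increment pipeline
#'
#' Fits the base Cox model (lymph node + imaging, imputed from stage when not
#' observed) and one augmented model per marker form; reports predicted-risk
#' distribution summaries, c-indices, risk stratification tables, event and
#' non-event NRI, IDI (all with percentile bootstrap CIs refitting both
#' models per replicate) and the reclassification calibration statistic.
#'
#' @param config a [run_config()].
#' @return a `prediction_report`: list with `risk_table` (distribution
#'   summary rows), `metrics` (one row per marker form), `strat_tables`,
#'   `per_subject` risks, and `provenance`.
#' @export
run_prediction_pipeline <- function(config = run_config()) {
  cohort <- resolve_cohort(config)
  direction <- attr(cohort, "marker_direction")
  cats <- risk_categories(config$risk_cuts)
  horizon <- config$horizon
  tests <- resolve_tests(cohort)
  cens <- censor_at_horizon(cohort$followup_time_years, cohort$death, horizon)
  base_dat <- data.frame(time = cens$time, event = cens$event,
                         ln = tests$ln_test, ri = tests$ri_test)

  base_fit <- fit_cox(base_dat[, c("ln", "ri")], base_dat$time, base_dat$event)
  base_risk <- predicted_risk(base_fit, base_dat, horizon)
  risk_table <- cbind(model = "base", risk_distribution_summary(base_risk))
  c_base_boot <- bootstrap_intervals(function(d) {
    f <- fit_cox(d[, c("ln", "ri")], d$time, d$event)
    harrell_c_index(predicted_risk(f, d, horizon), d$time, d$event)
  }, base_dat, B = config$bootstrap_B, seed = config$seed)

  metrics <- list(); strat <- list(); per_subject <- list()
  for (form in config$marker_forms) {
    lab <- form_label(form)
    dat <- cbind(base_dat, marker_covariate(cohort, form, direction))
    cmp <- compare_models(dat, horizon, cats)
    boot <- function(metric) {
      bootstrap_intervals(function(d) compare_models(d, horizon, cats)[[metric]],
                          dat, B = config$bootstrap_B, seed = config$seed)
    }
    b_cnew <- boot("c_new"); b_env <- boot("event_nri")
    b_nnv <- boot("nonevent_nri"); b_idi <- boot("idi")
    calib <- safe_calibration(
      cmp$new_risk, dat$time, dat$event, cats, horizon,
      cells = paste(cmp$base_cat, cmp$new_cat, sep = ":"))
    st <- stratification_table(cmp$base_risk, cmp$new_risk, cmp$status, cats)
    risk_table <- rbind(risk_table,
                        cbind(model = lab, risk_distribution_summary(cmp$new_risk)))
    metrics[[lab]] <- data.frame(
      form = lab,
      c_index = cmp$c_new, c_index_lo = b_cnew$lo95, c_index_hi = b_cnew$hi95,
      moved_up = st$moved_up, moved_up_pct = st$moved_up_pct,
      moved_down = st$moved_down, moved_down_pct = st$moved_down_pct,
      reclassified = st$reclassified, reclassified_pct = st$reclassified_pct,
      calibration_stat = calib$statistic, calibration_p = calib$p_value,
      event_nri = cmp$event_nri, event_nri_lo = b_env$lo95,
      event_nri_hi = b_env$hi95,
      nonevent_nri = cmp$nonevent_nri, nonevent_nri_lo = b_nnv$lo95,
      nonevent_nri_hi = b_nnv$hi95,
      idi = cmp$idi, idi_lo = b_idi$lo95, idi_hi = b_idi$hi95)
    strat[[lab]] <- st
    per_subject[[lab]] <- data.frame(subject_id = cohort$subject_id,
                                     risk_base = cmp$base_risk,
                                     risk_new = cmp$new_risk)
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  rownames(risk_table) <- NULL
  structure(list(risk_table = risk_table, metrics = metrics,
                 strat_tables = strat, per_subject = per_subject,
                 c_base = c_base_boot,
                 provenance = list(seed = config$seed, B = config$bootstrap_B,
                                   risk_cuts = config$risk_cuts,
                                   horizon = horizon, n = nrow(cohort),
                                   marker_forms = vapply(config$marker_forms,
                                                         form_label, ""))),
            class = "prediction_report")
}

#' Exhaustive cut-point scan
#'
#' For each cut point in the grid: number of marker-positive subjects, marker
#' Se/Sp from the chosen dependence structure, and the prediction-increment
#' metrics of the dichotomized marker (c-index, event/non-event NRI, IDI,
#' calibration p). Point estimates only (no bootstrap), so a dense grid stays
#' tractable.
#'
#' @param config a [run_config()].
#' @param grid cut points in (0, 3]; defaults to the distinct observed marker
#'   values (every achievable dichotomization).
#' @param scan_model dependence structure for the accuracy column.
#' @return data.frame, one row per cut point.
#' @export
cutpoint_scan <- function(config = run_config(), grid = NULL,
                          scan_model = "fully_independent") {
  cohort <- resolve_cohort(config)
  direction <- attr(cohort, "marker_direction")
  if (is.null(grid)) grid <- sort(unique(cohort$marker_score))
  grid <- grid[grid > 0 & grid <= 3]
  if (!length(grid)) stop("empty cut-point grid", call. = FALSE)
  cats <- risk_categories(config$risk_cuts)
  horizon <- config$horizon
  tests <- resolve_tests(cohort)
  cens <- censor_at_horizon(cohort$followup_time_years, cohort$death, horizon)
  mcmc <- list(burn_in = config$mcmc$burn_in,
               iterations = config$mcmc$iterations, seed = config$seed)
  rows <- lapply(grid, function(cp) {
    emt <- dichotomize_marker(cohort$marker_score, cp, direction)
    counts <- pattern_counts(cohort, cp, direction)
    fit <- fit_latent_class(counts, dependence_spec(scan_model),
                            config$priors, mcmc, config$quad_order)
    s <- fit$summary
    dat <- data.frame(time = cens$time, event = cens$event,
                      ln = tests$ln_test, ri = tests$ri_test, marker = emt)
    cmp <- compare_models(dat, horizon, cats)
    calib <- safe_calibration(
      cmp$new_risk, dat$time, dat$event, cats, horizon,
      cells = paste(cmp$base_cat, cmp$new_cat, sep = ":"))
    data.frame(cut_point = cp, positives = sum(emt),
               se = 100 * s$median[s$parameter == "se_emt"],
               sp = 100 * s$median[s$parameter == "sp_emt"],
               c_index = cmp$c_new, event_nri = cmp$event_nri,
               nonevent_nri = cmp$nonevent_nri, idi = cmp$idi,
               calibration_p = calib$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline reports to disk
#'
#' CSV tables plus one JSON bundle embedding the full provenance (seed,
#' priors, schedule); reruns with the same configuration are byte-identical.
#'
#' @param report an `accuracy_report` or `prediction_report`.
#' @param out_dir output directory (created if needed).
#' @return invisible vector of files written.
#' @export
write_reports <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (inherits(report, "accuracy_report")) {
    emit_csv(report$table, "accuracy_table.csv")
    bundle <- list(kind = "accuracy", table = report$table,
                   provenance = report$provenance[c("seed", "mcmc", "models",
                                                    "cut_points", "n")])
  } else if (inherits(report, "prediction_report")) {
    emit_csv(report$risk_table, "risk_distributions.csv")
    emit_csv(report$metrics, "reclassification_metrics.csv")
    for (lab in names(report$strat_tables)) {
      st <- report$strat_tables[[lab]]
      m <- as.data.frame.matrix(st$overall)
      emit_csv(cbind(base_category = rownames(m), m),
               sprintf("stratification_%s.csv", lab))
    }
    bundle <- list(kind = "prediction", risk_table = report$risk_table,
                   metrics = report$metrics,
                   c_base = report$c_base[c("point", "lo95", "hi95")],
                   provenance = report$provenance)
  } else stop("unknown report type", call. = FALSE)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}
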