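# Risk reclassification machinery: categories, stratification tables,
# event/non-event NRI, IDI, reclassification calibration, bootstrap CIs.

#' Mortality risk categories
#'
#' Default cut points 20/30/40% give the categories 0-20%, 20-30%, 30-40%
#' and >40%; intervals are half-open on the right, so a risk exactly at a cut
#' point falls in the higher category.
#'
#' @param cuts strictly increasing probabilities in (0, 1).
#' @return a `risk_categories` list with `cuts` and `labels`.
#' @export
risk_categories <- function(cuts = c(0.20, 0.30, 0.40)) {
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 1))
    stop("cut points must be strictly increasing within (0, 1)", call. = FALSE)
  pct <- function(p) sprintf("%g%%", 100 * p)
  labels <- c(paste0("0-", pct(cuts[1])),
              if (length(cuts) > 1)
                paste0(pct(cuts[-length(cuts)]), "-", pct(cuts[-1])),
              paste0(">", pct(cuts[length(cuts)])))
  structure(list(cuts = cuts, labels = labels), class = "risk_categories")
}

#' Assign predicted risks to risk categories
#'
#' @param p predicted probabilities in \[0, 1\].
#' @param cats a [risk_categories()] object.
#' @return integer category indices (1 = lowest), with the labels as levels
#'   attribute.
#' @export
assign_risk_category <- function(p, cats = risk_categories()) {
  if (any(p < 0 | p > 1)) stop("risks must lie in [0, 1]", call. = FALSE)
  idx <- findInterval(p, cats$cuts) + 1L
  attr(idx, "labels") <- cats$labels
  idx
}

#' Risk stratification table
#'
#' Cross-classifies subjects by base-model and new-model risk category,
#' overall and within events / non-events, with counts (and percent of n)
#' moved to a higher category, moved to a lower category, and total
#' reclassified.
#'
#' @param base_risks,new_risks predicted probabilities from the two models.
#' @param events 0/1 event status used for the per-stratum tables (may be a
#'   three-level status from [five_year_status()]; censored subjects appear
#'   only in the overall table).
#' @param cats a [risk_categories()] object.
#' @return a `stratification_table` list: `overall`, `events`, `nonevents`
#'   (K x K matrices), `moved_up`, `moved_down`, `reclassified` (counts),
#'   and the matching `_pct` percentages of n.
#' @export
stratification_table <- function(base_risks, new_risks, events,
                                 cats = risk_categories()) {
  n <- length(base_risks)
  if (length(new_risks) != n || length(events) != n)
    stop("length mismatch between risks and events", call. = FALSE)
  b <- assign_risk_category(base_risks, cats)
  a <- assign_risk_category(new_risks, cats)
  K <- length(cats$labels)
  tab <- function(sel) {
    m <- table(factor(b[sel], 1:K, cats$labels),
               factor(a[sel], 1:K, cats$labels))
    names(dimnames(m)) <- c("base", "new")
    m
  }
  st <- if (is.numeric(events)) ifelse(events == 1, "event", "nonevent")
        else as.character(events)
  up <- sum(a > b); down <- sum(a < b)
  structure(list(
    overall = tab(rep(TRUE, n)),
    events = tab(st == "event"),
    nonevents = tab(st == "nonevent"),
    moved_up = up, moved_down = down, reclassified = up + down,
    moved_up_pct = 100 * up / n, moved_down_pct = 100 * down / n,
    reclassified_pct = 100 * (up + down) / n, n = n),
    class = "stratification_table")
}

#' @export
print.stratification_table <- function(x, ...) {
  cat(sprintf("n = %d; moved up %d (%.0f%%), moved down %d (%.0f%%), total reclassified %d (%.0f%%)\n",
              x$n, x$moved_up, x$moved_up_pct, x$moved_down, x$moved_down_pct,
              x$reclassified, x$reclassified_pct))
  print(x$overall)
  invisible(x)
}

#' Classify subjects by 5-year outcome status
#'
#' Deaths within the horizon are events; subjects followed alive to the
#' horizon (or beyond) are non-events; subjects censored alive before the
#' horizon are `censored` and are excluded from NRI/IDI.
#'
#' @param times follow-up times (years).
#' @param events 0/1 death indicators.
#' @param horizon horizon in years (default 5).
#' @return character vector in `{"event", "nonevent", "censored"}`.
#' @export
five_year_status <- function(times, events, horizon = 5) {
  ifelse(events == 1 & times <= horizon, "event",
         ifelse(times >= horizon, "nonevent", "censored"))
}

# internal: shared up/down tally for the NRIs
nri_moves <- function(base_cats, new_cats, status, stratum) {
  sel <- status == stratum
  if (!any(sel)) stop("no subjects with status '", stratum, "'", call. = FALSE)
  list(up = mean(new_cats[sel] > base_cats[sel]),
       down = mean(new_cats[sel] < base_cats[sel]))
}

#' Event net reclassification index
#'
#' Among events, 100 x (proportion moved to a higher risk category minus
#' proportion moved lower) under the new model.
#'
#' @param base_cats,new_cats category indices from [assign_risk_category()].
#' @param status statuses from [five_year_status()] (or a 0/1 event vector).
#' @return percentage in \[-100, 100\].
#' @export
event_nri <- function(base_cats, new_cats, status) {
  if (is.numeric(status)) status <- ifelse(status == 1, "event", "nonevent")
  m <- nri_moves(base_cats, new_cats, status, "event")
  100 * (m$up - m$down)
}

#' Non-event net reclassification index
#'
#' Among non-events, 100 x (proportion moved lower minus proportion moved
#' higher).
#'
#' @inheritParams event_nri
#' @return percentage in \[-100, 100\].
#' @export
nonevent_nri <- function(base_cats, new_cats, status) {
  if (is.numeric(status)) status <- ifelse(status == 1, "event", "nonevent")
  m <- nri_moves(base_cats, new_cats, status, "nonevent")
  100 * (m$down - m$up)
}

#' Integrated discrimination improvement
#'
#' Difference between models in discrimination slope (mean predicted risk in
#' events minus mean predicted risk in non-events), x 100.
#'
#' @param base_risks,new_risks predicted probabilities.
#' @param status see [event_nri()].
#' @return percentage in \[-100, 100\].
#' @export
idi <- function(base_risks, new_risks, status) {
  if (is.numeric(status)) status <- ifelse(status == 1, "event", "nonevent")
  ev <- status == "event"; ne <- status == "nonevent"
  if (!any(ev) || !any(ne))
    stop("need at least one event and one non-event", call. = FALSE)
  slope <- function(r) mean(r[ev]) - mean(r[ne])
  100 * (slope(new_risks) - slope(base_risks))
}

#' Reclassification calibration statistic
#'
#' Hosmer-Lemeshow-type goodness of fit over the cells of the risk table:
#' `sum_k (O_k - n_k p_k)^2 / (n_k p_k (1 - p_k))` where `O_k` is the
#' observed number of deaths by the horizon in cell k (Kaplan-Meier
#' complement at the horizon times `n_k` when censoring is present) and `p_k`
#' the cell's mean predicted risk. Cells with fewer than `min_cell` subjects
#' are merged into the cell nearest in mean predicted risk; the reference
#' distribution is chi-square with (number of included cells - 2) degrees of
#' freedom. A small p-value indicates poor calibration.
#'
#' @param risks predicted probabilities from the model being assessed.
#' @param times,events follow-up data.
#' @param cats a [risk_categories()] object (used when `cells` is NULL).
#' @param horizon horizon in years.
#' @param cells optional cell membership (e.g. the interaction of base and
#'   new categories for the cross-classified version); defaults to the risk
#'   category of `risks`.
#' @param min_cell minimum cell size before merging (default 5).
#' @return list with `statistic`, `df`, `p_value`, and the per-cell table.
#' @export
reclassification_calibration <- function(risks, times, events,
                                         cats = risk_categories(), horizon = 5,
                                         cells = NULL, min_cell = 5) {
  if (is.null(cells)) cells <- assign_risk_category(risks, cats)
  cells <- as.character(cells)
  km_deaths <- function(sel) {
    # observed deaths by horizon: n * (1 - KM survival at horizon)
    if (all(events[sel] == 0)) return(0)
    sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    s_h <- c(1, sf$surv)[findInterval(horizon, c(0, sf$time))]
    sum(sel) * (1 - s_h)
  }
  ids <- split(seq_along(risks), cells)
  cell_tab <- data.frame(
    cell = names(ids),
    n = vapply(ids, length, 0L),
    observed = vapply(ids, function(i) {
      sel <- rep(FALSE, length(risks)); sel[i] <- TRUE; km_deaths(sel)
    }, 0),
    mean_risk = vapply(ids, function(i) mean(risks[i]), 0),
    row.names = NULL)
  # merge small cells into nearest neighbour by mean predicted risk
  while (nrow(cell_tab) > 1 && any(cell_tab$n < min_cell)) {
    k <- which.min(cell_tab$n)
    d <- abs(cell_tab$mean_risk - cell_tab$mean_risk[k]); d[k] <- Inf
    j <- which.min(d)
    w <- cell_tab$n[c(j, k)]
    cell_tab$mean_risk[j] <- sum(w * cell_tab$mean_risk[c(j, k)]) / sum(w)
    cell_tab$n[j] <- sum(w)
    cell_tab$observed[j] <- cell_tab$observed[j] + cell_tab$observed[k]
    cell_tab$cell[j] <- paste(cell_tab$cell[j], cell_tab$cell[k], sep = "+")
    cell_tab <- cell_tab[-k, , drop = FALSE]
  }
  if (nrow(cell_tab) < 3) stop("fewer than 3 cells after merging", call. = FALSE)
  expected <- cell_tab$n * cell_tab$mean_risk
  vr <- cell_tab$n * cell_tab$mean_risk * (1 - cell_tab$mean_risk)
  statistic <- sum((cell_tab$observed - expected)^2 / vr)
  df <- nrow(cell_tab) - 2
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       cells = cell_tab)
}

#' Percentile bootstrap interval for a reclassification metric
#'
#' Resamples subjects with replacement, re-runs the full metric computation
#' (including any model refitting inside `metric_fn`) on each replicate, and
#' returns the percentile 2.5/97.5 interval plus a two-sided bootstrap
#' p-value against zero. Deterministic given `seed`.
#'
#' @param metric_fn function taking a data.frame of subjects and returning a
#'   scalar metric (refitting whatever models it needs).
#' @param data data.frame of subjects (rows resampled).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `point`, `lo95`, `hi95`, `p_value`, `B`, `seed`,
#'   `n_failed`.
#' @export
bootstrap_intervals <- function(metric_fn, data, B = 1000, seed = 1) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  point <- metric_fn(data)
  set.seed(seed)
  n <- nrow(data)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(suppressWarnings(metric_fn(data[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, 0)
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.1 * B)
    stop(sprintf("metric undefined in %d of %d bootstrap replicates", n_failed, B),
         call. = FALSE)
  ok <- vals[!is.na(vals)]
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  p <- 2 * min(mean(ok <= 0), mean(ok >= 0))
  list(point = point, lo95 = ci[1], hi95 = ci[2], p_value = min(1, p),
       B = B, seed = seed, n_failed = n_failed)
}
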