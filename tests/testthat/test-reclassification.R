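test_that("risk categories use the half-open 20/30/40 convention", {
  cats <- risk_categories()
  expect_equal(cats$labels, c("0-20%", "20%-30%", "30%-40%", ">40%"))
  idx <- assign_risk_category(c(0.10, 0.45, 0.20, 0.2999, 0.40), cats)
  expect_equal(as.integer(idx), c(1L, 4L, 2L, 2L, 4L))
  expect_error(assign_risk_category(1.2, cats), "\\[0, 1\\]")
  expect_error(risk_categories(c(0.3, 0.2)), "increasing")
})

test_that("stratification table counts movement between categories", {
  cats <- risk_categories()
  base <- c(0.1, 0.1, 0.25, 0.25, 0.35, 0.35, 0.5, 0.5, 0.1, 0.25)
  new <- base
  ev <- rep(c(1, 0), 5)
  st0 <- stratification_table(base, new, ev, cats)
  expect_equal(st0$reclassified, 0)
  expect_equal(sum(st0$overall) , 10)
  expect_true(all(st0$overall[row(st0$overall) != col(st0$overall)] == 0))
  # 3 move up, 1 moves down
  new2 <- base; new2[c(1, 3, 5)] <- c(0.22, 0.32, 0.45); new2[7] <- 0.1
  st <- stratification_table(base, new2, ev, cats)
  expect_equal(st$moved_up, 3); expect_equal(st$moved_down, 1)
  expect_equal(st$reclassified, 4)
  expect_equal(st$moved_up_pct, 30); expect_equal(st$moved_down_pct, 10)
  expect_equal(st$reclassified_pct, 40)
  # order invariance
  perm <- sample(10)
  stp <- stratification_table(base[perm], new2[perm], ev[perm], cats)
  expect_equal(stp$overall, st$overall)
  expect_equal(sum(st$events) + sum(st$nonevents), 10)
})

test_that("event and non-event NRI follow their defining formulas", {
  cats <- risk_categories()
  # 10 events: 3 up, 1 down
  b <- rep(2L, 10); n <- b; n[1:3] <- 3L; n[4] <- 1L
  status <- rep("event", 10)
  expect_equal(event_nri(b, n, status), 20)
  expect_equal(event_nri(b, b, status), 0)
  expect_equal(event_nri(rep(1L, 4), rep(4L, 4), rep("event", 4)), 100)
  # 100 non-events: 50 down, 10 up
  b2 <- rep(2L, 100); n2 <- b2; n2[1:50] <- 1L; n2[51:60] <- 3L
  expect_equal(nonevent_nri(b2, n2, rep("nonevent", 100)), 40)
  expect_equal(nonevent_nri(rep(3L, 5), rep(1L, 5), rep("nonevent", 5)), 100)
  expect_error(event_nri(b, n, rep("nonevent", 10)), "no subjects")
  # exhaustive enumeration oracle on all movement patterns of an n = 12 toy
  set.seed(4)
  for (i in 1:25) {
    bc <- sample(1:4, 12, replace = TRUE)
    nc <- sample(1:4, 12, replace = TRUE)
    st <- sample(c("event", "nonevent"), 12, replace = TRUE)
    if (!any(st == "event")) st[1] <- "event"
    if (!any(st == "nonevent")) st[2] <- "nonevent"
    ev_ids <- which(st == "event"); ne_ids <- which(st == "nonevent")
    oracle_e <- 100 * (sum(nc[ev_ids] > bc[ev_ids]) - sum(nc[ev_ids] < bc[ev_ids])) /
      length(ev_ids)
    oracle_n <- 100 * (sum(nc[ne_ids] < bc[ne_ids]) - sum(nc[ne_ids] > bc[ne_ids])) /
      length(ne_ids)
    expect_equal(event_nri(bc, nc, st), oracle_e)
    expect_equal(nonevent_nri(bc, nc, st), oracle_n)
  }
})

test_that("IDI equals the difference of discrimination slopes", {
  status <- c("event", "event", "nonevent", "nonevent")
  base <- c(0.5, 0.5, 0.5, 0.5)
  new <- c(0.7, 0.9, 0.3, 0.1)
  expect_equal(idi(base, new, status), 60)
  expect_equal(idi(base, base, status), 0)
  expect_equal(idi(new, base, status), -60)   # antisymmetry
  # independent two-slope oracle on random data
  set.seed(6)
  for (i in 1:10) {
    st <- sample(c("event", "nonevent"), 15, replace = TRUE)
    st[1:2] <- c("event", "nonevent")
    b <- runif(15); nn <- runif(15)
    slope <- function(r) mean(r[st == "event"]) - mean(r[st == "nonevent"])
    expect_equal(idi(b, nn, st), 100 * (slope(nn) - slope(b)), tolerance = 1e-12)
  }
  expect_error(idi(base, new, rep("event", 4)), "non-event")
})

test_that("reclassification calibration matches the hand-computed chi-square", {
  # exact agreement in every cell -> statistic 0, p = 1
  risks <- rep(c(0.20, 0.30, 0.40), each = 50)
  cells <- rep(c("a", "b", "c"), each = 50)
  times <- rep(5, 150)   # deaths at the horizon count as 5-year deaths
  events <- unlist(lapply(c(10, 15, 20), function(k) rep(c(1, 0), c(k, 50 - k))))
  out <- reclassification_calibration(risks, times, events, cells = cells)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)
  expect_equal(out$df, 1)
  # perturbed cells against a hand-written chi-square (no censoring)
  events2 <- unlist(lapply(c(13, 15, 24), function(k) rep(c(1, 0), c(k, 50 - k))))
  out2 <- reclassification_calibration(risks, times, events2, cells = cells)
  hand <- (13 - 10)^2 / (50 * .2 * .8) + 0 + (24 - 20)^2 / (50 * .4 * .6)
  expect_equal(out2$statistic, hand, tolerance = 1e-10)
  expect_equal(out2$p_value, pchisq(hand, 1, lower.tail = FALSE))
  # small cells get merged; fewer than 3 surviving cells is an error
  expect_error(reclassification_calibration(risks[1:60], times[1:60], events[1:60],
                                            cells = rep(c("a", "b"), each = 30)),
               "fewer than 3")
})

test_that("calibration uses the Kaplan-Meier complement under censoring", {
  # one cell, half censored early: KM inflates observed deaths accordingly
  times <- c(1, 1, 2, 4, 4, 4)
  events <- c(1, 0, 1, 0, 0, 0)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  km5 <- 6 * (1 - min(sf$surv))
  out <- reclassification_calibration(
    risks = rep(c(0.3, 0.4, 0.5), each = 6),
    times = rep(times, 3), events = rep(events, 3),
    cells = rep(c("a", "b", "c"), each = 6), min_cell = 2)
  expect_equal(out$cells$observed, rep(km5, 3), tolerance = 1e-10)
})

test_that("bootstrap intervals are seeded, percentile-based and guarded", {
  dat <- toy_reclass_data()
  metric <- function(d) mean(d$marker) - 0.5
  b1 <- bootstrap_intervals(metric, dat, B = 500, seed = 42)
  b2 <- bootstrap_intervals(metric, dat, B = 500, seed = 42)
  expect_identical(b1, b2)
  b3 <- bootstrap_intervals(metric, dat, B = 500, seed = 43)
  expect_false(identical(b1$lo95, b3$lo95))
  expect_lte(b1$lo95, b1$hi95)
  expect_equal(b1$point, metric(dat))
  # constant metric -> zero-width interval
  bc <- bootstrap_intervals(function(d) 7, dat, B = 50, seed = 1)
  expect_equal(bc$lo95, 7); expect_equal(bc$hi95, 7)
  # metric failing in too many replicates aborts with a report
  # fails whenever the replicate contains duplicated subjects (i.e. in
  # essentially every bootstrap resample, but not on the original data)
  flaky <- function(d) if (any(duplicated(d))) stop("boom") else 1
  expect_error(bootstrap_intervals(flaky, dat, B = 50, seed = 1), "replicates")
  expect_error(bootstrap_intervals(metric, dat, B = 1), "B must be")
})

test_that("five_year_status separates events, non-events and early censoring", {
  st <- five_year_status(c(2, 6, 5, 3), c(1, 0, 0, 0))
  expect_equal(st, c("event", "nonevent", "nonevent", "censored"))
  expect_equal(five_year_status(6, 1), "nonevent")  # death after horizon
})
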