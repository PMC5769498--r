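test_that("cohort CSV round-trip preserves the table and validates input", {
  df <- toy_cohort_df()
  coh <- cohort_table(df)
  expect_s3_class(coh, "cohort_table")
  expect_equal(nrow(coh), 3)
  expect_equal(coh$stage, c("local", "regional", "distant"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)

  # missing required column named in the error
  bad <- df[, setdiff(names(df), "followup_time_years")]
  expect_error(cohort_table(bad), "followup_time_years")
  # bad values named with row
  df2 <- df; df2$stage[2] <- "stage9"
  expect_error(cohort_table(df2), "stage")
  df3 <- df; df3$followup_time_years[3] <- -1
  expect_error(cohort_table(df3), "row 3")
  df4 <- df; df4$marker_score[1] <- 3.5
  expect_error(cohort_table(df4), "marker_score")
})

test_that("marker scores are filled from a cores file", {
  df <- toy_cohort_df(); df$marker_score[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  cores_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(subject_id = c("b", "b"),
                       core_intensity = c(1.0, 2.0),
                       core_area = c(1, 3)),
            cores_path, row.names = FALSE)
  coh <- read_cohort(path, cores_path)
  expect_equal(coh$marker_score[2], 1.75)
  # neither score nor cores -> refusal, not imputation
  write.csv(data.frame(subject_id = "zzz", core_intensity = 1, core_area = 1),
            cores_path, row.names = FALSE)
  expect_error(read_cohort(path, cores_path), "marker_score")
})

test_that("summarize_cores is the area-weighted average", {
  expect_equal(summarize_cores(c(2, 2, 2), c(1, 5, 9)), 2.0)
  expect_equal(summarize_cores(c(1, 2), c(1, 3)), 1.75)
  expect_equal(summarize_cores(c(0, 3), c(2, 2)), 1.5)
  expect_error(summarize_cores(numeric(0), numeric(0)), "empty")
  expect_error(summarize_cores(c(1, 2), c(1, 2, 3)), "length")
  expect_error(summarize_cores(c(1, 2), c(1, 0)), "positive")
  # invariance to rescaling all areas, and range containment
  set.seed(1)
  for (i in 1:20) {
    x <- runif(4, 0, 3); a <- runif(4, 0.1, 10)
    m <- summarize_cores(x, a)
    expect_equal(m, summarize_cores(x, a * 7.3), tolerance = 1e-12)
    expect_gte(m, min(x)); expect_lte(m, max(x))
  }
})

test_that("marker dichotomization follows the stated boundary convention", {
  # epithelial: below the cut point is EMT-positive, at/above is negative
  expect_equal(dichotomize_marker(0.50, 0.52, "epithelial"), 1L)
  expect_equal(dichotomize_marker(0.52, 0.52, "epithelial"), 0L)
  # mesenchymal/inducer: high expression is EMT-positive
  expect_equal(dichotomize_marker(2.5, 0.85, "mesenchymal_or_inducer"), 1L)
  expect_error(dichotomize_marker(1, 3.2, "epithelial"), "cut_point")
  # monotonicity of positives in the cut point
  set.seed(2)
  scores <- runif(200, 0, 3)
  cuts <- sort(runif(10, 0.1, 3))
  pos_epi <- vapply(cuts, function(cp) sum(dichotomize_marker(scores, cp, "epithelial")), 0L)
  pos_mes <- vapply(cuts, function(cp) sum(dichotomize_marker(scores, cp, "mesenchymal_or_inducer")), 0L)
  expect_true(all(diff(pos_epi) >= 0))
  expect_true(all(diff(pos_mes) <= 0))
})

test_that("stage-based imputation reproduces the assignment rules and printed margins", {
  expect_equal(unlist(impute_tests_from_stage("local", "not_applicable")),
               c(ln_test = 0L, ri_test = 0L))
  expect_equal(unlist(impute_tests_from_stage("regional")),
               c(ln_test = 1L, ri_test = 0L))
  expect_equal(unlist(impute_tests_from_stage("distant", "N0")),
               c(ln_test = 0L, ri_test = 1L))
  expect_equal(unlist(impute_tests_from_stage("distant", "N1orN2")),
               c(ln_test = 1L, ri_test = 1L))
  expect_equal(unlist(impute_tests_from_stage("distant", "unknown")),
               c(ln_test = 1L, ri_test = 1L))
  expect_error(impute_tests_from_stage("distant", NA), "N-stage")

  dist <- printed_stage_distribution()
  imp <- impute_tests_from_stage(dist$stage, dist$n_stage)
  expect_equal(sum(imp$ln_test), 86)
  expect_equal(sum(imp$ln_test == 0), 102)
  expect_equal(sum(imp$ri_test), 23)
  expect_equal(sum(imp$ri_test == 0), 165)
})

test_that("pattern counts cover the cohort and respect observed tests", {
  coh <- generate_cohort(cancors_like_preset(), seed = 7)
  for (cp in c(0.52, 0.85, 2.0)) {
    cnt <- pattern_counts(coh, cp)
    expect_equal(nrow(cnt), 8)
    expect_equal(sum(cnt$count), nrow(coh))
  }
  # empty cohort -> all zero cells
  empty <- cohort_table(toy_cohort_df()[0, ])
  expect_equal(sum(pattern_counts(empty, 0.85)$count), 0)
  # all tests negative concentrates in (0,0,0)
  df <- toy_cohort_df()
  df$stage <- "local"; df$marker_score <- 2.9
  cnt <- pattern_counts(cohort_table(df), 0.85)
  expect_equal(cnt$count[cnt$emt == 0 & cnt$ln == 0 & cnt$ri == 0], 3L)
  expect_equal(sum(cnt$count), 3L)
  # pattern-counts CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(cnt), path, row.names = FALSE)
  expect_equal(read_pattern_counts(path)$count, cnt$count)
})
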