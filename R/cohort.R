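STAGES <- c("local", "regional", "distant")
N_STAGES <- c("N0", "N1orN2", "unknown", "not_applicable")
TESTS <- c("emt", "ln", "ri")

# internal: map stage codes to local/regional/distant; I/II -> local, III ->
# regional, IV -> distant
normalize_stage <- function(stage) {
  s <- tolower(trimws(as.character(stage)))
  map <- c(i = "local", ii = "local", iii = "regional", iv = "distant",
           local = "local", regional = "regional", distant = "distant")
  out <- unname(map[s])
  bad <- which(is.na(out) & !is.na(s))
  if (length(bad))
    fail_field("stage", bad[1], sprintf("unparseable stage code '%s'", s[bad[1]]))
  out
}

normalize_n_stage <- function(n_stage) {
  s <- trimws(as.character(n_stage))
  s[is.na(s) | s == ""] <- NA
  ok <- is.na(s) | s %in% N_STAGES
  if (!all(ok))
    fail_field("n_stage", which(!ok)[1],
               sprintf("unknown code '%s'", s[which(!ok)[1]]))
  s
}

#' Construct a validated cohort table
#'
#' One row per subject. Required columns: `subject_id`, `stage`
#' (I/II/III/IV or local/regional/distant), `n_stage`
#' (N0/N1orN2/unknown/not_applicable; may be NA except for distant disease),
#' `marker_score` (continuous, 0-3 intensity scale), `followup_time_years`
#' (>= 0) and `death` (0/1). Optional columns `ln_test`, `ri_test` (1 =
#' positive, i.e. evidence supporting detachment; 0 = negative) override
#' stage-based imputation.
#'
#' @param df data.frame of subject rows.
#' @param marker_direction `"epithelial"` (expression falls during EMT; low
#'   score is test-positive) or `"mesenchymal_or_inducer"` (expression rises;
#'   high score is test-positive).
#' @return a `cohort_table`: the validated data.frame with the direction
#'   stored as an attribute.
#' @export
cohort_table <- function(df, marker_direction = c("epithelial", "mesenchymal_or_inducer")) {
  marker_direction <- match.arg(marker_direction)
  required <- c("subject_id", "stage", "n_stage", "marker_score",
                "followup_time_years", "death")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    fail_field("subject_id", msg = "subject ids must be unique")
  df$stage <- normalize_stage(df$stage)
  df$n_stage <- normalize_n_stage(df$n_stage)
  ms <- suppressWarnings(as.numeric(df$marker_score))
  bad <- which(!is.na(ms) & (ms < 0 | ms > 3))
  if (length(bad)) fail_field("marker_score", bad[1], "outside the 0-3 scale")
  if (anyNA(ms)) fail_field("marker_score", which(is.na(ms))[1],
                            "missing (supply cores or a score)")
  df$marker_score <- ms
  tt <- suppressWarnings(as.numeric(df$followup_time_years))
  bad <- which(is.na(tt) | tt < 0)
  if (length(bad)) fail_field("followup_time_years", bad[1],
                              "must be a nonnegative number")
  df$followup_time_years <- tt
  if (!all(df$death %in% c(0, 1)))
    fail_field("death", which(!df$death %in% c(0, 1))[1], "must be 0 or 1")
  for (tcol in c("ln_test", "ri_test")) {
    if (tcol %in% names(df)) {
      ok <- is.na(df[[tcol]]) | df[[tcol]] %in% c(0, 1)
      if (!all(ok)) fail_field(tcol, which(!ok)[1], "must be 0/1 or NA")
    }
  }
  structure(df, class = c("cohort_table", "data.frame"),
            marker_direction = marker_direction)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects, marker direction '%s'\n",
              nrow(x), attr(x, "marker_direction")))
  NextMethod()
}

#' Read a cohort from CSV
#'
#' Reads the subject-level cohort CSV (and, optionally, a long-format per-core
#' CSV with columns `subject_id`, `core_intensity`, `core_area`). Missing
#' `marker_score` values are filled from the cores by area-weighted averaging;
#' a subject with neither a score nor cores is a validation error.
#'
#' @param path cohort CSV path.
#' @param cores_path optional per-core CSV path.
#' @param marker_direction see [cohort_table()].
#' @return a `cohort_table`, row order preserved.
#' @export
read_cohort <- function(path, cores_path = NULL,
                        marker_direction = c("epithelial", "mesenchymal_or_inducer")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"marker_score" %in% names(df)) df$marker_score <- NA_real_
  if (!is.null(cores_path)) {
    cores <- utils::read.csv(cores_path, stringsAsFactors = FALSE)
    need <- c("subject_id", "core_intensity", "core_area")
    if (length(setdiff(need, names(cores))))
      stop("cores file missing column(s): ",
           paste(setdiff(need, names(cores)), collapse = ", "), call. = FALSE)
    fill <- which(is.na(df$marker_score))
    for (i in fill) {
      sub <- cores[cores$subject_id == df$subject_id[i], , drop = FALSE]
      if (nrow(sub))
        df$marker_score[i] <- summarize_cores(sub$core_intensity, sub$core_area)
    }
  }
  cohort_table(df, marker_direction)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' the table.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Area-weighted average of per-core marker intensities
#'
#' Core average intensities (0-3 scale) are combined into one subject-level
#' score as a weighted average, weighted by the core area analyzed.
#'
#' @param core_intensities intensities in \[0, 3\].
#' @param core_areas positive analyzed areas, same length.
#' @return the weighted mean, guaranteed within the range of the inputs.
#' @export
summarize_cores <- function(core_intensities, core_areas) {
  if (!length(core_intensities)) stop("empty core list", call. = FALSE)
  if (length(core_intensities) != length(core_areas))
    stop("core intensity and area lists differ in length", call. = FALSE)
  if (any(!is.finite(core_areas)) || any(core_areas <= 0))
    stop("core areas must be positive", call. = FALSE)
  if (any(core_intensities < 0 | core_intensities > 3))
    stop("core intensities must lie in [0, 3]", call. = FALSE)
  sum(core_intensities * core_areas) / sum(core_areas)
}

#' Dichotomize a continuous marker score into an EMT test result
#'
#' For an epithelial marker (expression lost during EMT), expression below
#' the cut point is EMT-positive; expression at or above the cut point is
#' high, hence EMT-negative. For a mesenchymal marker or EMT inducer the
#' coding is reversed: at-or-above the cut point is EMT-positive.
#'
#' @param marker_score continuous score(s) on the 0-3 scale.
#' @param cut_point cut point in (0, 3\].
#' @param direction `"epithelial"` or `"mesenchymal_or_inducer"`.
#' @return integer vector, 1 = EMT-positive, 0 = EMT-negative.
#' @export
dichotomize_marker <- function(marker_score, cut_point,
                               direction = c("epithelial", "mesenchymal_or_inducer")) {
  direction <- match.arg(direction)
  if (cut_point <= 0 || cut_point > 3)
    stop("cut_point must lie in (0, 3]", call. = FALSE)
  if (direction == "epithelial") as.integer(marker_score < cut_point)
  else as.integer(marker_score >= cut_point)
}

#' Impute lymph node and imaging test results from TNM stage
#'
#' Local disease (stage I/II) is lymph node-negative and imaging-negative;
#' regional (III) is node-positive, imaging-negative; distant (IV) is
#' imaging-positive with node status from N-stage (N0 negative, N1/N2 or
#' unknown positive).
#'
#' @param stage stage codes (vectorized; see [cohort_table()]).
#' @param n_stage N-stage codes; required (possibly `"unknown"`) when stage is
#'   distant. An absent (`NA`) N-stage for distant disease is an error,
#'   distinct from the value `"unknown"`.
#' @return data.frame with integer columns `ln_test`, `ri_test` (1 = positive).
#' @export
impute_tests_from_stage <- function(stage, n_stage = NULL) {
  stage <- normalize_stage(stage)
  n <- length(stage)
  if (is.null(n_stage)) n_stage <- rep(NA_character_, n)
  n_stage <- normalize_n_stage(n_stage)
  ln <- integer(n); ri <- integer(n)
  ln[stage == "regional"] <- 1L
  ri[stage == "distant"] <- 1L
  dist <- which(stage == "distant")
  if (length(dist)) {
    missing_n <- dist[is.na(n_stage[dist]) | n_stage[dist] == "not_applicable"]
    if (length(missing_n))
      fail_field("n_stage", missing_n[1],
                 "N-stage required for distant disease (use 'unknown' if unknown)")
    ln[dist] <- ifelse(n_stage[dist] == "N0", 0L, 1L)
  }
  data.frame(ln_test = ln, ri_test = ri)
}

# internal: resolve ln/ri for every subject (observed value wins, else impute)
resolve_tests <- function(cohort) {
  imp <- impute_tests_from_stage(cohort$stage, cohort$n_stage)
  ln <- if ("ln_test" %in% names(cohort))
    ifelse(is.na(cohort$ln_test), imp$ln_test, cohort$ln_test) else imp$ln_test
  ri <- if ("ri_test" %in% names(cohort))
    ifelse(is.na(cohort$ri_test), imp$ri_test, cohort$ri_test) else imp$ri_test
  data.frame(ln_test = as.integer(ln), ri_test = as.integer(ri))
}

# the 8 test-result patterns in canonical order (emt, ln, ri)
pattern_grid <- function() {
  g <- expand.grid(emt = 0:1, ln = 0:1, ri = 0:1)
  g[order(g$emt, g$ln, g$ri, decreasing = TRUE), ][8:1, ]  # 000 ... 111
}

#' Cross-classify a cohort into the 8 test-result patterns
#'
#' Applies the marker dichotomization at `cut_point` and resolves lymph node /
#' imaging results (observed if present, otherwise imputed from stage), then
#' counts subjects in each (emt, ln, ri) cell.
#'
#' @param cohort a `cohort_table`.
#' @param cut_point marker cut point.
#' @param direction marker direction; defaults to the cohort's attribute.
#' @return a `pattern_counts` object: data.frame with columns `emt`, `ln`,
#'   `ri`, `count` (8 rows, counts summing to the cohort size).
#' @export
pattern_counts <- function(cohort, cut_point, direction = NULL) {
  if (is.null(direction)) direction <- attr(cohort, "marker_direction")
  grid <- pattern_grid()
  if (nrow(cohort) == 0L) {
    grid$count <- 0L
  } else {
    emt <- dichotomize_marker(cohort$marker_score, cut_point, direction)
    tests <- resolve_tests(cohort)
    key <- paste(emt, tests$ln_test, tests$ri_test)
    tab <- table(factor(key, levels = paste(grid$emt, grid$ln, grid$ri)))
    grid$count <- as.integer(tab)
  }
  stopifnot(sum(grid$count) == nrow(cohort))
  structure(grid, class = c("pattern_counts", "data.frame"))
}

#' Read pattern counts from CSV
#'
#' CSV columns: `emt`, `ln`, `ri` (0/1) and `count`.
#'
#' @param path CSV path.
#' @return a `pattern_counts` object.
#' @export
read_pattern_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("emt", "ln", "ri", "count")
  if (length(setdiff(need, names(df))))
    stop("pattern counts file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  grid <- pattern_grid()
  key <- paste(df$emt, df$ln, df$ri)
  m <- match(paste(grid$emt, grid$ln, grid$ri), key)
  grid$count <- ifelse(is.na(m), 0L, as.integer(df$count[m]))
  if (any(grid$count < 0)) stop("negative pattern count", call. = FALSE)
  structure(grid, class = c("pattern_counts", "data.frame"))
}
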