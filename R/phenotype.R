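#' Mean pressure pain threshold over the 8 assessment sites
#'
#' PPTs are assessed bilaterally at 4 anatomical sites (supraspinatus,
#' lateral epicondyle, gluteus, knee medial fat pad); the subject-level
#' score is the arithmetic mean of all 8 readings. Missing readings are an
#' error (no silent imputation).
#'
#' @param sites Numeric vector of exactly 8 positive pressures (kPa). May
#'   be named; names of missing entries are reported.
#' @return Mean PPT in kPa.
#' @export
mean_ppt <- function(sites) {
  if (!is.numeric(sites) || length(sites) != 8L)
    stopf("`sites` must contain exactly 8 PPT readings (got %d)", length(sites))
  if (anyNA(sites)) {
    miss <- which(is.na(sites))
    lab <- if (!is.null(names(sites))) names(sites)[miss] else paste0("site ", miss)
    stopf("missing PPT readings: %s", paste(lab, collapse = ", "))
  }
  if (any(sites <= 0)) stopf("PPT readings must be positive pressures (kPa)")
  mean(sites)
}

#' Conditioned pain modulation score
#'
#' `(end PPT - baseline PPT) / baseline PPT`: the relative change of the
#' pressure pain threshold at the test site while the conditioning
#' (tourniquet) stimulus is applied. Positive scores represent pain
#' inhibition, negative scores pain facilitation. The score is unitless
#' and invariant to rescaling both pressures.
#'
#' @param baseline Baseline PPT (kPa), must be > 0.
#' @param end End PPT (kPa) under conditioning.
#' @return CPM score (unitless).
#' @export
cpm_score <- function(baseline, end) {
  if (!is.numeric(baseline) || !is.numeric(end) || length(baseline) != length(end))
    stopf("`baseline` and `end` must be numeric vectors of equal length")
  if (anyNA(baseline) || anyNA(end)) stopf("CPM inputs contain missing values")
  if (any(baseline <= 0)) stopf("baseline PPT must be > 0")
  (end - baseline) / baseline
}

#' Validate a subject phenotype table
#'
#' Checks scale bounds (VAS and FIQ in \[0, 100\], positive pressures),
#' recomputes `ppt_mean` and `cpm_score` from their raw inputs when the
#' site/pressure columns are present, and returns the table with those
#' derived columns filled in. Violations raise errors naming the subject
#' and column; explicit `NA`s are propagated, not imputed.
#'
#' @param df Data frame with (a subset of) the phenotype columns:
#'   `subject_id`, `group`, `vas_avg`, `vas_max`, `vas_min`,
#'   `vas_current`, `fiq`, `bdi`, `ppt_s1`..`ppt_s8`, `cpm_baseline`,
#'   `cpm_end`, `age`, `bmi`, `fm_duration`, `pain_duration`.
#' @return The validated data frame with `ppt_mean` and `cpm_score`
#'   derived where possible.
#' @export
validate_phenotypes <- function(df) {
  stopifnot(is.data.frame(df), "subject_id" %in% names(df))
  for (col in intersect(c("vas_avg", "vas_max", "vas_min", "vas_current", "fiq"), names(df))) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
    if (length(bad))
      stopf("`%s` outside [0, 100] for subject(s): %s", col,
            paste(df$subject_id[bad], collapse = ", "))
  }
  for (col in intersect(c("bdi", "age", "bmi"), names(df))) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stopf("`%s` negative for subject(s): %s", col, paste(df$subject_id[bad], collapse = ", "))
  }
  site_cols <- paste0("ppt_s", 1:8)
  if (all(site_cols %in% names(df))) {
    df$ppt_mean <- vapply(seq_len(nrow(df)), function(i) {
      s <- as.numeric(df[i, site_cols])
      if (anyNA(s)) NA_real_ else mean_ppt(s)
    }, numeric(1))
  }
  if (all(c("cpm_baseline", "cpm_end") %in% names(df))) {
    ok <- !is.na(df$cpm_baseline) & !is.na(df$cpm_end)
    df$cpm_score <- NA_real_
    if (any(ok)) df$cpm_score[ok] <- cpm_score(df$cpm_baseline[ok], df$cpm_end[ok])
  }
  df
}

#' Read and validate a phenotype CSV
#' @param path CSV with one row per subject.
#' @return Validated phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  validate_phenotypes(utils::read.csv(path, stringsAsFactors = FALSE))
}
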