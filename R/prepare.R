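# Cohort preparation: per-protocol mean BP, BMI SDS, weight classification,
# and exclusion filtering.

#' Mean blood pressure from up to three readings
#'
#' Protocol: with three readings, the mean of the last two (the first reading
#' is discarded as an accommodation reading); with two, their mean; with one,
#' the reading itself.  Readings are taken in measurement order and never
#' re-ordered by value.  No rounding is applied.
#'
#' @param readings numeric vector of 1-3 readings (mmHg) in measurement
#'   order; trailing NAs (readings not taken) are dropped.
#' @return mean BP in mmHg.
#' @export
mean_bp <- function(readings) {
  r <- as.numeric(readings)
  r <- r[!is.na(r)]
  if (length(r) == 0)
    bp_stop("bp_data_error", "mean_bp(): no readings available")
  if (length(r) > 3)
    bp_stop("bp_data_error", "mean_bp(): more than 3 readings supplied")
  if (length(r) == 3) mean(r[2:3]) else mean(r)
}

# Vectorised over the cohort's reading columns; rows with no readings give NA
# (missing BP is an exclusion state, not an error, at cohort level).
mean_bp_rows <- function(m) {
  apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_real_)
    if (length(r) == 3) mean(r[2:3]) else mean(r)
  })
}

#' IOTF-style overweight cut-off in z units
#'
#' The z-score of the centile passing through a BMI of `bmi_at` kg/m^2 at age
#' `age` (default 25 at 18) in the supplied BMI reference.  The cut-off is
#' derived from the reference rather than hard-coded, because the published
#' IOTF coefficient tables are external data.
#'
#' @param bmi_ref BMI [growth_reference()] covering `age`.
#' @param sex "female" or "male".
#' @param bmi_at cut-off BMI (kg/m^2) at the anchoring age.
#' @param age anchoring age in years.
#' @return the cut-off as a z-score.
#' @export
iotf_cutoff <- function(bmi_ref, sex, bmi_at = 25, age = 18) {
  p <- lms_at(bmi_ref, sex, age)
  lms_zscore(bmi_at, p$L, p$M, p$S)
}

#' Classify weight status
#'
#' Weight present: overweight iff the BMI SDS is at or above the supplied
#' cut-off.  Weight missing but waist present: overweight iff
#' waist-to-height ratio >= 0.5 (boundary inclusive).  Both missing:
#' unclassifiable.  Missingness is a state, not an error.
#'
#' @param bmi_sds BMI standard deviation score (NA when weight missing).
#' @param whtr waist-to-height ratio (NA when waist missing).
#' @param sds_cutoff overweight cut-off in z units (per child; recycled).
#' @param whtr_cutoff waist-to-height cut-off (default 0.5).
#' @return factor with levels normal, overweight, unclassifiable.
#' @export
classify_weight <- function(bmi_sds, whtr, sds_cutoff, whtr_cutoff = 0.5) {
  k <- max(length(bmi_sds), length(whtr))
  bmi_sds <- rep_len(bmi_sds, k)
  whtr <- rep_len(whtr, k)
  sds_cutoff <- rep_len(sds_cutoff, k)
  cls <- ifelse(!is.na(bmi_sds),
                ifelse(bmi_sds >= sds_cutoff, "overweight", "normal"),
                ifelse(!is.na(whtr),
                       ifelse(whtr >= whtr_cutoff, "overweight", "normal"),
                       "unclassifiable"))
  factor(cls, levels = c("normal", "overweight", "unclassifiable"))
}

#' Exclusion criteria recognised by [apply_exclusions()]
#'
#' Fixed precedence order: data availability first (no BP, unclassifiable
#' weight), then medication, diagnosis, and non-Danish origin.
#'
#' @return character vector of criterion names in precedence order.
#' @export
exclusion_criteria <- function() {
  c("no_bp", "unclassifiable_weight", "medication", "diagnosis",
    "non_danish_origin")
}

#' Apply exclusion criteria to a prepared cohort
#'
#' Each excluded record carries exactly one `exclusion_reason` (the first
#' matching criterion in the fixed precedence order of
#' [exclusion_criteria()]); included records have `included = TRUE`.  The
#' per-reason counts are attached as attribute `exclusion_log`.
#'
#' @param prepared a prepared cohort data frame (see [prepare_cohort()]).
#' @param criteria subset of [exclusion_criteria()] to apply.
#' @return `prepared` with columns `included` and `exclusion_reason` set.
#' @export
apply_exclusions <- function(prepared, criteria = exclusion_criteria()) {
  unknown <- setdiff(criteria, exclusion_criteria())
  if (length(unknown))
    bp_stop("bp_config_error", "unknown exclusion criterion: %s",
            paste(unknown, collapse = ", "))
  n <- nrow(prepared)
  reason <- rep(NA_character_, n)
  hit <- function(criterion) {
    switch(criterion,
      no_bp = is.na(prepared$mean_sbp) | is.na(prepared$mean_dbp),
      unclassifiable_weight = prepared$weight_class == "unclassifiable",
      medication = prepared$excl_medication %in% TRUE,
      diagnosis = prepared$excl_diagnosis %in% TRUE,
      non_danish_origin = !(prepared$origin_danish %in% TRUE)
    )
  }
  # precedence: table order, regardless of the order `criteria` was given in
  for (criterion in intersect(exclusion_criteria(), criteria)) {
    h <- hit(criterion)
    reason[is.na(reason) & h] <- criterion
  }
  prepared$included <- is.na(reason)
  prepared$exclusion_reason <- reason
  counts <- as.list(table(factor(reason, levels = exclusion_criteria())))
  log <- list(n_input = n, n_included = sum(prepared$included),
              n_excluded = sum(!prepared$included),
              criteria = intersect(exclusion_criteria(), criteria),
              counts = counts)
  attr(prepared, "exclusion_log") <- log
  prepared
}

#' Prepare a raw cohort for analysis
#'
#' Derives mean systolic/diastolic BP per protocol, BMI and BMI SDS (when a
#' BMI reference is supplied and weight is present), waist-to-height ratio,
#' weight classification, and applies the exclusion criteria.
#'
#' @param cohort a `bp_cohort` data frame (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param bmi_ref BMI [growth_reference()] used for BMI SDS, or NULL to skip
#'   SDS computation (weight classification then falls back to WHtR).
#' @param criteria exclusion criteria to apply; see [exclusion_criteria()].
#' @param sds_cutoff optional override of the overweight z cut-off; by
#'   default derived per sex from `bmi_ref` via [iotf_cutoff()].
#' @return a `bp_prepared` data frame with derived columns and an
#'   `exclusion_log` attribute (which also records the cut-offs used).
#' @export
prepare_cohort <- function(cohort, bmi_ref = NULL,
                           criteria = exclusion_criteria(),
                           sds_cutoff = NULL) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  df$mean_sbp <- if (n) mean_bp_rows(as.matrix(df[c("sbp1", "sbp2", "sbp3")])) else numeric(0)
  df$mean_dbp <- if (n) mean_bp_rows(as.matrix(df[c("dbp1", "dbp2", "dbp3")])) else numeric(0)
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df$whtr <- df$waist_cm / df$height_cm

  cutoffs <- NULL
  df$bmi_sds <- NA_real_
  if (!is.null(bmi_ref) && n) {
    ok <- !is.na(df$bmi)
    if (any(ok)) {
      p <- lms_at(bmi_ref, df$sex[ok], df$age_years[ok])
      df$bmi_sds[ok] <- lms_zscore(df$bmi[ok], p$L, p$M, p$S)
    }
    cutoffs <- c(female = iotf_cutoff(bmi_ref, "female"),
                 male = iotf_cutoff(bmi_ref, "male"))
  }
  cut_vec <- if (!is.null(sds_cutoff)) {
    rep_len(sds_cutoff, n)
  } else if (!is.null(cutoffs)) {
    unname(cutoffs[ifelse(df$sex == "female", "female", "male")])
  } else {
    rep(Inf, n)  # no BMI reference: SDS unavailable, WHtR rule decides
  }
  df$weight_class <- classify_weight(df$bmi_sds, df$whtr, cut_vec)

  df <- apply_exclusions(df, criteria)
  log <- attr(df, "exclusion_log")
  log$sds_cutoff <- if (!is.null(sds_cutoff)) sds_cutoff else cutoffs
  log$n_normal_weight_included <-
    sum(df$included & df$weight_class == "normal", na.rm = TRUE)
  attr(df, "exclusion_log") <- log
  class(df) <- c("bp_prepared", "bp_cohort", "data.frame")
  attr(df, "seed") <- attr(cohort, "seed", exact = TRUE)
  attr(df, "config_hash") <- attr(cohort, "config_hash", exact = TRUE)
  df
}
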