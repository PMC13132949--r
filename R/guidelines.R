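# Guideline classification rules.
#
# Below a guideline's fixed-threshold age, hypertension-range BP is defined by
# percentile (systolic and/or diastolic BP at or above the percentile cut-off,
# 95th by default); from that age upward, by fixed mmHg thresholds.  The three
# international rule sets differ in the switch age and the fixed cut-offs:
# AAP switches at 13 years to 130/80, ESC at 16 to 130/85, ESH at 16 to
# 140/90 (all boundaries inclusive).

#' Build a guideline specification
#'
#' @param name label ("aap", "esc", "esh", "danish", or custom).
#' @param reference a `bp_reference` used for the percentile branch.
#' @param percentile_cutoff percentile defining positivity (default 95).
#' @param fixed_threshold_age age (years) from which fixed thresholds apply
#'   (Inf for a purely percentile-based rule).
#' @param fixed_sbp,fixed_dbp fixed thresholds in mmHg.
#' @param evaluation_age_window ages the guideline may be evaluated on;
#'   classifying a child outside it is a range error.
#' @return a `bp_guideline`.
#' @export
guideline_spec <- function(name, reference, percentile_cutoff = 95,
                           fixed_threshold_age = Inf,
                           fixed_sbp = NA_real_, fixed_dbp = NA_real_,
                           evaluation_age_window = c(1, 18)) {
  if (!inherits(reference, "bp_reference"))
    bp_stop("bp_config_error", "guideline '%s': reference must be a bp_reference", name)
  if (!is_scalar_number(percentile_cutoff) ||
      percentile_cutoff <= 0 || percentile_cutoff >= 100)
    bp_stop("bp_config_error", "percentile_cutoff must lie in (0, 100)")
  if (is.finite(fixed_threshold_age) &&
      (!is_scalar_number(fixed_sbp) || !is_scalar_number(fixed_dbp)))
    bp_stop("bp_config_error",
            "guideline '%s': fixed thresholds required when fixed_threshold_age is finite", name)
  structure(list(name = name, reference = reference,
                 percentile_cutoff = percentile_cutoff,
                 fixed_threshold_age = fixed_threshold_age,
                 fixed_sbp = fixed_sbp, fixed_dbp = fixed_dbp,
                 evaluation_age_window = evaluation_age_window),
            class = "bp_guideline")
}

#' Preset guidelines
#'
#' `"danish"` is the purely percentile-based rule over the packaged Danish
#' lookup reference.  For `"aap"`, `"esc"` and `"esh"` the percentile branch
#' needs a US-style reference; by default the packaged SYNTHETIC stand-in
#' coefficient sets are used (the published coefficients are third-party
#' appendix data) — supply `reference` to use real ones.
#'
#' @param name one of "aap", "esc", "esh", "danish".
#' @param reference optional `bp_reference` overriding the default.
#' @return a `bp_guideline`.
#' @export
guideline <- function(name = c("aap", "esc", "esh", "danish"),
                      reference = NULL) {
  name <- match.arg(name)
  if (name == "danish") {
    return(guideline_spec("danish", reference %||% danish_reference(),
                          fixed_threshold_age = Inf,
                          evaluation_age_window = c(4, 16)))
  }
  ref <- reference %||% read_reference_model(
    system.file("extdata", sprintf("synthetic_us_%s.json", name),
                package = "pedbpref"))
  switch(name,
    aap = guideline_spec("aap", ref, fixed_threshold_age = 13,
                         fixed_sbp = 130, fixed_dbp = 80),
    esc = guideline_spec("esc", ref, fixed_threshold_age = 16,
                         fixed_sbp = 130, fixed_dbp = 85),
    esh = guideline_spec("esh", ref, fixed_threshold_age = 16,
                         fixed_sbp = 140, fixed_dbp = 90)
  )
}

#' Classify children under a guideline
#'
#' Children below the guideline's fixed-threshold age are positive iff their
#' mean systolic and/or diastolic BP is at or above the reference's
#' percentile cut-off value for their age and sex; children at or above it
#' are positive iff mean SBP >= fixed_sbp or mean DBP >= fixed_dbp.  Boundary
#' equality is positive on both branches.
#'
#' @param data prepared cohort rows to classify (uses mean_sbp, mean_dbp,
#'   age_years, sex, and height for height-dependent references).
#' @param guideline a [guideline_spec()].
#' @param growth_ref height [growth_reference()], required when the
#'   guideline's reference needs a height z-score.
#' @return data frame: id, age_years, sex, status ("positive"/"negative"),
#'   basis ("percentile"/"fixed").
#' @export
classify_bp <- function(data, guideline, growth_ref = NULL) {
  stopifnot(inherits(guideline, "bp_guideline"))
  df <- as.data.frame(data)
  if (!nrow(df))
    return(data.frame(id = character(0), age_years = numeric(0),
                      sex = character(0), status = character(0),
                      basis = character(0)))
  w <- guideline$evaluation_age_window
  out_of_window <- df$age_years < w[1] | df$age_years >= w[2]
  if (any(out_of_window))
    bp_stop("bp_range_error",
            "guideline '%s' evaluated outside its age window [%g, %g): id(s) %s",
            guideline$name, w[1], w[2],
            paste(utils::head(df$id[out_of_window], 10), collapse = ", "))
  if (anyNA(df$mean_sbp) || anyNA(df$mean_dbp))
    bp_stop("bp_data_error", "classify_bp(): missing mean BP for id(s): %s",
            paste(utils::head(df$id[is.na(df$mean_sbp) | is.na(df$mean_dbp)], 10),
                  collapse = ", "))

  ref <- guideline$reference
  hz <- NULL
  if (isTRUE(ref$requires_height)) {
    if (is.null(growth_ref))
      bp_stop("bp_coverage_error",
              "guideline '%s' reference requires height; supply growth_ref",
              guideline$name)
    hz <- height_zscore(df$height_cm, df$age_years, df$sex, growth_ref)
  }

  fixed_branch <- df$age_years >= guideline$fixed_threshold_age
  positive <- logical(nrow(df))
  if (any(!fixed_branch)) {
    i <- which(!fixed_branch)
    p <- guideline$percentile_cutoff
    thr_s <- predict_quantile(ref, p, df$age_years[i], df$sex[i], "sbp",
                              height_z = if (is.null(hz)) NULL else hz[i])
    thr_d <- predict_quantile(ref, p, df$age_years[i], df$sex[i], "dbp",
                              height_z = if (is.null(hz)) NULL else hz[i])
    positive[i] <- df$mean_sbp[i] >= thr_s | df$mean_dbp[i] >= thr_d
  }
  if (any(fixed_branch)) {
    i <- which(fixed_branch)
    positive[i] <- df$mean_sbp[i] >= guideline$fixed_sbp |
      df$mean_dbp[i] >= guideline$fixed_dbp
  }
  data.frame(
    id = df$id, age_years = df$age_years, sex = df$sex,
    status = factor(ifelse(positive, "positive", "negative"),
                    levels = c("negative", "positive")),
    basis = ifelse(fixed_branch, "fixed", "percentile"),
    stringsAsFactors = FALSE
  )
}
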