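# Fixtures built in code: tiny growth references and cohorts.

flat_growth_ref <- function(M = 140, S = 0.05, L = 1, ages = 0:18,
                            measure = "height") {
  df <- expand.grid(sex = c("female", "male"), age_years = ages)
  growth_reference(df$sex, df$age_years, L = L, M = M, S = S, measure = measure)
}

# A raw cohort data frame assembled by hand (id, readings etc.), bypassing
# the generator, for prep/IO tests.
tiny_cohort <- function(n = 6) {
  df <- data.frame(
    id = sprintf("K%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age_years = seq(5, 14, length.out = n),
    height_cm = seq(110, 165, length.out = n),
    weight_kg = seq(20, 55, length.out = n),
    waist_cm = seq(50, 70, length.out = n),
    origin_danish = TRUE, excl_medication = FALSE, excl_diagnosis = FALSE,
    sbp1 = 100, sbp2 = 102, sbp3 = 104,
    dbp1 = 60, dbp2 = 62, dbp3 = 64,
    heart_rate = 80,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("bp_cohort", "data.frame"))
}

# Construct a quantile-fit set directly from a coefficient matrix (taus x
# (intercept, age)), to exercise table building without fitting.
manual_qset <- function(coefs, taus, outcome = "sbp", sex = "female") {
  colnames(coefs) <- c("(Intercept)", "age_years")
  structure(list(outcome = outcome, sex = sex, taus = taus,
                 predictors = "age_years", coefficients = coefs, n = NA_integer_),
            class = "bp_quantile_set")
}

expect_bp_error <- function(expr, class) expect_error(expr, class = class)
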