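# Synthetic pediatric cohort generator.
#
# The generator emulates the structure of a population-based child cohort with
# oscillometric office blood pressure: ~1,700 children aged 4 to 15 completed
# years, triplicate readings one minute apart, age-trending mean BP with an
# age-increasing systolic spread and a roughly constant diastolic spread,
# anthropometry from per-sex LMS models, a small missing-weight fraction, and
# register-derived exclusion flags.  Defaults are calibrated once to the
# published cohort description and centile table; see the methods vignette.

# Per-sex mean heights (cm) at integer ages; spread grows from ~5 to ~8 cm,
# inside the 3.6-8.5 cm band reported for the national growth reference.
default_height_model <- function() {
  age <- 4:16
  sd <- 4.0 + 0.25 * age
  f_M <- c(104, 111, 117.5, 124, 130, 136, 142, 148, 154, 159.5, 163.5, 166, 167)
  m_M <- c(105, 112, 118.5, 125, 131, 136.5, 142, 147.5, 153, 159.5, 166, 172, 176)
  list(
    female = list(age = age, L = rep(1, 13), M = f_M, S = sd / f_M),
    male   = list(age = age, L = rep(1, 13), M = m_M, S = sd / m_M)
  )
}

# BMI medians dip in early childhood and rise towards 21-22 kg/m^2 at 18;
# mild right skew (L < 1).  The table extends to age 18 so the IOTF-style
# overweight cut-off (the centile through BMI 25 at 18) can be derived.
default_bmi_model <- function() {
  age <- 4:18
  f_M <- c(15.3, 15.2, 15.3, 15.6, 16.0, 16.4, 16.9, 17.5, 18.2, 18.9,
           19.5, 20.1, 20.6, 21.0, 21.4)
  m_M <- c(15.5, 15.4, 15.4, 15.6, 15.9, 16.3, 16.8, 17.4, 18.0, 18.7,
           19.4, 20.1, 20.7, 21.2, 21.7)
  list(
    female = list(age = age, L = rep(-0.8, 15), M = f_M, S = rep(0.11, 15)),
    male   = list(age = age, L = rep(-0.8, 15), M = m_M, S = rep(0.11, 15))
  )
}

# Systolic: median ~96 mmHg at age 4 rising ~1.4 mmHg/year; residual SD grows
# with age (heteroscedastic).  Diastolic: flatter trend, constant spread.
default_sbp_model <- function() {
  list(
    female = list(intercept = 90.5, age_slope = 1.37,
                  sd_intercept = 6.3, sd_age_slope = 0.11, height_beta = 0),
    male   = list(intercept = 90.4, age_slope = 1.38,
                  sd_intercept = 7.4, sd_age_slope = 0.11, height_beta = 0)
  )
}

default_dbp_model <- function() {
  list(
    female = list(intercept = 60.2, age_slope = 0.45,
                  sd_intercept = 4.9, sd_age_slope = 0, height_beta = 0),
    male   = list(intercept = 59.4, age_slope = 0.44,
                  sd_intercept = 4.9, sd_age_slope = 0, height_beta = 0)
  )
}

#' Configure the synthetic cohort generator
#'
#' Returns a validated generator configuration.  Defaults encode the stated
#' world the downstream analysis assumes: n = 1771 children, continuous
#' uniform age on [4, 16) (so "age 15" children exist as 15.0-15.99 completed
#' years), balanced sexes, Gaussian BP conditional on age and sex with an
#' age-increasing systolic spread and constant diastolic spread, triplicate
#' integer-mmHg readings, 3.5% missing weight, and a 14.6% overweight
#' fraction (the published 1771 minus 1512 normal-weight children).
#'
#' @param n_children number of children to draw.
#' @param age_range half-open age interval (years), within [0, 18).
#' @param sex_ratio fraction female.
#' @param height_model,bmi_model per-sex LMS tables by age (lists with
#'   elements `age`, `L`, `M`, `S`).
#' @param waist_model waist-to-height ratio model: `mean`, `sd`, and
#'   `bmi_loading` (WHtR units per BMI z).
#' @param sbp_model,dbp_model per-sex Gaussian BP models: `intercept` and
#'   `age_slope` (mmHg, mmHg/year) for the mean, `sd_intercept` and
#'   `sd_age_slope` for the residual SD, and `height_beta` (mmHg per height
#'   z-score; 0 by default, a knob for the height-inclusion comparison).
#'   A single unnamed list is shared by both sexes.
#' @param within_visit_sd SD (mmHg) of one reading around the child's true BP.
#'   The device's within-visit SD is not published; 3 mmHg is an assumption,
#'   not an estimate (see the methods vignette).
#' @param missing_weight_rate,missing_waist_rate missingness fractions.
#' @param overweight_rate fraction of children drawn from above the IOTF-style
#'   BMI cut-off.
#' @param exclusion_flag_rates named rates for `medication`, `diagnosis`,
#'   `non_danish_origin` flags.
#' @param reading_count_probs probabilities of a child having 1, 2 or 3
#'   reading pairs (trailing readings are the missing ones).
#' @param heart_rate_model `intercept`, `age_slope`, `sd` (per minute).
#' @param seed master seed; per-variable sub-streams are derived from it.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_children = 1771,
                             age_range = c(4, 16),
                             sex_ratio = 0.5,
                             height_model = default_height_model(),
                             bmi_model = default_bmi_model(),
                             waist_model = list(mean = 0.45, sd = 0.025,
                                                bmi_loading = 0.03),
                             sbp_model = default_sbp_model(),
                             dbp_model = default_dbp_model(),
                             within_visit_sd = 3,
                             missing_weight_rate = 0.035,
                             missing_waist_rate = 0.01,
                             overweight_rate = 0.146,
                             exclusion_flag_rates = list(medication = 0.03,
                                                         diagnosis = 0.02,
                                                         non_danish_origin = 0.05),
                             reading_count_probs = c(0.01, 0.01, 0.98),
                             heart_rate_model = list(intercept = 95,
                                                     age_slope = -1.6, sd = 9),
                             seed = 20201L) {
  cfg <- structure(
    list(n_children = n_children, age_range = age_range, sex_ratio = sex_ratio,
         height_model = per_sex(height_model), bmi_model = per_sex(bmi_model),
         waist_model = waist_model, sbp_model = per_sex(sbp_model),
         dbp_model = per_sex(dbp_model), within_visit_sd = within_visit_sd,
         missing_weight_rate = missing_weight_rate,
         missing_waist_rate = missing_waist_rate,
         overweight_rate = overweight_rate,
         exclusion_flag_rates = exclusion_flag_rates,
         reading_count_probs = reading_count_probs,
         heart_rate_model = heart_rate_model, seed = seed),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

# Accept a single BP/anthropometry sub-model shared by both sexes.
per_sex <- function(model) {
  if (is.list(model) && !is.null(names(model)) &&
      all(c("female", "male") %in% names(model))) return(model)
  list(female = model, male = model)
}

validate_generator_config <- function(cfg) {
  if (!is_scalar_number(cfg$n_children) || cfg$n_children < 0 ||
      cfg$n_children != floor(cfg$n_children))
    bp_stop("bp_config_error", "field 'n_children' must be a non-negative integer")
  if (!is.numeric(cfg$age_range) || length(cfg$age_range) != 2 ||
      cfg$age_range[1] >= cfg$age_range[2] ||
      cfg$age_range[1] < 0 || cfg$age_range[2] > 18)
    bp_stop("bp_config_error", "field 'age_range' must be an increasing pair within [0, 18]")
  check_rate(cfg$sex_ratio, "sex_ratio")
  check_rate(cfg$missing_weight_rate, "missing_weight_rate")
  check_rate(cfg$missing_waist_rate, "missing_waist_rate")
  check_rate(cfg$overweight_rate, "overweight_rate")
  check_nonneg(cfg$within_visit_sd, "within_visit_sd")
  for (nm in names(cfg$exclusion_flag_rates))
    check_rate(cfg$exclusion_flag_rates[[nm]],
               paste0("exclusion_flag_rates$", nm))
  if (length(cfg$reading_count_probs) != 3 ||
      any(cfg$reading_count_probs < 0) ||
      abs(sum(cfg$reading_count_probs) - 1) > 1e-8)
    bp_stop("bp_config_error", "field 'reading_count_probs' must be 3 probabilities summing to 1")
  for (out in c("sbp_model", "dbp_model")) {
    for (s in c("female", "male")) {
      m <- cfg[[out]][[s]]
      for (f in c("intercept", "age_slope", "sd_intercept", "sd_age_slope"))
        if (!is_scalar_number(m[[f]] %||% NA))
          bp_stop("bp_config_error", "field '%s$%s$%s' must be a number", out, s, f)
      if (m$sd_intercept < 0)
        bp_stop("bp_config_error", "field '%s$%s$sd_intercept' must be >= 0", out, s)
      sds <- m$sd_intercept + m$sd_age_slope * cfg$age_range
      if (any(sds < 0))
        bp_stop("bp_config_error",
                "field '%s$%s': residual SD negative within age_range", out, s)
    }
  }
  if (!is_scalar_number(cfg$seed))
    bp_stop("bp_config_error", "field 'seed' must be a single integer")
  cfg
}

# LMS model list -> growth_reference table restricted to rows covering ages.
model_as_reference <- function(model, measure) {
  rows <- lapply(c("female", "male"), function(s) {
    m <- model[[s]]
    data.frame(sex = s, age_years = m$age, L = m$L, M = m$M, S = m$S)
  })
  df <- do.call(rbind, rows)
  growth_reference(df$sex, df$age_years, df$L, df$M, df$S, measure = measure)
}

#' Emit the growth reference implied by a generator configuration
#'
#' The returned table is exactly the per-sex, per-integer-age LMS model the
#' generator draws from, so z-scoring generated measurements against it gives
#' approximately standard-normal values (exactly, up to output rounding).
#'
#' @param config a [generator_config()].
#' @param measure "height" or "bmi".
#' @return a [growth_reference()] table.
#' @export
make_growth_reference <- function(config, measure = c("height", "bmi")) {
  measure <- match.arg(measure)
  stopifnot(inherits(config, "generator_config"))
  model <- if (measure == "height") config$height_model else config$bmi_model
  model_as_reference(model, measure)
}

# The z-score above which a child is "overweight": the centile that passes
# through BMI 25 at age 18 in the configured BMI model.
generator_overweight_z <- function(config, sex) {
  ref <- make_growth_reference(config, "bmi")
  p <- lms_at(ref, sex, 18)
  lms_zscore(25, p$L, p$M, p$S)
}

#' Generate a synthetic cohort
#'
#' Draws `n_children` children per the configuration.  Each child receives a
#' continuous true systolic/diastolic BP from the Gaussian model at their age
#' and sex; individual readings are the true value plus independent
#' within-visit noise, rounded to integer mmHg (oscillometric devices report
#' integers).  Weight is set missing at the configured rate; exclusion flags
#' are drawn independently.  Identical configuration and seed give a
#' bit-identical cohort.
#'
#' @param config a [generator_config()].
#' @return a `bp_cohort` data frame (one row per child) with columns
#'   id, sex, age_years, height_cm, weight_kg, waist_cm, origin_danish,
#'   excl_medication, excl_diagnosis, sbp1..sbp3, dbp1..dbp3, heart_rate.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- as.integer(config$n_children)
  draw <- function(key) set.seed(substream_seed(config$seed, key))

  if (n == 0L) return(empty_cohort(config))

  draw("sex")
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  draw("age")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  height_ref <- make_growth_reference(config, "height")
  draw("height")
  z_height <- stats::rnorm(n)
  hp <- lms_at(height_ref, sex, age)
  height <- round(lms_inverse(z_height, hp$L, hp$M, hp$S), 1)

  # BMI z: two-part mixture pinned to the configured overweight fraction.
  bmi_ref <- make_growth_reference(config, "bmi")
  z_cut <- vapply(c(female = "female", male = "male"),
                  function(s) generator_overweight_z(config, s), numeric(1))
  draw("bmi")
  ow <- stats::runif(n) < config$overweight_rate
  u <- stats::runif(n)
  p_cut <- stats::pnorm(z_cut[ifelse(sex == "female", "female", "male")])
  z_bmi <- ifelse(ow,
                  stats::qnorm(p_cut + u * (1 - p_cut)),
                  stats::qnorm(u * p_cut))
  bp_lms <- lms_at(bmi_ref, sex, age)
  bmi <- lms_inverse(z_bmi, bp_lms$L, bp_lms$M, bp_lms$S)
  weight <- round(bmi * (height / 100)^2, 1)

  draw("waist")
  wm <- config$waist_model
  whtr <- wm$mean + wm$bmi_loading * z_bmi + stats::rnorm(n, 0, wm$sd)
  waist <- round(pmax(whtr, 0.3) * height, 1)

  true_bp <- function(key, model) {
    draw(key)
    e <- stats::rnorm(n)
    mu <- sdv <- numeric(n)
    for (s in c("female", "male")) {
      m <- model[[s]]
      i <- sex == s
      mu[i] <- m$intercept + m$age_slope * age[i] +
        (m$height_beta %||% 0) * z_height[i]
      sdv[i] <- m$sd_intercept + m$sd_age_slope * age[i]
    }
    mu + e * sdv
  }
  true_sbp <- true_bp("sbp", config$sbp_model)
  true_dbp <- true_bp("dbp", config$dbp_model)

  draw("readings")
  k <- sample.int(3L, n, replace = TRUE, prob = config$reading_count_probs)
  noise <- function() matrix(stats::rnorm(3 * n, 0, config$within_visit_sd),
                             nrow = n)
  sbp <- round(true_sbp + noise())
  dbp <- round(true_dbp + noise())
  for (j in 2:3) {
    sbp[k < j, j] <- NA
    dbp[k < j, j] <- NA
  }

  draw("missing_weight")
  weight[stats::runif(n) < config$missing_weight_rate] <- NA
  draw("missing_waist")
  waist[stats::runif(n) < config$missing_waist_rate] <- NA

  flag <- function(name) {
    rate <- config$exclusion_flag_rates[[name]] %||% 0
    draw(paste0("flag_", name))
    stats::runif(n) < rate
  }
  excl_medication <- flag("medication")
  excl_diagnosis <- flag("diagnosis")
  origin_danish <- !flag("non_danish_origin")

  draw("heart_rate")
  hm <- config$heart_rate_model
  heart_rate <- round(pmax(40, hm$intercept + hm$age_slope * age +
                             stats::rnorm(n, 0, hm$sd)))

  df <- data.frame(
    id = sprintf("C%06d", seq_len(n)),
    sex = sex, age_years = age, height_cm = height, weight_kg = weight,
    waist_cm = waist, origin_danish = origin_danish,
    excl_medication = excl_medication, excl_diagnosis = excl_diagnosis,
    sbp1 = sbp[, 1], sbp2 = sbp[, 2], sbp3 = sbp[, 3],
    dbp1 = dbp[, 1], dbp2 = dbp[, 2], dbp3 = dbp[, 3],
    heart_rate = heart_rate,
    stringsAsFactors = FALSE
  )
  as_bp_cohort(df, seed = config$seed, config_hash = config_hash(config))
}

empty_cohort <- function(config = NULL) {
  df <- data.frame(
    id = character(0), sex = character(0), age_years = numeric(0),
    height_cm = numeric(0), weight_kg = numeric(0), waist_cm = numeric(0),
    origin_danish = logical(0), excl_medication = logical(0),
    excl_diagnosis = logical(0),
    sbp1 = numeric(0), sbp2 = numeric(0), sbp3 = numeric(0),
    dbp1 = numeric(0), dbp2 = numeric(0), dbp3 = numeric(0),
    heart_rate = numeric(0), stringsAsFactors = FALSE
  )
  as_bp_cohort(df,
               seed = if (is.null(config)) NA_integer_ else config$seed,
               config_hash = if (is.null(config)) NA_character_ else config_hash(config))
}

as_bp_cohort <- function(df, seed = NA_integer_, config_hash = NA_character_) {
  if (anyDuplicated(df$id))
    bp_stop("bp_data_error", "cohort ids must be unique")
  structure(df, class = c("bp_cohort", "data.frame"),
            seed = seed, config_hash = config_hash)
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("<bp_cohort> %d children", nrow(x)))
  if (nrow(x))
    cat(sprintf(", ages %.1f-%.1f, %.0f%% female",
                min(x$age_years), max(x$age_years),
                100 * mean(x$sex == "female")))
  cat("\n")
  invisible(x)
}
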