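# Percentile engines: the three reference representations, guideline
# classification, serialization.

gauss_ref <- function(alpha_s = 104, sigma_s = 7, alpha_d = 65, sigma_d = 5,
                      beta = c(1.4), gamma = numeric(0), name = "toy_gauss") {
  one <- function(a, s) list(alpha = a, beta = beta, gamma = gamma, sigma = s)
  gaussian_poly_reference(list(
    sbp = list(female = one(alpha_s, sigma_s), male = one(alpha_s + 1, sigma_s)),
    dbp = list(female = one(alpha_d, sigma_d), male = one(alpha_d, sigma_d))
  ), name = name)
}

test_that("height_zscore round-trips through the LMS transform", {
  ref <- flat_growth_ref(M = 140, S = 0.05, L = 1)
  expect_equal(height_zscore(140, 10, "female", ref), 0)
  expect_equal(height_zscore(147, 10, "male", ref), 1)  # (x/M - 1)/S with L=1
  set.seed(12)
  for (i in 1:20) {
    z <- runif(1, -3, 3)
    h <- lms_inverse(z, 1, 140, 0.05)
    expect_equal(height_zscore(h, 8, "female", ref), z, tolerance = 1e-10)
  }
})

test_that("Gaussian polynomial percentiles follow the normal CDF", {
  ref <- gauss_ref()
  mu10 <- 104 + 1.4 * (10 - 10)
  expect_equal(percentile_of(ref, mu10, 10, "female", "sbp"), 50)
  expect_equal(percentile_of(ref, mu10 + qnorm(0.95) * 7, 10, "female", "sbp"),
               95, tolerance = 0.1 / 95)
  expect_equal(predict_quantile(ref, 95, 10, "female", "sbp"),
               mu10 + qnorm(0.95) * 7)

  # height-dependent model demands a z-score
  href <- gauss_ref(gamma = c(0.9))
  expect_true(href$requires_height)
  expect_bp_error(percentile_of(href, 110, 10, "female", "sbp"),
                  "bp_coverage_error")
  expect_equal(
    predict_quantile(href, 50, 10, "female", "sbp", height_z = 2) -
      predict_quantile(href, 50, 10, "female", "sbp", height_z = 0),
    1.8)
})

test_that("the packaged lookup reference reproduces its printed categories", {
  dref <- danish_reference()
  expect_equal(predict_quantile(dref, 95, 10.6, "female", "sbp"), 116)
  expect_identical(as.character(percentile_of(dref, 116, 10.6, "female", "sbp")),
                   ">=95th")
  expect_identical(as.character(percentile_of(dref, 115, 10.2, "female", "sbp")),
                   ">=90th")
  expect_identical(as.character(percentile_of(dref, 100, 10.9, "female", "sbp")),
                   "<90th")
  expect_bp_error(predict_quantile(dref, 95, 17, "female", "sbp"),
                  "bp_coverage_error")
  expect_bp_error(predict_quantile(dref, 85, 10, "female", "sbp"),
                  "bp_config_error")
})

test_that("quantile-set percentiles interpolate the grid and clamp the tails", {
  taus <- seq(0.05, 0.95, 0.05)
  cf <- cbind(80 + qnorm(taus) * 5, rep(1, 19))  # N(80 + age, 5) quantiles
  qs <- quantile_set_reference(manual_qset(cf, taus))
  mid <- predict_quantile(qs, 50, 10, "female", "sbp")
  expect_equal(mid, 90)
  expect_equal(percentile_of(qs, 90, 10, "female", "sbp"), 50)
  expect_equal(percentile_of(qs, 90 + qnorm(0.95) * 5, 10, "female", "sbp"), 95)
  expect_equal(percentile_of(qs, 40, 10, "female", "sbp"), 2.5)
  expect_equal(percentile_of(qs, 140, 10, "female", "sbp"), 97.5)
  # interpolated value sits between bracketing grid percentiles
  p <- percentile_of(qs, 92, 10, "female", "sbp")
  expect_gt(p, 100 * 0.60); expect_lt(p, 100 * 0.70)
})

test_that("percentile_of is non-decreasing in bp for every representation", {
  taus <- seq(0.05, 0.95, 0.05)
  models <- list(
    gauss = gauss_ref(),
    qset = quantile_set_reference(manual_qset(cbind(80 + qnorm(taus) * 5, rep(1, 19)), taus)),
    lookup = danish_reference()
  )
  bps <- seq(70, 150, by = 0.5)
  for (m in models) {
    p <- percentile_of(m, bps, 10.5, "female", "sbp")
    expect_true(all(diff(as.integer(factor(p, levels = unique(p)))) >= 0) ||
                  all(diff(as.numeric(p)) >= -1e-9))
  }
})

test_that("quantile-set and Gaussian representations classify consistently", {
  # homoscedastic world where both representations describe the same truth
  model <- list(intercept = 94, age_slope = 1.4, sd_intercept = 7,
                sd_age_slope = 0, height_beta = 0)
  cfg <- generator_config(n_children = 5000, seed = 27, sbp_model = model,
                          dbp_model = list(intercept = 60, age_slope = 0.45,
                                           sd_intercept = 4.9, sd_age_slope = 0,
                                           height_beta = 0),
                          within_visit_sd = 0)
  prep <- prepare_cohort(generate_cohort(cfg))
  fits <- list()
  for (s in c("female", "male"))
    fits[[s]] <- fit_quantile_set(prep, "sbp", s)
  qs <- quantile_set_reference(fits)
  one <- function() list(alpha = 94 + 1.4 * 10, beta = c(1.4),
                         gamma = numeric(0), sigma = 7)
  gp <- gaussian_poly_reference(list(sbp = list(female = one(), male = one())))
  thr_q <- predict_quantile(qs, 95, prep$age_years, prep$sex, "sbp")
  thr_g <- predict_quantile(gp, 95, prep$age_years, prep$sex, "sbp")
  agree <- mean((prep$mean_sbp >= thr_q) == (prep$mean_sbp >= thr_g))
  expect_gte(agree, 0.99)
})

test_that("guideline classification applies percentile and fixed branches", {
  dan <- guideline("danish")
  aap <- guideline_spec("aap", gauss_ref(), fixed_threshold_age = 13,
                        fixed_sbp = 130, fixed_dbp = 80)

  child <- function(age, sbp, dbp, sex = "female")
    data.frame(id = "X1", sex = sex, age_years = age, height_cm = 150,
               mean_sbp = sbp, mean_dbp = dbp)

  # fixed branch at and beyond the switch age, boundary inclusive
  r <- classify_bp(child(13.5, 130, 70), aap)
  expect_identical(as.character(r$status), "positive")
  expect_identical(r$basis, "fixed")
  r2 <- classify_bp(child(13.5, 129.5, 79.5), aap)
  expect_identical(as.character(r2$status), "negative")

  # percentile branch: exactly the 95th percentile value is positive
  thr <- predict_quantile(gauss_ref(), 95, 9, "female", "sbp")
  r3 <- classify_bp(child(9, thr, 60), aap)
  expect_identical(as.character(r3$status), "positive")
  expect_identical(r3$basis, "percentile")

  # and/or rule: diastolic alone can trigger
  thr_d <- predict_quantile(gauss_ref(), 95, 9, "female", "dbp")
  r4 <- classify_bp(child(9, 95, thr_d), aap)
  expect_identical(as.character(r4$status), "positive")

  # low BP far below thresholds is negative under ESH
  esh <- guideline_spec("esh", gauss_ref(), fixed_threshold_age = 16,
                        fixed_sbp = 140, fixed_dbp = 90)
  expect_identical(as.character(classify_bp(child(15, 98, 55), esh)$status),
                   "negative")

  # age window enforcement
  expect_bp_error(classify_bp(child(16.5, 110, 60), dan), "bp_range_error")
})

test_that("classification is monotone in BP", {
  aap <- guideline_spec("aap", gauss_ref(), fixed_threshold_age = 13,
                        fixed_sbp = 130, fixed_dbp = 80)
  for (age in c(8, 14)) {
    prev <- NULL
    for (sbp in seq(90, 150, 2)) {
      d <- data.frame(id = "X", sex = "male", age_years = age,
                      height_cm = 150, mean_sbp = sbp, mean_dbp = 60)
      cur <- as.character(classify_bp(d, aap)$status) == "positive"
      if (!is.null(prev)) expect_false(prev && !cur)
      prev <- cur
    }
  }
})

test_that("reference models round-trip through JSON", {
  tmp <- tempfile("refmodels")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  # gaussian
  g <- gauss_ref(gamma = c(0.5, 0.1))
  pg <- file.path(tmp, "g.json")
  write_reference_model(g, pg)
  g2 <- read_reference_model(pg)
  expect_equal(g2$coef, g$coef, tolerance = 1e-12)
  expect_true(g2$requires_height)

  # lookup
  dref <- danish_reference()
  pl <- file.path(tmp, "l.json")
  write_reference_model(dref, pl)
  l2 <- read_reference_model(pl)
  expect_equal(l2$table, dref$table)

  # quantile set
  taus <- seq(0.05, 0.95, 0.05)
  qs <- quantile_set_reference(manual_qset(cbind(80 + qnorm(taus) * 5, rep(1, 19)), taus))
  pq <- file.path(tmp, "q.json")
  write_reference_model(qs, pq)
  q2 <- read_reference_model(pq)
  expect_equal(predict_quantile(q2, 95, 8:12, "female", "sbp"),
               predict_quantile(qs, 95, 8:12, "female", "sbp"))

  expect_bp_error(read_reference_model(file.path(tmp, "nope.json")),
                  "bp_config_error")
})
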