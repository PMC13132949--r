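# Model fitting: least squares, splines, quantile sets, table emission,
# model comparison.

test_that("fit_linear reproduces hand-solved least squares and R2 bookkeeping", {
  # perfect fit
  x <- 1:10
  f <- fit_linear(2 * x, cbind(x = x))
  expect_equal(f$r2, 1)
  expect_equal(f$adj_r2, 1)

  # null model
  y <- c(3, 1, 4, 1, 5)
  f0 <- fit_linear(y, NULL)
  expect_equal(f0$r2, 0)
  expect_equal(f0$adj_r2, 0)
  expect_equal(unname(f0$coefficients), mean(y))

  # normal equations by hand: points (0,0), (1,1), (2,4)
  f2 <- fit_linear(c(0, 1, 4), cbind(x = c(0, 1, 2)))
  expect_equal(unname(f2$coefficients["x"]), 2)
  expect_equal(unname(f2$coefficients["(Intercept)"]), -1 / 3)

  # rank deficiency names the collinear column
  X <- cbind(a = 1:6, b = 2 * (1:6))
  err <- tryCatch(fit_linear(rnorm(6), X), condition = identity)
  expect_s3_class(err, "bp_singular_error")
  expect_match(conditionMessage(err), "b")
})

test_that("spline basis is smooth, linear in the tails, and spans the truncated-power space", {
  set.seed(3)
  x <- sort(runif(200, 0, 10))
  spec <- spline_spec(x)
  expect_equal(spec$knots,
               unname(quantile(x, c(0.25, 0.5, 0.75), type = 7)))
  B <- spline_basis(x, spec)
  expect_equal(ncol(B), 2)

  # second differences on a fine grid: no jump across any knot
  g <- seq(min(x), max(x), length.out = 4001)
  Bg <- spline_basis(g, spec)
  h <- g[2] - g[1]
  for (j in 1:2) {
    d2 <- diff(Bg[, j], differences = 2) / h^2
    expect_lt(max(abs(diff(d2))), 1e-3 * (1 + max(abs(d2))))
  }
  # affine beyond the largest knot: second differences vanish there
  # (stencil kept clear of the knot itself)
  tail_idx <- which(g[2:4000] > spec$knots[3] + 2.5 * h)
  for (j in 1:2) {
    d2 <- (diff(Bg[, j], differences = 2) / h^2)[tail_idx]
    expect_lt(max(abs(d2)), 1e-8)
  }

  # independent truncated-power restricted-cubic oracle: same fitted values
  k <- spec$knots
  tp <- function(u) pmax(u, 0)^3
  rcs_term <- (tp(x - k[1]) - tp(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
                 tp(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
  y <- sin(x) + 0.1 * x^2
  fit_ns <- lm.fit(cbind(1, x, B), y)
  fit_tp <- lm.fit(cbind(1, x, rcs_term), y)
  idx <- sample(length(x), 50)
  expect_equal(fit_ns$fitted.values[idx], fit_tp$fitted.values[idx],
               tolerance = 1e-8)

  expect_bp_error(spline_spec(c(1, 1, 1, 2)), "bp_data_error")
  expect_bp_error(spline_spec(knots = c(1, 3, 2)), "bp_config_error")
})

test_that("fit_quantile solves small cases exactly", {
  # intercept-only median
  f <- fit_quantile(c(1, 2, 3, 4, 5), NULL, tau = 0.5)
  expect_equal(unname(f$coefficients), 3)

  # translation equivariance
  set.seed(9)
  x <- runif(40); y <- 3 + 2 * x + rnorm(40)
  f0 <- fit_quantile(y, cbind(x = x), 0.3)
  f1 <- fit_quantile(y + 7, cbind(x = x), 0.3)
  expect_equal(unname(f1$coefficients["(Intercept)"]),
               unname(f0$coefficients["(Intercept)"]) + 7, tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["x"]), unname(f0$coefficients["x"]),
               tolerance = 1e-6)

  # exact interpolation data: zero loss at every tau
  yy <- 2 * (1:20)
  for (tau in c(0.1, 0.5, 0.9)) {
    ff <- fit_quantile(yy, cbind(x = 1:20), tau)
    expect_lt(ff$loss, 1e-9)
  }

  expect_bp_error(fit_quantile(1:10, NULL, tau = 0), "bp_config_error")
  expect_bp_error(fit_quantile(rnorm(6), cbind(a = 1:6, b = 2 * (1:6)), 0.5),
                  "bp_singular_error")
})

test_that("median regression agrees with least squares under symmetric noise", {
  set.seed(15)
  n <- 4000
  x <- runif(n, 4, 16)
  y <- 90 + 1.5 * x + rnorm(n, 0, 5)
  qf <- fit_quantile(y, cbind(age = x), 0.5)
  lf <- fit_linear(y, cbind(age = x))
  expect_equal(unname(qf$coefficients), unname(lf$coefficients),
               tolerance = 0.02)
})

test_that("per-tau slopes converge to slope + z_tau * sd-slope", {
  cfg <- generator_config(
    n_children = 8000, seed = 33, within_visit_sd = 0,
    sbp_model = list(intercept = 90, age_slope = 1.5,
                     sd_intercept = 2, sd_age_slope = 0.3, height_beta = 0))
  prep <- prepare_cohort(generate_cohort(cfg))
  set <- fit_quantile_set(prep, "sbp", "male", taus = c(0.05, 0.5, 0.95))
  slopes <- set$coefficients[, "age_years"]
  truth <- 1.5 + qnorm(c(0.05, 0.5, 0.95)) * 0.3
  expect_equal(unname(slopes), truth, tolerance = 0.12)
})

test_that("reference tables are rearranged, rounded, and validated", {
  taus <- seq(0.05, 0.95, 0.05)
  # degenerate fit: identical coefficients -> constant across percentiles
  cf <- matrix(rep(c(100, 1), each = 19), ncol = 2)
  tab <- build_reference_table(manual_qset(cf, taus), ages = 4:6,
                               percentiles = c(50, 90, 95))
  expect_true(all(tapply(tab$value_mmhg, tab$age, function(v) length(unique(v))) == 1))

  # crossing coefficients are repaired by rearrangement
  cf2 <- cbind(100 + seq(-9, 9), seq(1.9, 0.1, length.out = 19))  # cross at high age
  tab2 <- build_reference_table(manual_qset(cf2, taus), ages = 4:15,
                                percentiles = seq(5, 95, 5))
  mono <- tapply(tab2$value_mmhg, tab2$age, function(v) all(diff(v) >= 0))
  expect_true(all(mono))

  # rounding is half away from zero
  cf3 <- matrix(rep(c(100.5, 0), each = 19), ncol = 2)
  tab3 <- build_reference_table(manual_qset(cf3, taus), ages = 4,
                                percentiles = 50)
  expect_identical(tab3$value_mmhg, 101L)

  expect_bp_error(
    build_reference_table(manual_qset(cf, taus), ages = 4:6, percentiles = 72),
    "bp_config_error")
})

test_that("compare_models recovers a known height effect and the no-effect limit", {
  b <- 3  # mmHg per height z
  model <- list(intercept = 90, age_slope = 1.4, sd_intercept = 6,
                sd_age_slope = 0.1, height_beta = b)
  cfg <- generator_config(n_children = 6000, seed = 19, sbp_model = model,
                          missing_weight_rate = 0,
                          exclusion_flag_rates = list())
  prep <- prepare_cohort(generate_cohort(cfg),
                         bmi_ref = make_growth_reference(cfg, "bmi"))
  cmp <- compare_models(prep, make_growth_reference(cfg, "height"))
  # mean systolic 95th-percentile gap ~ b * 1.645
  expect_equal(cmp$height_gap$mean_abs_diff[cmp$height_gap$outcome == "sbp"],
               b * qnorm(0.95), tolerance = 0.25)
  # with a real height effect the simple model misses some positives
  expect_lt(cmp$detection$detection_rate, 100)
  expect_equal(cmp$detection$n,
               sum(prep$included & prep$weight_class == "normal"))

  # adjusted R2 ladder is present, bounded by 1, and height adds signal here
  expect_identical(nrow(cmp$adj_r2), 6L)
  expect_true(all(cmp$adj_r2$sbp <= 1 & cmp$adj_r2$dbp <= 1))
  r2 <- function(m) cmp$adj_r2$sbp[cmp$adj_r2$model == m]
  expect_gt(r2("age + height + sex"), r2("age + sex"))
})

test_that("a model compared with itself reclassifies nobody", {
  cfg <- generator_config(n_children = 1200, seed = 4)
  prep <- prepare_cohort(generate_cohort(cfg),
                         bmi_ref = make_growth_reference(cfg, "bmi"))
  rows <- prep[prep$included & prep$weight_class == "normal", ]
  set <- lapply(c(sbp = "sbp", dbp = "dbp"), function(o)
    fit_quantile_set(rows, o, "female", taus = 0.95))
  thr <- function(o) {
    cf <- set[[o]]$coefficients[1, ]
    cf[1] + cf[2] * rows$age_years
  }
  pos <- (rows$mean_sbp >= thr("sbp")) | (rows$mean_dbp >= thr("dbp"))
  tab <- build_reclass_table(pos, pos)
  expect_identical(tab$b + tab$c, 0L)
})
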