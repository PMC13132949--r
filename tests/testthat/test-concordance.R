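# Reclassification tables, rates, threshold gaps, Bland-Altman.

test_that("build_reclass_table cross-tabulates and conserves n", {
  x <- c(TRUE, TRUE, FALSE, FALSE)
  y <- c(TRUE, FALSE, TRUE, FALSE)
  t1 <- build_reclass_table(x, y)
  expect_identical(c(t1$a, t1$b, t1$c, t1$d), rep(1L, 4))
  expect_identical(t1$n, 4L)

  # identical labels: no off-diagonals
  t2 <- build_reclass_table(x, x)
  expect_identical(t2$b + t2$c, 0L)

  # NA pairs are dropped and reported
  t3 <- build_reclass_table(c(x, NA), c(y, TRUE))
  expect_identical(t3$n, 4L)
  expect_identical(t3$n_dropped, 1L)

  # factor labels with a "positive" level work too
  f <- factor(c("positive", "negative"), levels = c("negative", "positive"))
  t4 <- build_reclass_table(f, f)
  expect_identical(t4$a, 1L)

  expect_bp_error(build_reclass_table(x, y[1:3]), "bp_data_error")
  expect_bp_error(reclass_table(-1, 0, 0, 0), "bp_data_error")
})

test_that("detection and fn/fp rates follow their definitions", {
  t <- reclass_table(57, 26, 9, 1027)
  d <- detection_rate(t)
  expect_equal(d$percent, 100 * 57 / 83)
  expect_identical(d$percent_rounded, 69)
  r <- fn_fp_rates(t)
  expect_equal(r$fn_percent, 100 * 26 / 1119)
  expect_equal(r$fp_percent, 100 * 9 / 1119)

  expect_identical(detection_rate(reclass_table(5, 0, 3, 2))$percent_rounded, 100)
  expect_true(is.na(detection_rate(reclass_table(0, 0, 3, 2))$percent))
  expect_identical(fn_fp_rates(reclass_table(0, 0, 0, 4)),
                   list(fn_percent = 0, fp_percent = 0))
  # degenerate: benchmark all positive, comparator all negative
  t5 <- reclass_table(0, 10, 0, 0)
  expect_equal(fn_fp_rates(t5)$fn_percent, 100)
})

test_that("rates are invariant to permutation of children", {
  set.seed(31)
  bench <- runif(500) < 0.1
  comp <- bench & (runif(500) < 0.8)
  t1 <- build_reclass_table(bench, comp)
  perm <- sample(500)
  t2 <- build_reclass_table(bench[perm], comp[perm])
  expect_identical(unclass(t1), unclass(t2))
})

test_that("fn/fp rates are bounded by their margins", {
  set.seed(77)
  for (i in 1:20) {
    cnt <- rmultinom(1, 200, prob = runif(4, 0.05, 1))
    t <- reclass_table(cnt[1], cnt[2], cnt[3], cnt[4])
    r <- fn_fp_rates(t)
    expect_lte(r$fn_percent, 100 * (t$a + t$b) / t$n + 1e-12)
    expect_lte(r$fp_percent, 100 * (t$c + t$d) / t$n + 1e-12)
  }
})

test_that("diff_at_p95 sees translations exactly", {
  one <- function(a) list(alpha = a, beta = c(1.4), gamma = numeric(0), sigma = 7)
  A <- gaussian_poly_reference(list(sbp = list(female = one(104), male = one(105))))
  B <- gaussian_poly_reference(list(sbp = list(female = one(107), male = one(108))))
  d0 <- diff_at_p95(A, A, 4:15, "female")
  expect_true(all(d0$diff == 0))
  d3 <- diff_at_p95(A, B, 4:15, "female")
  expect_equal(d3$diff, rep(3, 12))
  expect_equal(d3$abs_diff, rep(3, 12))
})

test_that("lookup vs moment-matched Gaussian agree at the matched age", {
  dref <- danish_reference()
  p50 <- predict_quantile(dref, 50, 10, "female", "sbp")
  p95 <- predict_quantile(dref, 95, 10, "female", "sbp")
  sigma <- (p95 - p50) / qnorm(0.95)
  g <- gaussian_poly_reference(list(sbp = list(
    female = list(alpha = p50, beta = numeric(0), gamma = numeric(0),
                  sigma = sigma))))
  d <- diff_at_p95(dref, g, 10, "female")
  expect_equal(d$abs_diff, 0, tolerance = 1e-9)
})

test_that("bland_altman matches an independent recomputation", {
  expect_bp_error(bland_altman(1, 2), "bp_data_error")

  b <- c(100, 110, 120)
  ba0 <- bland_altman(b, b)
  expect_equal(c(ba0$mean_diff, ba0$sd_diff, ba0$loa_low, ba0$loa_high),
               rep(0, 4))
  bak <- bland_altman(b, b + 4)
  expect_equal(bak$mean_diff, 4)
  expect_equal(bak$sd_diff, 0)

  set.seed(91)
  x <- rnorm(50, 110, 8); y <- x + rnorm(50, 1, 2)
  ba <- bland_altman(x, y)
  d <- y - x
  m <- sum(d) / 50
  s <- sqrt(sum((d - m)^2) / 49)
  expect_equal(ba$mean_diff, m, tolerance = 1e-10)
  expect_equal(ba$sd_diff, s, tolerance = 1e-10)
  expect_equal(ba$loa_low, m - 1.96 * s, tolerance = 1e-10)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
})

test_that("a uniformly stricter comparator can miss but never over-call", {
  one <- function(a) list(alpha = a, beta = c(1.4), gamma = numeric(0), sigma = 6)
  oned <- function(a) list(alpha = a, beta = c(0.45), gamma = numeric(0), sigma = 4.5)
  bench <- gaussian_poly_reference(list(
    sbp = list(female = one(104), male = one(104)),
    dbp = list(female = oned(65), male = oned(65))))
  strict <- gaussian_poly_reference(list(
    sbp = list(female = one(109), male = one(109)),
    dbp = list(female = oned(70), male = oned(70))))
  cfg <- generator_config(n_children = 2000, seed = 55)
  prep <- prepare_cohort(generate_cohort(cfg))
  gb <- guideline_spec("bench", bench)
  gs <- guideline_spec("strict", strict)
  lb <- classify_bp(prep, gb)
  ls <- classify_bp(prep, gs)
  t <- build_reclass_table(lb$status, ls$status)
  expect_identical(t$c, 0L)
  expect_gte(t$b, 0L)
  rep <- concordance(lb$status, ls$status, sex = prep$sex)
  expect_named(rep$by_sex, c("female", "male"))
  expect_equal(rep$table$n, nrow(prep))
})
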