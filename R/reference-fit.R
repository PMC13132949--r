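# Model family for reference construction: linear regression (adjusted R^2
# comparison), restricted cubic splines, sex-stratified quantile fits on the
# 19-point 5% grid, and emission of integer-mmHg percentile tables with
# non-crossing enforced by isotonic rearrangement.

#' Least-squares fit with R-squared bookkeeping
#'
#' @param y outcome vector (mmHg).
#' @param X predictor matrix (NULL for the intercept-only null model).
#' @param intercept include an intercept.
#' @return a `bp_linear_fit`: coefficients, r2, adj_r2, residual_sd, n, p.
#'   adj_r2 = 1 - (1 - r2)(n - 1)/(n - p - 1) with p the number of
#'   predictors (excluding the intercept).
#' @export
fit_linear <- function(y, X = NULL, intercept = TRUE) {
  A <- build_design(y, X, intercept)
  y <- as.numeric(y)
  n <- nrow(A)
  p <- ncol(A) - as.integer(intercept)
  if (n < p + 2)
    bp_stop("bp_data_error", "fit_linear(): need n >= p + 2 (n = %d, p = %d)", n, p)
  check_full_rank(A)
  qr_A <- qr(A)
  beta <- qr.coef(qr_A, y)
  fitted <- as.numeric(A %*% beta)
  ssr <- sum((y - fitted)^2)
  sst <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), colnames(A)),
         r2 = r2, adj_r2 = adj_r2,
         residual_sd = sqrt(ssr / (n - p - 1)), n = n, p = p),
    class = "bp_linear_fit"
  )
}

#' @export
print.bp_linear_fit <- function(x, ...) {
  cat(sprintf("<bp_linear_fit> n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$p, x$r2, x$adj_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Three-knot spline specification
#'
#' Knots sit at the 1st quartile, median and 3rd quartile of the predictor
#' (linear-interpolation quantile definition, [stats::quantile()] type 7).
#'
#' @param x predictor values used to place the knots (ignored if `knots`
#'   given).
#' @param knots optional explicit knots (strictly increasing, length 3).
#' @param variable name of the predictor.
#' @return a `spline_spec`.
#' @export
spline_spec <- function(x = NULL, knots = NULL, variable = "x") {
  if (is.null(knots)) {
    if (is.null(x) || length(unique(x[!is.na(x)])) < 3)
      bp_stop("bp_data_error",
              "spline_spec(): need at least 3 distinct values to place knots")
    knots <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE))
  }
  if (length(knots) != 3 || any(diff(knots) <= 0))
    bp_stop("bp_config_error", "knots must be 3 strictly increasing values")
  structure(list(variable = variable, knots = as.numeric(knots)),
            class = "spline_spec")
}

#' Restricted (natural) cubic spline basis
#'
#' Expands a predictor into a 2-column basis spanning the restricted cubic
#' spline space with 3 knots: linear plus one nonlinear degree of freedom,
#' cubic between the outer knots, linear beyond them, with continuous first
#' and second derivatives everywhere.  Backed by [splines::ns()] with the
#' middle knot interior and the outer knots as boundary knots.
#'
#' @param x predictor vector.
#' @param spec a [spline_spec()]; computed from `x`'s quartiles if NULL.
#' @return numeric matrix with 2 columns and attributes `knots`, `spec`.
#' @export
spline_basis <- function(x, spec = NULL) {
  if (is.null(spec)) spec <- spline_spec(x)
  stopifnot(inherits(spec, "spline_spec"))
  k <- spec$knots
  B <- splines::ns(x, knots = k[2], Boundary.knots = k[c(1, 3)])
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0(spec$variable, c("_ns1", "_ns2"))
  attr(B, "knots") <- k
  attr(B, "spec") <- spec
  B
}

#' Fit a sex-stratified quantile regression set on the 5% grid
#'
#' One fit per tau in `taus` (default the 19-point grid 0.05, 0.10, ...,
#' 0.95) for one outcome and one sex, linear in the supplied predictors.
#'
#' @param data prepared cohort rows to fit on (already filtered to the
#'   analysis population).
#' @param outcome "sbp" or "dbp" (uses `mean_sbp` / `mean_dbp`).
#' @param sex "female" or "male".
#' @param taus quantile grid.
#' @param predictors column names used as linear predictors.
#' @return a `bp_quantile_set`: tau grid plus a taus x (1+p) coefficient
#'   matrix (intercept first).
#' @export
fit_quantile_set <- function(data, outcome = c("sbp", "dbp"),
                             sex = c("female", "male"),
                             taus = seq(0.05, 0.95, by = 0.05),
                             predictors = "age_years") {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  rows <- data[normalize_sex(data$sex) == sex, , drop = FALSE]
  y <- rows[[paste0("mean_", outcome)]]
  keep <- !is.na(y) & stats::complete.cases(rows[predictors])
  rows <- rows[keep, , drop = FALSE]
  y <- y[keep]
  X <- as.matrix(rows[predictors])
  coefs <- t(vapply(taus, function(tau) {
    fit_quantile(y, X, tau)$coefficients
  }, numeric(1L + length(predictors))))
  rownames(coefs) <- sprintf("tau_%.2f", taus)
  structure(
    list(outcome = outcome, sex = sex, taus = taus, predictors = predictors,
         coefficients = coefs, n = length(y)),
    class = "bp_quantile_set"
  )
}

#' @export
print.bp_quantile_set <- function(x, ...) {
  cat(sprintf("<bp_quantile_set> %s, %s, n = %d, %d taus (%.2f-%.2f)\n",
              x$outcome, x$sex, x$n, length(x$taus), min(x$taus), max(x$taus)))
  invisible(x)
}

# Predicted quantiles of one set at given ages, across the full tau grid,
# with non-crossing enforced by sorting (isotonic rearrangement) per age.
# Optional extra predictor values (e.g. height z) must be named.
predict_quantile_grid <- function(set, ages, extra = NULL, rearrange = TRUE) {
  stopifnot(inherits(set, "bp_quantile_set"))
  X <- matrix(1, nrow = length(ages), ncol = 1)
  for (p in set$predictors) {
    v <- if (p == "age_years") ages else {
      if (is.null(extra) || is.null(extra[[p]]))
        bp_stop("bp_coverage_error",
                "quantile set needs predictor '%s' to be supplied", p)
      rep_len(extra[[p]], length(ages))
    }
    X <- cbind(X, v)
  }
  Q <- X %*% t(set$coefficients)  # ages x taus
  if (rearrange && ncol(Q) > 1) Q <- t(apply(Q, 1, sort))
  dimnames(Q) <- list(NULL, sprintf("tau_%.2f", set$taus))
  Q
}

#' Build an integer-mmHg percentile reference table
#'
#' Evaluates each tau's linear predictor at integer ages, enforces
#' non-crossing by isotonic rearrangement (sorting across the tau grid at
#' each age), extracts the requested percentiles, and rounds half away from
#' zero to integer mmHg.  Unrounded values are kept in the
#' `unrounded` attribute.
#'
#' @param fits a `bp_quantile_set`, or a (possibly nested) list of them
#'   covering the outcomes/sexes wanted.
#' @param ages integer ages to tabulate.
#' @param percentiles percentiles to extract; each must sit on the fitted
#'   tau grid.
#' @return a `bp_reference_table` data frame: outcome, sex, age, percentile,
#'   value_mmhg.
#' @export
build_reference_table <- function(fits, ages = 4:15,
                                  percentiles = c(50, 90, 95)) {
  sets <- flatten_sets(fits)
  if (!length(sets))
    bp_stop("bp_config_error", "no quantile fits supplied")
  rows <- list()
  for (set in sets) {
    if (!identical(set$predictors, "age_years"))
      bp_stop("bp_config_error",
              "reference tables require age-only quantile fits (got: %s)",
              paste(set$predictors, collapse = ", "))
    idx <- match_tau(percentiles / 100, set$taus)
    Q <- predict_quantile_grid(set, ages)
    for (j in seq_along(percentiles)) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = set$outcome, sex = set$sex, age = as.integer(ages),
        percentile = percentiles[j], value = Q[, idx[j]]
      )
    }
  }
  long <- do.call(rbind, rows)
  long <- long[order(long$outcome, long$sex, long$age, long$percentile), ,
               drop = FALSE]
  rownames(long) <- NULL
  out <- long
  out$value_mmhg <- as.integer(round_half_away(long$value))
  out$value <- NULL
  structure(out, class = c("bp_reference_table", "data.frame"),
            unrounded = long)
}

#' @export
print.bp_reference_table <- function(x, ...) {
  cat(sprintf("<bp_reference_table> %d rows (%s; ages %d-%d; percentiles %s)\n",
              nrow(x), paste(unique(x$outcome), collapse = "/"),
              min(x$age), max(x$age),
              paste(unique(x$percentile), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

flatten_sets <- function(fits) {
  if (inherits(fits, "bp_quantile_set")) return(list(fits))
  if (!is.list(fits)) bp_stop("bp_config_error", "unrecognised quantile fits object")
  out <- list()
  for (f in fits) out <- c(out, flatten_sets(f))
  out
}

match_tau <- function(taus, grid) {
  idx <- vapply(taus, function(t) {
    i <- which(abs(grid - t) < 1e-9)
    if (!length(i))
      bp_stop("bp_config_error",
              "percentile %.6g is not on the fitted tau grid", 100 * t)
    i[1]
  }, integer(1))
  idx
}

#' Compare the full (age + sex + height) and simple (age + sex) models
#'
#' Produces (i) adjusted R-squared for the standard model ladder per outcome,
#' (ii) the mean and maximum absolute difference in the predicted 95th
#' percentile between children at median height and those at the 5th or 95th
#' height percentile, and (iii) the fraction of full-model-positive children
#' (systolic and/or diastolic BP at or above the fitted 95th percentile) that
#' are also positive under the simple model, plus the overall reclassified
#' fraction.  Quantile fits are sex-stratified; height enters as a z-score
#' against `growth_ref`.
#'
#' @param prepared prepared cohort (rows with `included = TRUE` and a normal
#'   weight classification are used when those columns are present).
#' @param growth_ref height [growth_reference()] used for z-scoring.
#' @param tau quantile level of the comparison threshold (default 0.95).
#' @param z_span height z offset corresponding to the 5th/95th height
#'   percentile (default `qnorm(0.95)`).
#' @return a `bp_model_comparison` list: `adj_r2` (data frame), `height_gap`
#'   (per-outcome mean/max absolute 95th-percentile difference, mmHg),
#'   `detection` (rates and denominators).
#' @export
compare_models <- function(prepared, growth_ref, tau = 0.95,
                           z_span = stats::qnorm(0.95)) {
  df <- as.data.frame(prepared)
  if (!is.null(df$included)) df <- df[df$included %in% TRUE, , drop = FALSE]
  if (!is.null(df$weight_class))
    df <- df[df$weight_class %in% "normal", , drop = FALSE]
  if (anyNA(df$height_cm))
    bp_stop("bp_data_error", "missing height for id(s): %s",
            paste(utils::head(df$id[is.na(df$height_cm)], 10), collapse = ", "))
  df$sex <- normalize_sex(df$sex)
  df$height_z <- height_zscore(df$height_cm, df$age_years, df$sex, growth_ref)
  df$female <- as.numeric(df$sex == "female")

  # (i) adjusted R^2 ladder
  ladder <- list(
    "age" = "age_years", "height" = "height_cm", "sex" = "female",
    "age + height" = c("age_years", "height_cm"),
    "age + sex" = c("age_years", "female"),
    "age + height + sex" = c("age_years", "height_cm", "female")
  )
  adj <- lapply(c(sbp = "mean_sbp", dbp = "mean_dbp"), function(yc) {
    vapply(ladder, function(vars)
      fit_linear(df[[yc]], as.matrix(df[vars]))$adj_r2, numeric(1))
  })
  adj_r2 <- data.frame(model = names(ladder), sbp = adj$sbp, dbp = adj$dbp,
                       row.names = NULL)

  # sex-stratified tau-level fits, full (age + height z) and simple (age)
  ages <- seq(floor(min(df$age_years)), ceiling(max(df$age_years)) - 1L)
  fits <- list()
  for (outcome in c("sbp", "dbp")) for (s in c("female", "male")) {
    fits[[outcome]][[s]] <- list(
      full = fit_quantile_set(df, outcome, s, taus = tau,
                              predictors = c("age_years", "height_z")),
      simple = fit_quantile_set(df, outcome, s, taus = tau,
                                predictors = "age_years")
    )
  }

  # (ii) predicted 95th-percentile gap across the height span
  gap_rows <- list()
  for (outcome in c("sbp", "dbp")) {
    diffs <- c()
    for (s in c("female", "male")) {
      full <- fits[[outcome]][[s]]$full
      at_z <- function(z) as.numeric(
        predict_quantile_grid(full, ages, extra = list(height_z = z)))
      mid <- at_z(0)
      diffs <- c(diffs, abs(mid - at_z(-z_span)), abs(mid - at_z(z_span)))
    }
    gap_rows[[outcome]] <- data.frame(
      outcome = outcome, mean_abs_diff = mean(diffs), max_abs_diff = max(diffs))
  }
  height_gap <- do.call(rbind, gap_rows)
  rownames(height_gap) <- NULL

  # (iii) per-child positivity under each model
  pos <- function(kind) {
    hit <- rep(FALSE, nrow(df))
    for (outcome in c("sbp", "dbp")) {
      thr <- numeric(nrow(df))
      for (s in c("female", "male")) {
        set <- fits[[outcome]][[s]][[kind]]
        i <- df$sex == s
        cf <- set$coefficients[1, ]
        thr[i] <- cf[1] + cf["age_years"] * df$age_years[i] +
          (if (kind == "full") cf["height_z"] * df$height_z[i] else 0)
      }
      hit <- hit | (df[[paste0("mean_", outcome)]] >= thr)
    }
    hit
  }
  full_pos <- pos("full")
  simple_pos <- pos("simple")
  n_full_pos <- sum(full_pos)
  detection <- if (n_full_pos > 0)
    100 * sum(full_pos & simple_pos) / n_full_pos else NA_real_
  reclassified <- 100 * mean(full_pos != simple_pos)

  structure(
    list(adj_r2 = adj_r2, height_gap = height_gap,
         detection = list(detection_rate = detection,
                          reclassified_rate = reclassified,
                          n = nrow(df), n_full_positive = n_full_pos,
                          n_simple_positive = sum(simple_pos)),
         tau = tau),
    class = "bp_model_comparison"
  )
}

#' @export
print.bp_model_comparison <- function(x, ...) {
  cat("<bp_model_comparison>\nAdjusted R-squared:\n")
  print(transform(x$adj_r2, sbp = round(sbp, 4), dbp = round(dbp, 4)))
  cat(sprintf("\n95th-percentile height gap (mmHg): %s\n",
              paste(sprintf("%s mean %.2f max %.2f", x$height_gap$outcome,
                            x$height_gap$mean_abs_diff,
                            x$height_gap$max_abs_diff), collapse = "; ")))
  d <- x$detection
  cat(sprintf("Simple-vs-full detection: %.1f%% (of %d full-model positives); reclassified %.2f%% of %d\n",
              d$detection_rate, d$n_full_positive, d$reclassified_rate, d$n))
  invisible(x)
}
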