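# Reference-system representations and percentile engines.
#
# Three representations of a pediatric BP reference are supported:
#   * lookup:        a printed table of percentile values per (sex, age);
#   * gaussian_poly: the US-style form mu = alpha + sum beta_j (age-10)^j
#                    + sum gamma_k z_height^k with Gaussian residual sigma;
#   * quantile_set:  fitted per-tau linear coefficients on the 5% grid.
# All three answer two questions: the BP value at a given percentile
# (predict_quantile) and the percentile (or category) of a given BP
# (percentile_of).

#' Lookup-table reference
#'
#' @param table a [build_reference_table()] result or a data frame with
#'   columns outcome, sex, age, percentile, value_mmhg.
#' @param age_coding how a continuous age maps to a table row: "floor"
#'   (completed years, the default) or "nearest".
#' @param name provenance label.
#' @return a `bp_ref_lookup` reference model.
#' @export
lookup_reference <- function(table, age_coding = c("floor", "nearest"),
                             name = "lookup") {
  age_coding <- match.arg(age_coding)
  df <- as.data.frame(table)[c("outcome", "sex", "age", "percentile", "value_mmhg")]
  df$sex <- normalize_sex(df$sex)
  df <- df[order(df$outcome, df$sex, df$age, df$percentile), , drop = FALSE]
  rownames(df) <- NULL
  chk <- stats::aggregate(value_mmhg ~ outcome + sex + age, data = df,
                          FUN = function(v) all(diff(v) >= 0))
  if (!all(chk$value_mmhg))
    bp_stop("bp_data_error",
            "lookup table has percentile columns that decrease within an age row")
  structure(list(type = "lookup", table = df, age_coding = age_coding,
                 percentiles = sort(unique(df$percentile)),
                 requires_height = FALSE, name = name),
            class = c("bp_ref_lookup", "bp_reference"))
}

#' Gaussian polynomial reference (US guideline functional form)
#'
#' @param coef nested list: `coef[[outcome]][[sex]]` with elements `alpha`
#'   (mmHg), `beta` (up to 4 coefficients on (age - 10)^j), `gamma` (up to 4
#'   coefficients on height z^k) and `sigma` (> 0).
#' @param name provenance label.
#' @return a `bp_ref_gauss` reference model; `requires_height` is TRUE when
#'   any gamma coefficient is nonzero.
#' @export
gaussian_poly_reference <- function(coef, name = "gaussian_poly") {
  req <- FALSE
  for (outcome in names(coef)) for (s in names(coef[[outcome]])) {
    cc <- coef[[outcome]][[s]]
    if (!is_scalar_number(cc$sigma) || cc$sigma <= 0)
      bp_stop("bp_config_error", "sigma must be positive (%s, %s)", outcome, s)
    coef[[outcome]][[s]]$beta <- as.numeric(cc$beta %||% numeric(0))
    coef[[outcome]][[s]]$gamma <- as.numeric(cc$gamma %||% numeric(0))
    if (any(coef[[outcome]][[s]]$gamma != 0)) req <- TRUE
  }
  structure(list(type = "gaussian_poly", coef = coef, requires_height = req,
                 name = name),
            class = c("bp_ref_gauss", "bp_reference"))
}

#' Quantile-fit reference
#'
#' Wraps fitted [fit_quantile_set()] objects (one per outcome and sex) as a
#' reference model.
#'
#' @param fits list or nested list of `bp_quantile_set` objects.
#' @param name provenance label.
#' @return a `bp_ref_qset` reference model.
#' @export
quantile_set_reference <- function(fits, name = "quantile_set") {
  sets <- flatten_sets(fits)
  store <- list()
  req <- FALSE
  for (set in sets) {
    store[[set$outcome]][[set$sex]] <- set
    if (!identical(set$predictors, "age_years")) req <- TRUE
  }
  structure(list(type = "quantile_set", sets = store, requires_height = req,
                 name = name),
            class = c("bp_ref_qset", "bp_reference"))
}

#' The packaged Danish oscillometric lookup reference
#'
#' Loads the packaged age- and sex-specific 50th/90th/95th percentile table
#' of oscillometric office BP for Danish children aged 4-15 (the population-
#' specific reference this package benchmarks against).
#'
#' @param age_coding passed to [lookup_reference()].
#' @return a `bp_ref_lookup`.
#' @export
danish_reference <- function(age_coding = "floor") {
  path <- system.file("extdata", "danish_2025_reference.csv",
                      package = "pedbpref")
  if (path == "")
    bp_stop("bp_config_error", "packaged danish_2025_reference.csv not found")
  df <- utils::read.csv(path, comment.char = "#")
  long <- stats::reshape(
    df, direction = "long",
    varying = c("p50", "p90", "p95"), v.names = "value_mmhg",
    times = c(50, 90, 95), timevar = "percentile", idvar = c("outcome", "sex", "age")
  )
  lookup_reference(long, age_coding = age_coding, name = "danish_2025")
}

lookup_age_key <- function(model, age) {
  if (model$age_coding == "floor") floor(age) else round(age)
}

gauss_mu <- function(cc, age, height_z) {
  mu <- rep(cc$alpha, length(age))
  if (length(cc$beta))
    for (j in seq_along(cc$beta)) mu <- mu + cc$beta[j] * (age - 10)^j
  if (length(cc$gamma) && any(cc$gamma != 0)) {
    if (is.null(height_z))
      bp_stop("bp_coverage_error",
              "this reference requires a height z-score")
    hz <- rep_len(height_z, length(age))
    for (k in seq_along(cc$gamma)) mu <- mu + cc$gamma[k] * hz^k
  }
  mu
}

#' BP value at a given percentile under a reference model
#'
#' @param model a `bp_reference`.
#' @param p percentile (0-100).  Lookup models support only their printed
#'   percentiles; quantile-set models any tau on their grid.
#' @param age age in years (vectorised).
#' @param sex sex (recycled).
#' @param outcome "sbp" or "dbp".
#' @param height_z height z-score, if the model requires height.
#' @return BP values in mmHg.
#' @export
predict_quantile <- function(model, p, age, sex, outcome = c("sbp", "dbp"),
                             height_z = NULL) {
  UseMethod("predict_quantile")
}

#' @export
predict_quantile.bp_ref_lookup <- function(model, p, age, sex,
                                           outcome = c("sbp", "dbp"),
                                           height_z = NULL) {
  outcome <- match.arg(outcome)
  if (!p %in% model$percentiles)
    bp_stop("bp_config_error",
            "percentile %g not present in lookup table (has: %s)",
            p, paste(model$percentiles, collapse = ", "))
  k <- max(length(age), length(sex))
  age <- rep_len(age, k); sex <- normalize_sex(rep_len(sex, k))
  key <- lookup_age_key(model, age)
  tab <- model$table[model$table$outcome == outcome &
                       model$table$percentile == p, , drop = FALSE]
  idx <- match(paste(sex, key), paste(tab$sex, tab$age))
  if (anyNA(idx))
    bp_stop("bp_coverage_error",
            "lookup table does not cover age(s): %s",
            paste(unique(key[is.na(idx)]), collapse = ", "))
  tab$value_mmhg[idx]
}

#' @export
predict_quantile.bp_ref_gauss <- function(model, p, age, sex,
                                          outcome = c("sbp", "dbp"),
                                          height_z = NULL) {
  outcome <- match.arg(outcome)
  k <- max(length(age), length(sex))
  age <- rep_len(age, k); sex <- normalize_sex(rep_len(sex, k))
  out <- numeric(k)
  for (s in unique(sex)) {
    cc <- model$coef[[outcome]][[s]]
    if (is.null(cc))
      bp_stop("bp_coverage_error", "no coefficients for %s / %s", outcome, s)
    i <- sex == s
    out[i] <- gauss_mu(cc, age[i],
                       if (is.null(height_z)) NULL else rep_len(height_z, k)[i]) +
      stats::qnorm(p / 100) * cc$sigma
  }
  out
}

#' @export
predict_quantile.bp_ref_qset <- function(model, p, age, sex,
                                         outcome = c("sbp", "dbp"),
                                         height_z = NULL) {
  outcome <- match.arg(outcome)
  k <- max(length(age), length(sex))
  age <- rep_len(age, k); sex <- normalize_sex(rep_len(sex, k))
  out <- numeric(k)
  for (s in unique(sex)) {
    set <- model$sets[[outcome]][[s]]
    if (is.null(set))
      bp_stop("bp_coverage_error", "no quantile fit for %s / %s", outcome, s)
    j <- match_tau(p / 100, set$taus)
    i <- sex == s
    extra <- if (is.null(height_z)) NULL else
      list(height_z = rep_len(height_z, k)[i])
    Q <- predict_quantile_grid(set, age[i], extra = extra)
    out[i] <- Q[, j]
  }
  out
}

#' Percentile (or category) of a BP value under a reference model
#'
#' Gaussian polynomial models return the continuous percentile
#' 100 Phi((bp - mu)/sigma).  Quantile-set models return the largest grid tau
#' whose predicted quantile is at or below the BP, linearly interpolated
#' between bracketing taus and clamped to [2.5, 97.5] outside the grid.
#' Lookup models return an ordered category (e.g. "<90th", ">=90th",
#' ">=95th"; boundary inclusive) because interpolating between three printed
#' columns would invent precision the table does not carry.
#'
#' @param model a `bp_reference`.
#' @param bp mean BP values in mmHg.
#' @param age,sex,outcome,height_z as in [predict_quantile()].
#' @return numeric percentiles, or an ordered factor for lookup models.
#' @export
percentile_of <- function(model, bp, age, sex, outcome = c("sbp", "dbp"),
                          height_z = NULL) {
  UseMethod("percentile_of")
}

#' @export
percentile_of.bp_ref_gauss <- function(model, bp, age, sex,
                                       outcome = c("sbp", "dbp"),
                                       height_z = NULL) {
  outcome <- match.arg(outcome)
  k <- max(length(bp), length(age), length(sex))
  bp <- rep_len(bp, k); age <- rep_len(age, k)
  sex <- normalize_sex(rep_len(sex, k))
  out <- numeric(k)
  for (s in unique(sex)) {
    cc <- model$coef[[outcome]][[s]]
    if (is.null(cc))
      bp_stop("bp_coverage_error", "no coefficients for %s / %s", outcome, s)
    i <- sex == s
    mu <- gauss_mu(cc, age[i],
                   if (is.null(height_z)) NULL else rep_len(height_z, k)[i])
    out[i] <- 100 * stats::pnorm((bp[i] - mu) / cc$sigma)
  }
  out
}

#' @export
percentile_of.bp_ref_qset <- function(model, bp, age, sex,
                                      outcome = c("sbp", "dbp"),
                                      height_z = NULL) {
  outcome <- match.arg(outcome)
  k <- max(length(bp), length(age), length(sex))
  bp <- rep_len(bp, k); age <- rep_len(age, k)
  sex <- normalize_sex(rep_len(sex, k))
  out <- numeric(k)
  for (s in unique(sex)) {
    set <- model$sets[[outcome]][[s]]
    if (is.null(set))
      bp_stop("bp_coverage_error", "no quantile fit for %s / %s", outcome, s)
    i <- which(sex == s)
    extra <- if (is.null(height_z)) NULL else
      list(height_z = rep_len(height_z, k)[i])
    Q <- predict_quantile_grid(set, age[i], extra = extra)
    taus <- set$taus
    for (jj in seq_along(i)) {
      q <- Q[jj, ]
      b <- bp[i[jj]]
      if (b < q[1]) { out[i[jj]] <- 2.5; next }
      if (b >= q[length(q)]) {
        out[i[jj]] <- if (abs(b - q[length(q)]) < 1e-12)
          100 * taus[length(taus)] else 97.5
        next
      }
      j <- max(which(q <= b))  # largest grid tau with quantile <= bp
      frac <- if (q[j + 1] > q[j]) (b - q[j]) / (q[j + 1] - q[j]) else 0
      out[i[jj]] <- 100 * (taus[j] + frac * (taus[j + 1] - taus[j]))
    }
  }
  out
}

#' @export
percentile_of.bp_ref_lookup <- function(model, bp, age, sex,
                                        outcome = c("sbp", "dbp"),
                                        height_z = NULL) {
  outcome <- match.arg(outcome)
  k <- max(length(bp), length(age), length(sex))
  bp <- rep_len(bp, k); age <- rep_len(age, k)
  sex <- rep_len(sex, k)
  thresholds <- model$percentiles[model$percentiles > 50]
  labels <- c(sprintf("<%gth", min(thresholds)),
              sprintf(">=%gth", thresholds))
  cat_idx <- rep(1L, k)
  for (j in seq_along(thresholds)) {
    v <- predict_quantile(model, thresholds[j], age, sex, outcome)
    cat_idx[bp >= v] <- j + 1L
  }
  factor(labels[cat_idx], levels = labels, ordered = TRUE)
}

#' Read / write a reference model as JSON
#'
#' JSON schema: an object with a `type` field ("lookup", "gaussian_poly" or
#' "quantile_set") plus the representation's data and provenance `name`.
#'
#' @param path file path.
#' @return the reference model (reader); the path, invisibly (writer).
#' @export
read_reference_model <- function(path) {
  if (!file.exists(path))
    bp_stop("bp_config_error", "reference model file not found: %s", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  switch(j$type %||% "",
    lookup = lookup_reference(j$table, age_coding = j$age_coding %||% "floor",
                              name = j$name %||% "lookup"),
    gaussian_poly = {
      coef <- jsonlite::fromJSON(path, simplifyVector = FALSE)$coef
      coef <- lapply(coef, function(o) lapply(o, function(cc) {
        list(alpha = as.numeric(cc$alpha),
             beta = as.numeric(unlist(cc$beta %||% list())),
             gamma = as.numeric(unlist(cc$gamma %||% list())),
             sigma = as.numeric(cc$sigma))
      }))
      gaussian_poly_reference(coef, name = j$name %||% "gaussian_poly")
    },
    quantile_set = {
      raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$sets
      sets <- lapply(raw, function(s) {
        cf <- do.call(rbind, lapply(s$coefficients, unlist))
        colnames(cf) <- unlist(s$coef_names)
        structure(list(outcome = s$outcome, sex = s$sex,
                       taus = as.numeric(unlist(s$taus)),
                       predictors = unlist(s$predictors),
                       coefficients = cf, n = s$n %||% NA_integer_),
                  class = "bp_quantile_set")
      })
      quantile_set_reference(sets, name = j$name %||% "quantile_set")
    },
    bp_stop("bp_config_error", "unknown reference model type in %s", path)
  )
}

#' @param model a `bp_reference`.
#' @rdname read_reference_model
#' @export
write_reference_model <- function(model, path) {
  obj <- switch(model$type,
    lookup = list(type = "lookup", name = model$name,
                  age_coding = model$age_coding, table = model$table),
    gaussian_poly = list(type = "gaussian_poly", name = model$name,
                         coef = model$coef),
    quantile_set = list(
      type = "quantile_set", name = model$name,
      sets = unlist(lapply(model$sets, function(o) lapply(o, function(s) {
        list(outcome = s$outcome, sex = s$sex, taus = s$taus,
             predictors = s$predictors,
             coef_names = colnames(s$coefficients),
             coefficients = apply(s$coefficients, 1, as.list, simplify = FALSE),
             n = s$n)
      })), recursive = FALSE, use.names = FALSE)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
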