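# LMS (lambda-mu-sigma) transforms and growth-reference tables.
#
# A growth reference stores, per sex and (typically integer) age, the Box-Cox
# power L, median M and coefficient of variation S of a measurement.  Z-scores
# follow the standard LMS transform; parameters are interpolated linearly in
# age between table rows.

#' LMS z-score transform
#'
#' Converts a measurement to a standard deviation score given the LMS
#' parameters of the reference distribution at the child's age and sex:
#' \deqn{z = ((x/M)^L - 1) / (L S)} for \eqn{L \neq 0} and
#' \deqn{z = \log(x/M) / S} in the log-normal limit \eqn{L = 0}.
#'
#' @param x measurement (> 0); vectorised.
#' @param L Box-Cox power (0 gives the log-normal limit).
#' @param M reference median (> 0).
#' @param S reference coefficient of variation (> 0).
#' @return z-scores, same length as the longest argument.
#' @export
lms_zscore <- function(x, L, M, S) {
  k <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, k); L <- rep_len(L, k); M <- rep_len(M, k); S <- rep_len(S, k)
  bad <- !is.na(x) & (x <= 0 | M <= 0 | S <= 0)
  if (any(bad))
    bp_stop("bp_data_error", "lms_zscore(): x, M and S must be positive")
  ifelse(abs(L) < 1e-12, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Inverse LMS transform
#'
#' Maps a z-score back to the measurement scale; the exact inverse of
#' [lms_zscore()].
#'
#' @inheritParams lms_zscore
#' @param z standard deviation score.
#' @return measurement values.
#' @export
lms_inverse <- function(z, L, M, S) {
  k <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, k); L <- rep_len(L, k); M <- rep_len(M, k); S <- rep_len(S, k)
  ifelse(abs(L) < 1e-12,
         M * exp(S * z),
         M * pmax(1 + L * S * z, 1e-12)^(1 / L))
}

#' Construct a growth-reference table
#'
#' @param sex character vector, "female"/"male" (or "F"/"M").
#' @param age_years numeric ages of the table rows.
#' @param L,M,S LMS parameters per row.
#' @param measure label of the measurement ("height", "bmi", ...).
#' @return a `growth_reference` data frame with columns sex, age_years, L, M, S.
#' @export
growth_reference <- function(sex, age_years, L, M, S, measure = "height") {
  sex <- normalize_sex(sex)
  df <- data.frame(sex = sex, age_years = as.numeric(age_years),
                   L = as.numeric(L), M = as.numeric(M), S = as.numeric(S))
  if (any(df$M <= 0) || any(df$S <= 0))
    bp_stop("bp_config_error", "growth_reference(): M and S must be positive")
  df <- df[order(df$sex, df$age_years), , drop = FALSE]
  rownames(df) <- NULL
  if (any(duplicated(df[c("sex", "age_years")])))
    bp_stop("bp_config_error", "growth_reference(): duplicated (sex, age) rows")
  structure(df, class = c("growth_reference", "data.frame"), measure = measure)
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "girl", "girls")] <- "female"
  s[s %in% c("m", "male", "boy", "boys")] <- "male"
  if (!all(s %in% c("female", "male")))
    bp_stop("bp_data_error", "sex must be coded female/male (or F/M)")
  s
}

#' Interpolate LMS parameters at given ages
#'
#' Linear interpolation in age within each sex; requesting an age outside the
#' table's range for that sex is a range error (no extrapolation).
#'
#' @param ref a [growth_reference()] table.
#' @param sex sex vector (recycled).
#' @param age ages in years.
#' @return data frame with columns L, M, S aligned with `age`.
#' @export
lms_at <- function(ref, sex, age) {
  stopifnot(inherits(ref, "growth_reference"))
  k <- max(length(sex), length(age))
  sex <- normalize_sex(rep_len(sex, k))
  age <- rep_len(as.numeric(age), k)
  out <- data.frame(L = rep(NA_real_, k), M = NA_real_, S = NA_real_)
  for (s in unique(sex)) {
    rows <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(rows) == 0)
      bp_stop("bp_coverage_error", "growth reference has no rows for sex '%s'", s)
    i <- which(sex == s)
    a <- age[i]
    ok <- !is.na(a)
    if (any(a[ok] < min(rows$age_years) - 1e-9 | a[ok] > max(rows$age_years) + 1e-9))
      bp_stop("bp_range_error",
              "age outside growth-reference range [%g, %g] for sex '%s'",
              min(rows$age_years), max(rows$age_years), s)
    if (nrow(rows) == 1) {
      out$L[i] <- rows$L; out$M[i] <- rows$M; out$S[i] <- rows$S
    } else {
      out$L[i] <- stats::approx(rows$age_years, rows$L, xout = a, rule = 2)$y
      out$M[i] <- stats::approx(rows$age_years, rows$M, xout = a, rule = 2)$y
      out$S[i] <- stats::approx(rows$age_years, rows$S, xout = a, rule = 2)$y
    }
  }
  out
}

#' Height z-score against a growth reference
#'
#' @param height height in cm.
#' @param age age in years.
#' @param sex sex vector.
#' @param growth_ref a [growth_reference()] table for height.
#' @return z-scores.
#' @export
height_zscore <- function(height, age, sex, growth_ref) {
  p <- lms_at(growth_ref, sex, age)
  lms_zscore(height, p$L, p$M, p$S)
}

#' Read / write growth-reference CSV (columns sex, age_years, L, M, S)
#'
#' @param path file path.
#' @rdname growth_csv
#' @return `read_growth_csv` returns a [growth_reference()]; the writer
#'   returns the path invisibly.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path))
    bp_stop("bp_config_error", "growth reference file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("sex", "age_years", "L", "M", "S")
  miss <- setdiff(need, names(df))
  if (length(miss))
    bp_stop("bp_data_error", "growth CSV missing column(s): %s",
            paste(miss, collapse = ", "))
  growth_reference(df$sex, df$age_years, df$L, df$M, df$S)
}

#' @param ref a growth reference table.
#' @rdname growth_csv
#' @export
write_growth_csv <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
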