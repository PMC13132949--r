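# Cohort CSV interchange format.
#
# One row per child; blank cells are missing values.  Reading columns sbp1-3 /
# dbp1-3 hold the up-to-three readings in measurement order: trailing blanks
# mean "reading not taken", an internal blank (e.g. sbp1 empty but sbp2
# present) is a recording error and rejected with its row number.

cohort_columns <- function() {
  c("id", "sex", "age_years", "height_cm", "weight_kg", "waist_cm",
    "origin_danish", "excl_medication", "excl_diagnosis",
    "sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3", "heart_rate")
}

#' Write a cohort as CSV
#'
#' A comment header line records the generator seed and configuration hash so
#' outputs are traceable; [read_cohort_csv()] skips it.
#'
#' @param cohort a `bp_cohort`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns(), drop = FALSE]
  df$origin_danish <- as.integer(df$origin_danish)
  df$excl_medication <- as.integer(df$excl_medication)
  df$excl_diagnosis <- as.integer(df$excl_diagnosis)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# pedbpref cohort seed=%s config_hash=%s",
                     attr(cohort, "seed") %||% NA,
                     attr(cohort, "config_hash") %||% NA), con)
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path input path.
#' @return a `bp_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    bp_stop("bp_config_error", "cohort file not found: %s", path)
  first <- readLines(path, n = 1)
  seed <- NA_real_; hash <- NA_character_
  if (grepl("^# pedbpref cohort", first)) {
    m <- regmatches(first, regexec("seed=([-0-9.eNA]+) config_hash=(\\S+)", first))[[1]]
    if (length(m) == 3) {
      seed <- suppressWarnings(as.numeric(m[2]))
      hash <- m[3]
    }
  }
  df <- utils::read.csv(path, na.strings = "", comment.char = "#",
                        stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns(), names(df))
  if (length(miss))
    bp_stop("bp_data_error", "cohort CSV missing required column(s): %s",
            paste(miss, collapse = ", "))
  df <- df[cohort_columns()]
  num_cols <- setdiff(cohort_columns(), c("id", "sex"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v) && !is.logical(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        bp_stop("bp_data_error", "non-numeric value in column '%s' at row %d",
                cl, bad[1])
      df[[cl]] <- conv
    }
  }
  df$sex <- normalize_sex(df$sex)
  for (cl in c("origin_danish", "excl_medication", "excl_diagnosis"))
    df[[cl]] <- df[[cl]] %in% 1 | df[[cl]] %in% TRUE
  for (prefix in c("sbp", "dbp")) {
    m <- as.matrix(df[paste0(prefix, 1:3)])
    gap <- (is.na(m[, 1]) & (!is.na(m[, 2]) | !is.na(m[, 3]))) |
      (is.na(m[, 2]) & !is.na(m[, 3]))
    if (any(gap))
      bp_stop("bp_data_error",
              "internal gap in %s readings at row %d (trailing blanks only)",
              prefix, which(gap)[1])
  }
  n_s <- rowSums(!is.na(df[paste0("sbp", 1:3)]))
  n_d <- rowSums(!is.na(df[paste0("dbp", 1:3)]))
  if (any(n_s != n_d))
    bp_stop("bp_data_error",
            "sbp/dbp reading counts differ at row %d", which(n_s != n_d)[1])
  as_bp_cohort(df, seed = seed, config_hash = hash)
}
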