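# Agreement between a benchmark reference and comparator guidelines:
# reclassification 2x2 tables, detection / false negative / false positive
# rates, 95th-percentile mmHg gaps, and Bland-Altman limits of agreement.

#' Construct a reclassification table from counts
#'
#' @param a benchmark-positive, comparator-positive count.
#' @param b benchmark-positive, comparator-negative count (missed cases).
#' @param c benchmark-negative, comparator-positive count (over-calls).
#' @param d benchmark-negative, comparator-negative count.
#' @param n_dropped children excluded from cross-classification (failed a
#'   classifier precondition).
#' @return a `bp_reclass` object.
#' @export
reclass_table <- function(a, b, c, d, n_dropped = 0L) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    bp_stop("bp_data_error", "reclass counts must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d),
                 n_dropped = as.integer(n_dropped)),
            class = "bp_reclass")
}

#' Cross-classify benchmark and comparator labels
#'
#' @param benchmark,comparator equal-length logical vectors (or factors with
#'   a "positive" level) over the same children; NA in either drops the child
#'   (reported in `n_dropped`).
#' @return a `bp_reclass` table.
#' @export
build_reclass_table <- function(benchmark, comparator) {
  bm <- as_positive(benchmark)
  cp <- as_positive(comparator)
  if (length(bm) != length(cp))
    bp_stop("bp_data_error",
            "label vectors differ in length (%d vs %d)", length(bm), length(cp))
  keep <- !is.na(bm) & !is.na(cp)
  bm <- bm[keep]; cp <- cp[keep]
  reclass_table(sum(bm & cp), sum(bm & !cp), sum(!bm & cp), sum(!bm & !cp),
                n_dropped = sum(!keep))
}

as_positive <- function(x) {
  if (is.logical(x)) return(x)
  if (is.factor(x) || is.character(x)) return(as.character(x) == "positive")
  bp_stop("bp_data_error", "labels must be logical or positive/negative")
}

#' Detection rate of a reclassification table
#'
#' The fraction of benchmark-positives that the comparator also calls
#' positive, 100 a / (a + b), reported unrounded and rounded to the nearest
#' integer percent (half away from zero).  With no benchmark positives the
#' rate is undefined and reported as NA.
#'
#' @param table a `bp_reclass`.
#' @return list with `percent` and `percent_rounded`.
#' @export
detection_rate <- function(table) {
  stopifnot(inherits(table, "bp_reclass"))
  if (table$a + table$b == 0)
    return(list(percent = NA_real_, percent_rounded = NA_real_))
  p <- 100 * table$a / (table$a + table$b)
  list(percent = p, percent_rounded = round_half_away(p))
}

#' False negative and false positive rates
#'
#' fn = 100 b / n (benchmark-positives missed by the comparator, as a share
#' of all children); fp = 100 c / n.
#'
#' @param table a `bp_reclass`.
#' @return list with `fn_percent` and `fp_percent`.
#' @export
fn_fp_rates <- function(table) {
  stopifnot(inherits(table, "bp_reclass"))
  if (table$n == 0)
    bp_stop("bp_data_error", "empty reclassification table")
  list(fn_percent = 100 * table$b / table$n,
       fp_percent = 100 * table$c / table$n)
}

#' @export
print.bp_reclass <- function(x, ...) {
  cat("<bp_reclass>            comparator\n")
  cat("benchmark      >=cutoff   <cutoff\n")
  cat(sprintf("  >=cutoff   %8d  %8d\n", x$a, x$b))
  cat(sprintf("  <cutoff    %8d  %8d\n", x$c, x$d))
  dr <- detection_rate(x)
  if (!is.na(dr$percent))
    cat(sprintf("detection: %d/(%d + %d) = %d%%\n",
                x$a, x$a, x$b, dr$percent_rounded))
  if (x$n_dropped > 0)
    cat(sprintf("(%d children dropped before cross-classification)\n", x$n_dropped))
  invisible(x)
}

#' Per-age difference in a percentile threshold between two models
#'
#' Signed (`model_b - model_a`) and absolute differences of the two models'
#' percentile values per age, for one sex, with height fixed at the growth
#' reference's median (z = 0) for height-dependent models.
#'
#' @param model_a,model_b `bp_reference` objects.
#' @param ages integer ages.
#' @param sex "female" or "male".
#' @param outcome "sbp" or "dbp".
#' @param p percentile (default 95).
#' @param height_z height z-score at which to evaluate (default 0, the 50th
#'   height percentile).
#' @return data frame: age, value_a, value_b, diff, abs_diff.
#' @export
diff_at_p95 <- function(model_a, model_b, ages, sex, outcome = "sbp",
                        p = 95, height_z = 0) {
  va <- predict_quantile(model_a, p, ages, sex, outcome, height_z = height_z)
  vb <- predict_quantile(model_b, p, ages, sex, outcome, height_z = height_z)
  data.frame(age = ages, sex = sex, outcome = outcome,
             value_a = va, value_b = vb,
             diff = vb - va, abs_diff = abs(vb - va))
}

#' Bland-Altman agreement statistics
#'
#' Differences are comparator minus benchmark; limits of agreement are the
#' mean difference +/- 1.96 SD (n - 1 denominator).
#'
#' @param benchmark,comparator paired values in mmHg (>= 2 pairs).
#' @return a `bp_bland_altman`: mean_diff, sd_diff, loa_low, loa_high, n.
#' @export
bland_altman <- function(benchmark, comparator) {
  if (length(benchmark) != length(comparator))
    bp_stop("bp_data_error", "paired vectors differ in length")
  keep <- !is.na(benchmark) & !is.na(comparator)
  d <- comparator[keep] - benchmark[keep]
  if (length(d) < 2)
    bp_stop("bp_data_error", "bland_altman(): need at least 2 pairs")
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d)),
            class = "bp_bland_altman")
}

#' @export
print.bp_bland_altman <- function(x, ...) {
  cat(sprintf("<bp_bland_altman> n = %d, mean diff = %.2f mmHg, LoA [%.2f, %.2f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Full concordance report between benchmark and comparator labels
#'
#' @param benchmark,comparator label vectors as in [build_reclass_table()].
#' @param sex optional sex vector for a per-sex breakdown.
#' @param acceptable_detection detection-rate acceptability bound in percent
#'   (a screening-policy default, configurable).
#' @return a `bp_concordance`: table, detection, fn/fp rates, per-sex
#'   breakdown, threshold_pass.
#' @export
concordance <- function(benchmark, comparator, sex = NULL,
                        acceptable_detection = 85) {
  tab <- build_reclass_table(benchmark, comparator)
  det <- detection_rate(tab)
  rates <- fn_fp_rates(tab)
  by_sex <- NULL
  if (!is.null(sex)) {
    sex <- normalize_sex(sex)
    by_sex <- lapply(stats::setNames(nm = sort(unique(sex))), function(s) {
      t2 <- build_reclass_table(benchmark[sex == s], comparator[sex == s])
      list(table = t2, detection = detection_rate(t2), rates = fn_fp_rates(t2))
    })
  }
  structure(
    list(table = tab, detection = det, fn_percent = rates$fn_percent,
         fp_percent = rates$fp_percent, by_sex = by_sex,
         acceptable_detection = acceptable_detection,
         threshold_pass = !is.na(det$percent) &&
           det$percent >= acceptable_detection),
    class = "bp_concordance"
  )
}

#' @export
print.bp_concordance <- function(x, ...) {
  print(x$table)
  cat(sprintf("fn = %.1f%%, fp = %.1f%%; acceptable detection >= %g%%: %s\n",
              x$fn_percent, x$fp_percent, x$acceptable_detection,
              if (isTRUE(x$threshold_pass)) "yes" else "no"))
  if (!is.null(x$by_sex)) {
    for (s in names(x$by_sex)) {
      d <- x$by_sex[[s]]$detection
      cat(sprintf("  %s: detection %s%%\n", s,
                  if (is.na(d$percent)) "NA" else d$percent_rounded))
    }
  }
  invisible(x)
}
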