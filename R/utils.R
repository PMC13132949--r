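# Internal helpers: rounding, conditions, logging, config hashing.

#' Round half away from zero
#'
#' Printed reference tables use commercial rounding (0.5 rounds up in
#' magnitude), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers can distinguish configuration, data, range,
# coverage and singularity failures.
bp_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "pedbpref_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Emit a structured log line to standard error
#'
#' The threshold is controlled by `options(pedbpref.log_level = )`, one of
#' "debug", "info", "warn", "error".
#'
#' @param level log level of this record.
#' @param fmt,... sprintf-style message.
#' @return invisibly, TRUE if the record was emitted.
#' @export
bp_log <- function(level = c("info", "debug", "warn", "error"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("pedbpref.log_level", "info")
  if (!threshold %in% names(.log_levels)) threshold <- "info"
  emit <- .log_levels[[level]] >= .log_levels[[threshold]]
  if (emit) {
    msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
    message(sprintf("[%s] pedbpref: %s", toupper(level), msg))
  }
  invisible(emit)
}

# Stable md5 fingerprint of any jsonlite-serialisable configuration object.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(
    jsonlite::toJSON(unclass_recursive(x), auto_unbox = TRUE, digits = NA,
                     force = TRUE, null = "null"),
    f
  )
  unname(tools::md5sum(f))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else {
    x
  }
}

# Deterministic sub-stream seed per named variable, so adding one variable to
# the generator does not perturb the draws of the others.
substream_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) %% 1048576 + h * 9973) %% 2147483629)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_rate <- function(x, field) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    bp_stop("bp_config_error", "field '%s' must be a single rate in [0, 1]", field)
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is_scalar_number(x) || x < 0)
    bp_stop("bp_config_error", "field '%s' must be a single non-negative number", field)
  invisible(x)
}
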