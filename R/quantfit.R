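# Quantile regression by check-loss minimisation.
#
# The tau-th conditional quantile is estimated by minimising the pinball loss
#   sum_i rho_tau(y_i - x_i' beta),  rho_tau(u) = u (tau - 1{u < 0}),
# a piecewise-linear convex program.  The solver runs a Hunter-Lange MM
# (iteratively reweighted least squares) iteration with a shrinking
# epsilon-smoothing schedule, then polishes the solution exactly: an optimal
# basic solution interpolates p observations, so the p-subsets of the
# observations with the smallest absolute residuals are enumerated and the
# best vertex kept.  Any minimiser on the optimal face is acceptable.

#' Pinball (check) loss
#'
#' @param y outcome vector.
#' @param X design matrix (including any intercept column).
#' @param beta coefficient vector.
#' @param tau quantile level in (0, 1).
#' @return the summed check loss.
#' @export
pinball_loss <- function(y, X, beta, tau) {
  r <- as.numeric(y - X %*% beta)
  sum(r * (tau - (r < 0)))
}

#' Fit one quantile regression
#'
#' @param y numeric outcome (mmHg).
#' @param X predictor matrix (or NULL for an intercept-only model).  An
#'   intercept column is added unless `intercept = FALSE`.
#' @param tau quantile level in (0, 1).
#' @param intercept include an intercept term.
#' @param max_iter MM iteration cap per smoothing level.
#' @param tol coefficient-change convergence tolerance.
#' @return a `bp_quantile_fit` with elements `coefficients`, `tau`, `loss`,
#'   `n`, `converged`.
#' @export
fit_quantile <- function(y, X = NULL, tau, intercept = TRUE,
                         max_iter = 100L, tol = 1e-9) {
  if (!is_scalar_number(tau) || tau <= 0 || tau >= 1)
    bp_stop("bp_config_error", "tau must lie strictly between 0 and 1")
  A <- build_design(y, X, intercept)
  y <- as.numeric(y)
  n <- nrow(A); p <- ncol(A)
  if (n < p + 2)
    bp_stop("bp_data_error", "fit_quantile(): need n >= p + 2 (n = %d, p = %d)", n, p)
  check_full_rank(A)

  # start from the least-squares solution
  beta <- qr.coef(qr(A), y)
  scale <- stats::sd(y)
  if (!is.finite(scale) || scale == 0) scale <- 1
  eps <- 1e-2 * scale
  repeat {
    for (it in seq_len(max_iter)) {
      r <- y - A %*% beta
      w <- 1 / (abs(r) + eps)
      M <- crossprod(A, A * as.numeric(w))
      b <- crossprod(A, y * as.numeric(w)) + (2 * tau - 1) * colSums(A)
      new_beta <- tryCatch(solve(M, b), error = function(e) qr.solve(M, b))
      if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
        beta <- new_beta
        break
      }
      beta <- new_beta
    }
    if (eps <= 1e-9 * scale) break
    eps <- eps / 10
  }
  beta <- as.numeric(beta)

  # exact vertex polish over near-active observations
  r <- as.numeric(y - A %*% beta)
  k <- min(n, p + 6L)
  cand <- order(abs(r))[seq_len(k)]
  best <- beta
  best_loss <- pinball_loss(y, A, beta, tau)
  subsets <- utils::combn(cand, p, simplify = FALSE)
  for (s in subsets) {
    As <- A[s, , drop = FALSE]
    bs <- tryCatch(solve(As, y[s]), error = function(e) NULL)
    if (is.null(bs) || any(!is.finite(bs))) next
    l <- pinball_loss(y, A, bs, tau)
    if (l < best_loss - 1e-12) {
      best <- as.numeric(bs)
      best_loss <- l
    }
  }
  structure(
    list(coefficients = stats::setNames(best, colnames(A)),
         tau = tau, loss = best_loss, n = n, converged = TRUE),
    class = "bp_quantile_fit"
  )
}

build_design <- function(y, X, intercept) {
  n <- length(y)
  if (is.null(X)) {
    A <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    A <- as.matrix(X)
    if (is.null(colnames(A)))
      colnames(A) <- paste0("x", seq_len(ncol(A)))
    if (nrow(A) != n)
      bp_stop("bp_data_error", "nrow(X) (%d) does not match length(y) (%d)",
              nrow(A), n)
  }
  if (intercept)
    A <- cbind(`(Intercept)` = rep(1, n), A)
  if (ncol(A) == 0)
    bp_stop("bp_config_error", "model has no terms (no predictors, no intercept)")
  if (anyNA(A) || anyNA(y))
    bp_stop("bp_data_error", "missing values in y or X")
  A
}

check_full_rank <- function(A) {
  q <- qr(A)
  if (q$rank < ncol(A)) {
    bad <- colnames(A)[q$pivot[(q$rank + 1):ncol(A)]]
    bp_stop("bp_singular_error",
            "design matrix is rank deficient; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.bp_quantile_fit <- function(x, ...) {
  cat(sprintf("<bp_quantile_fit> tau = %.2f, n = %d, loss = %.4f\n",
              x$tau, x$n, x$loss))
  print(round(x$coefficients, 4))
  invisible(x)
}
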