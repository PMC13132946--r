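`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ta <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_ta(msg)
  invisible(TRUE)
}

is_symmetric_tol <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# objective value returned when an implied covariance is not positive-definite;
# sloped by the most negative eigenvalue so the optimizer is pushed back into
# the feasible region rather than stalling on a flat plateau
PENALTY_BASE <- 1e10

penalized_objective <- function(sigma) {
  ev <- tryCatch(min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) -1)
  PENALTY_BASE * (1 + abs(min(ev, 0)))
}

chol_or_null <- function(sigma) {
  tryCatch(chol(sigma), error = function(e) NULL)
}

# standard-normal truncated draw on [lo, hi] by inverse-CDF
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
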