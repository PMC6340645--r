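#' Second-difference operator
#'
#' The (N-2) x N sparse matrix `D` with rows `(1, -2, 1)` so that
#' `(D %*% tau)[t] = tau[t+2] - 2*tau[t+1] + tau[t]` — the discrete second
#' derivative over all interior points.
#'
#' @param n Series length (>= 3).
#' @return A `dgCMatrix`.
#' @export
second_diff_matrix <- function(n) {
  if (n < 3) stop_echogate("second difference needs n >= 3, got %d", n)
  Matrix::bandSparse(n - 2, n, k = 0:2,
                     diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
}

#' Hodrick-Prescott trend filter
#'
#' Decomposes a univariate series `u` into a smooth trend and a residual
#' by minimizing `sum((u - tau)^2) + lambda * sum((diff(tau, 2))^2)`.
#' The minimizer solves the sparse SPD system
#' `(I + lambda * t(D) %*% D) tau = u` with `D` the second-difference
#' operator; boundaries are unconstrained (natural).  Constant and linear
#' series are in the null space of `D`, so the filter reproduces them
#' exactly and always preserves the mean.
#'
#' @param u Numeric series of length >= 3.
#' @param lambda Smoothness penalty, >= 0.  Larger values push more of the
#'   signal into the residual; 6400 separates respiration (trend) from the
#'   heart beat (residual) at ~233 FPS mouse rates.
#' @return List with `trend` and `residual` (`u - trend`, exactly).
#' @export
hp_filter <- function(u, lambda = 6400) {
  u <- as.numeric(u)
  n <- length(u)
  if (n < 3) stop_echogate("hp_filter needs length >= 3, got %d", n)
  if (!is.finite(lambda) || lambda < 0)
    stop_echogate("lambda must be a nonnegative number")
  if (any(!is.finite(u))) stop_echogate("hp_filter input contains non-finite values")
  if (lambda == 0) return(list(trend = u, residual = rep(0, n)))
  D <- second_diff_matrix(n)
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  trend <- as.numeric(Matrix::solve(A, u))
  list(trend = trend, residual = u - trend)
}

# Filter every row of a matrix with a single Cholesky factorization.
hp_filter_rows <- function(S, lambda) {
  n <- ncol(S)
  if (lambda == 0)
    return(list(trend = S, residual = matrix(0, nrow(S), n)))
  D <- second_diff_matrix(n)
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  trend <- t(as.matrix(Matrix::solve(A, t(S))))
  list(trend = trend, residual = S - trend)
}
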