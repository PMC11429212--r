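# Epsilon-insensitive support vector regression with a Gaussian (RBF)
# kernel, solved in the dual by sequential minimal optimization.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an epsilon-SVR EBV predictor
#'
#' Solves the epsilon-SVR dual (box constraints `0 <= a, a* <= 1/lambda`,
#' equality constraint `sum(a - a*) = 0`, complementarity `a a* = 0`) with a
#' Gaussian kernel `k(x, x') = exp(-gamma ||x - x'||^2)` by a maximal
#' violating pair SMO, to a KKT gap tolerance.  Predictions include the
#' customary bias term of the dual formulation.  Defaults are the tuned
#' values used for the gait scores: `epsilon = 0.1`, `lambda = 1`
#' (`C = 1/lambda`), `gamma = 0.0125`.
#'
#' @param X centered feature matrix (n x p).
#' @param y target EBV vector.
#' @param epsilon half-width of the insensitivity tube (target units).
#' @param lambda regularization; the box constraint is `C = 1/lambda`.
#' @param gamma RBF kernel bandwidth.
#' @param tol KKT gap tolerance (default 1e-6).
#' @param max_iter SMO iteration cap.
#' @return object of class `gait_svr`: support-vector coefficients
#'   `beta = a - a*`, support rows, bias `b`, hyperparameters, `n_sv`.
#' @export
svr_fit <- function(X, y, epsilon = 0.1, lambda = 1, gamma = 0.0125,
                    tol = 1e-6, max_iter = 200000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, lambda > 0, gamma > 0, epsilon >= 0)
  K <- rbf_kernel(X, X, gamma)
  fit <- svr_smo(K, as.numeric(y), C = 1 / lambda, eps = epsilon,
                 tol = tol, max_iter = as.integer(max_iter))
  if (fit$gap > tol && fit$iterations >= max_iter) {
    stop("SVR did not reach the KKT tolerance within ", max_iter,
         " iterations (gap ", signif(fit$gap, 3), ")")
  }
  sv <- which(abs(fit$beta) > 1e-12)
  structure(list(beta = fit$beta[sv], sv_index = sv, sv = X[sv, , drop = FALSE],
                 b = fit$b, gamma = gamma, epsilon = epsilon, lambda = lambda,
                 C = 1 / lambda, n_sv = length(sv), p = ncol(X),
                 iterations = fit$iterations, gap = fit$gap),
            class = "gait_svr")
}

#' @export
predict.gait_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("feature dimension mismatch: model expects ", object$p,
         " columns, got ", ncol(newdata))
  }
  if (object$n_sv == 0L) return(rep(object$b, nrow(newdata)))
  as.numeric(rbf_kernel(newdata, object$sv, object$gamma) %*% object$beta) + object$b
}
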