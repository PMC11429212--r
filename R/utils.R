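# Shared numerical helpers.

#' Draw from a multivariate normal distribution
#'
#' Deterministic given the RNG state; uses the upper Cholesky factor of a
#' (possibly semi-definite) covariance matrix, falling back to an
#' eigendecomposition square root when the Cholesky fails.
#'
#' @param n number of draws.
#' @param sigma covariance matrix (symmetric PSD).
#' @return `n` x `ncol(sigma)` matrix of draws.
#' @keywords internal
rmvn <- function(n, sigma) {
  d <- ncol(sigma)
  if (d == 0L) return(matrix(0, n, 0))
  if (all(sigma == 0)) return(matrix(0, n, d))
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    es <- eigen(sigma, symmetric = TRUE)
    ev <- pmax(es$values, 0)
    R <- t(es$vectors %*% (t(es$vectors) * sqrt(ev)))
  }
  matrix(rnorm(n * d), n, d) %*% R
}

#' Check a matrix is symmetric positive semi-definite
#' @param m matrix.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @keywords internal
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] >= -tol * max(abs(ev[1]), 1)
}

#' Project a symmetric matrix onto the PSD cone
#' @keywords internal
psd_project <- function(m, floor = 0) {
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  ev <- pmax(es$values, floor)
  out <- es$vectors %*% (t(es$vectors) * ev)
  (out + t(out)) / 2
}

#' Derive a stage seed from a master seed
#'
#' Named-stream scheme: the stage name is hashed (polynomial rolling hash of
#' the UTF-8 bytes) and combined with the master seed modulo 2^31 - 1, so that
#' adding a stage never perturbs the streams of existing stages.
#'
#' @param master master seed (integer).
#' @param stage stage name (character scalar).
#' @return integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' derive_seed(42, "simulate")
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  bytes <- utf8ToInt(stage)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(master) %% 2147483647 * 92821) %% 2147483646 + 1)
}

# Correlation matrix from a covariance matrix, guarding zero variances.
cov2cor_safe <- function(m) {
  s <- sqrt(diag(m))
  s[s == 0] <- 1
  m / tcrossprod(s)
}
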