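# Multilayer perceptron for breeding-value prediction: three hidden layers
# (sigmoid, tanh, tanh) and a GELU output unit, trained by RMSprop on a mean
# absolute error loss with L2 weight regularization.

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)
sigm <- function(x) 1 / (1 + exp(-x))

ann_forward <- function(model, X) {
  # X: n x p (centered); biases recycle down the sample dimension
  A0 <- t(X)
  S1 <- model$W[[1]] %*% A0 + as.numeric(model$B[[1]])
  A1 <- sigm(S1)
  S2 <- model$W[[2]] %*% A1 + as.numeric(model$B[[2]])
  A2 <- tanh(S2)
  S3 <- model$W[[3]] %*% A2 + as.numeric(model$B[[3]])
  A3 <- tanh(S3)
  S4 <- model$W[[4]] %*% A3 + as.numeric(model$B[[4]])
  A4 <- gelu(S4)
  list(A0 = A0, S1 = S1, A1 = A1, S2 = S2, A2 = A2, S3 = S3, A3 = A3,
       S4 = S4, out = as.numeric(A4))
}

#' Fit the multilayer perceptron EBV predictor
#'
#' Architecture 4-6-4-1 by default: sigmoid, tanh, tanh hidden activations
#' and a GELU output (`x * Phi(x)` with the exact Gaussian CDF).  The loss is
#' the mean absolute error plus `lambda * ||W||^2` over the weights (biases
#' unpenalized); optimization is RMSprop (decay 0.9) with mini-batches of
#' `floor(n/2)` records for 100 epochs by default.  Weights start from
#' fan-in-scaled uniform values, deterministic given `seed`.
#'
#' @param X centered feature matrix (n x p).
#' @param y target EBV vector (from the multi-trait model).
#' @param alpha learning rate (default 0.1).
#' @param lambda L2 penalty on weights (default 0.001).
#' @param epochs training epochs (default 100).
#' @param batch_frac mini-batch fraction of n (default 0.5).
#' @param hidden hidden layer sizes (default `c(4, 6, 4)`).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return object of class `gait_ann` with weights, biases, hyperparameters
#'   and the per-epoch `loss_history` (MAE + penalty on the full data).
#' @export
ann_fit <- function(X, y, alpha = 0.1, lambda = 0.001, epochs = 100L,
                    batch_frac = 0.5, hidden = c(4L, 6L, 4L), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L)
  set.seed(seed)
  sizes <- c(p, hidden, 1L)
  W <- B <- cache_W <- cache_B <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    s <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l + 1L] * sizes[l], -s, s), sizes[l + 1L], sizes[l])
    B[[l]] <- matrix(0, sizes[l + 1L], 1L)
    cache_W[[l]] <- W[[l]] * 0
    cache_B[[l]] <- B[[l]] * 0
  }
  model <- list(W = W, B = B)
  rho <- 0.9; eps <- 1e-8
  bs <- max(1L, floor(n * batch_frac))
  loss_history <- numeric(epochs)
  full_loss <- function(model) {
    out <- ann_forward(model, X)$out
    mean(abs(out - y)) + lambda * sum(vapply(model$W, function(w) sum(w^2), 0))
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    for (st in starts) {
      idx <- ord[st:min(st + bs - 1L, n)]
      m <- length(idx)
      fw <- ann_forward(model, X[idx, , drop = FALSE])
      # MAE gradient wrt output
      dout <- matrix(sign(fw$out - y[idx]) / m, 1L, m)
      d4 <- dout * gelu_grad(fw$S4)
      d3 <- (t(model$W[[4]]) %*% d4) * (1 - fw$A3^2)
      d2 <- (t(model$W[[3]]) %*% d3) * (1 - fw$A2^2)
      d1 <- (t(model$W[[2]]) %*% d2) * (fw$A1 * (1 - fw$A1))
      grads_W <- list(d1 %*% t(fw$A0), d2 %*% t(fw$A1),
                      d3 %*% t(fw$A2), d4 %*% t(fw$A3))
      grads_B <- list(rowSums(d1), rowSums(d2), rowSums(d3), rowSums(d4))
      for (l in 1:4) {
        gW <- grads_W[[l]] + 2 * lambda * model$W[[l]]
        gB <- grads_B[[l]]
        cache_W[[l]] <- rho * cache_W[[l]] + (1 - rho) * gW^2
        cache_B[[l]] <- rho * cache_B[[l]] + (1 - rho) * gB^2
        model$W[[l]] <- model$W[[l]] - alpha * gW / (sqrt(cache_W[[l]]) + eps)
        model$B[[l]] <- model$B[[l]] - alpha * gB / (sqrt(cache_B[[l]]) + eps)
      }
    }
    loss_history[ep] <- full_loss(model)
    if (!is.finite(loss_history[ep])) {
      stop("ANN training produced a non-finite loss at epoch ", ep)
    }
  }
  structure(list(W = model$W, B = model$B, hidden = hidden, p = p,
                 alpha = alpha, lambda = lambda, epochs = epochs,
                 batch_size = bs, seed = seed, loss_history = loss_history),
            class = "gait_ann")
}

#' @export
predict.gait_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("feature dimension mismatch: model expects ", object$p,
         " columns, got ", ncol(newdata))
  }
  ann_forward(object, newdata)$out
}
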