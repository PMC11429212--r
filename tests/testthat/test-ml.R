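toy_regression <- function(n = 120, p = 6, seed = 1, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(sin(X[, 1]) + 0.5 * X[, 2] - 0.3 * X[, 3]^2 +
                    rnorm(n, 0, noise))
  list(X = X, y = y)
}

test_that("the ANN forward pass matches a hand-computed activation chain", {
  W <- list(matrix(c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6, 0.7, -0.8), 4, 2,
                   byrow = TRUE),
            matrix(seq(-0.6, 0.5, length.out = 24), 6, 4),
            matrix(seq(0.3, -0.4, length.out = 24), 4, 6),
            matrix(c(0.2, -0.3, 0.4, 0.5), 1, 4))
  B <- list(matrix(0.01, 4, 1), matrix(-0.02, 6, 1), matrix(0.03, 4, 1),
            matrix(0.1, 1, 1))
  m <- list(W = W, B = B)
  x <- c(0.5, -1.2)
  z1 <- 1 / (1 + exp(-(W[[1]] %*% x + 0.01)))
  z2 <- tanh(W[[2]] %*% z1 - 0.02)
  z3 <- tanh(W[[3]] %*% z2 + 0.03)
  s4 <- as.numeric(W[[4]] %*% z3 + 0.1)
  hand <- s4 * pnorm(s4)
  expect_equal(gaitbv:::ann_forward(m, matrix(x, 1, 2))$out, hand,
               tolerance = 1e-10)

  # zero weights and biases: output is exactly zero (GELU(0) = 0)
  m0 <- list(W = lapply(W, function(w) w * 0), B = lapply(B, function(b) b * 0))
  expect_equal(gaitbv:::ann_forward(m0, matrix(rnorm(10), 5, 2))$out, rep(0, 5))
})

test_that("ANN training reduces the loss and predicts deterministically", {
  d <- toy_regression(n = 150, seed = 3)
  fit <- ann_fit(d$X, d$y, epochs = 40, seed = 5)
  expect_true(all(is.finite(fit$loss_history)))
  # RMSprop at the tuned learning rate oscillates epoch to epoch; training
  # must still find a clearly better model than the initial one and stay
  # bounded at the end
  expect_lt(min(fit$loss_history), fit$loss_history[1])
  expect_lt(mean(tail(fit$loss_history, 5)), 2 * min(fit$loss_history) + 0.05)
  fit2 <- ann_fit(d$X, d$y, epochs = 40, seed = 5)
  expect_identical(predict(fit, d$X), predict(fit2, d$X))
  expect_error(predict(fit, d$X[, 1:3]), "dimension mismatch")
})

test_that("SVR matches a reference implementation and satisfies KKT", {
  skip_if_not_installed("e1071")
  set.seed(42)
  n <- 20; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(sin(X[, 1]) + 0.3 * X[, 2] + rnorm(n, 0, 0.1))
  fit <- svr_fit(X, y, epsilon = 0.1, lambda = 1, gamma = 0.5, tol = 1e-8)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    gamma = 0.5, cost = 1, epsilon = 0.1, scale = FALSE,
                    tolerance = 1e-8)
  Xn <- matrix(rnorm(40 * p), 40, p)
  expect_lt(max(abs(predict(fit, Xn) - predict(ref, Xn))), 1e-4)

  # KKT structure: |beta| <= C; strictly inside-tube points have beta = 0
  beta_full <- numeric(n); beta_full[fit$sv_index] <- fit$beta
  expect_true(all(abs(beta_full) <= fit$C + 1e-10))
  res <- predict(fit, X) - y
  inside <- abs(res) < fit$epsilon - 1e-6
  expect_true(all(beta_full[inside] == 0))

  # constant target: all points inside the tube, prediction == constant
  fc <- svr_fit(X, rep(2.5, n), epsilon = 0.1, lambda = 1, gamma = 0.5)
  expect_equal(fc$n_sv, 0L)
  expect_equal(predict(fc, Xn), rep(2.5, 40))

  # with a huge box (tiny lambda) a training point is fit within epsilon
  fl <- svr_fit(X, y, epsilon = 0.05, lambda = 1e-6, gamma = 0.5, tol = 1e-8)
  expect_true(all(abs(predict(fl, X) - y) <= 0.05 + 1e-4))
})

test_that("random forest behaves like bagged variance-reduction trees", {
  d <- toy_regression(n = 200, seed = 7)
  rf <- rfr_fit(d$X, d$y, k = 100, m = 2, n_min = 5, seed = 11)
  pr <- predict(rf, d$X)
  # averages of leaf means stay inside the training target range
  expect_true(all(pr >= min(d$y) & pr <= max(d$y)))

  # constant target: constant prediction
  rfc <- rfr_fit(d$X, rep(3.5, 200), k = 20, seed = 1)
  expect_equal(predict(rfc, d$X), rep(3.5, 200))

  # a single no-split tree predicts the bootstrap mean everywhere: with
  # n_min = n no split is possible
  rf1 <- rfr_fit(d$X, d$y, k = 1, n_min = 200, seed = 2)
  expect_equal(length(unique(predict(rf1, d$X))), 1L)

  # determinism
  rf2 <- rfr_fit(d$X, d$y, k = 100, m = 2, n_min = 5, seed = 11)
  expect_identical(predict(rf, d$X), predict(rf2, d$X))
})

test_that("random forest OOB error is close to the reference implementation", {
  skip_if_not_installed("randomForest")
  d <- toy_regression(n = 250, seed = 9, noise = 0.3)
  rf <- rfr_fit(d$X, d$y, k = 300, m = 2, n_min = 5, seed = 4)
  set.seed(4)
  ref <- randomForest::randomForest(d$X, d$y, ntree = 300, mtry = 2,
                                    nodesize = 5)
  ref_oob <- mean((ref$predicted - d$y)^2)
  expect_lt(abs(rf$oob_mse - ref_oob) / ref_oob, 0.20)
})

test_that("grid search returns the cross-validated argmin deterministically", {
  d <- toy_regression(n = 80, seed = 13)
  expect_error(grid_search("rfr", d$X, d$y, data.frame()), "empty")

  g1 <- grid_search("rfr", d$X, d$y, list(m = 2, n_min = 5, k = 25), folds = 3)
  expect_equal(g1$best$m, 2)

  # an absurd candidate (stumps on one feature) must lose to a sensible one
  g2 <- grid_search("rfr", d$X, d$y,
                    data.frame(m = c(2, 1), n_min = c(5, 80), k = c(50, 2)),
                    folds = 3, seed = 2)
  expect_equal(g2$best$n_min, 5)
  expect_equal(nrow(g2$scores), 2L)

  g3 <- grid_search("svr", d$X, d$y,
                    expand.grid(epsilon = c(0.05, 0.2), gamma = c(0.1, 1)),
                    folds = 3, seed = 5)
  g4 <- grid_search("svr", d$X, d$y,
                    expand.grid(epsilon = c(0.05, 0.2), gamma = c(0.1, 1)),
                    folds = 3, seed = 5)
  expect_identical(g3$best, g4$best)
  expect_identical(g3$scores$score, g4$scores$score)
})
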