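# Random forest regression: bagging plus random feature subsets at each
# split, trees grown by best variance reduction, prediction by tree average.

#' Fit a random forest EBV predictor
#'
#' Grows `k` regression trees, each on a bootstrap sample of the rows; at
#' every node the best variance-reduction split is chosen among `m` randomly
#' drawn features, and nodes with at most `n_min` rows are not split further.
#' The prediction is the average over trees.  Defaults follow the tuned
#' gait-score configuration: 200 trees, `m = ceiling(0.3 p)`, `n_min = 5`.
#'
#' @param X centered feature matrix (n x p).
#' @param y target EBV vector.
#' @param k number of trees (default 200).
#' @param m features tried per split (default `ceiling(0.3 * ncol(X))`).
#' @param n_min node size below which splitting stops (default 5).
#' @param seed RNG seed; per-tree streams are derived from it, so a forest is
#'   reproducible and tree b is identical regardless of k.
#' @return object of class `gait_rf` with the trees, out-of-bag predictions
#'   (`oob_pred`, NA where a row was never out of bag) and `oob_mse`.
#' @export
rfr_fit <- function(X, y, k = 200L, m = NULL, n_min = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p == 0L) stop("feature matrix has zero columns")
  stopifnot(length(y) == n)
  if (is.null(m)) m <- ceiling(0.3 * p)
  m <- max(1L, min(as.integer(m), p))
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, k)
  fit <- rf_fit_cpp(X, as.numeric(y), as.integer(k), m, as.integer(n_min),
                    tree_seeds)
  pred <- rf_predict_cpp(fit$trees, X)
  oob <- fit$inbag == 0L
  oob_pred <- rowSums(pred * oob) / pmax(rowSums(oob), 1L)
  oob_pred[rowSums(oob) == 0L] <- NA_real_
  ok <- !is.na(oob_pred)
  structure(list(trees = fit$trees, k = as.integer(k), m = m,
                 n_min = as.integer(n_min), p = p, seed = seed,
                 oob_pred = oob_pred,
                 oob_mse = mean((oob_pred[ok] - y[ok])^2),
                 y_range = range(y)),
            class = "gait_rf")
}

#' @export
predict.gait_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("feature dimension mismatch: model expects ", object$p,
         " columns, got ", ncol(newdata))
  }
  rowMeans(rf_predict_cpp(object$trees, newdata))
}
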