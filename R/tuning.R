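# Cross-validated grid search over model hyperparameters.

#' Grid search with k-fold cross-validation
#'
#' Scores every hyperparameter combination by cross-validated mean absolute
#' error (ANN) or mean squared error (SVR, RFR) and returns the argmin.  Fold
#' assignment is seeded and shared across candidates.
#'
#' @param family `"ann"`, `"svr"` or `"rfr"`.
#' @param X centered feature matrix.
#' @param y target vector.
#' @param grid data frame (or list of vectors, expanded to the full grid) of
#'   candidate hyperparameters; column names must match the fitting function
#'   arguments (e.g. `alpha`, `lambda` for ANN; `epsilon`, `lambda`, `gamma`
#'   for SVR; `m`, `n_min` for RFR).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment and model fits.
#' @return list with `best` (row of `grid`), `scores` (grid plus a `score`
#'   column), and `metric`.
#' @export
grid_search <- function(family = c("ann", "svr", "rfr"), X, y, grid,
                        folds = 5L, seed = 1L) {
  family <- match.arg(family)
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  metric <- if (family == "ann") "mae" else "mse"
  fit_one <- function(par, Xtr, ytr) {
    args <- c(list(Xtr, ytr), as.list(par), list(seed = seed))
    if (family == "svr") args$seed <- NULL
    do.call(switch(family, ann = ann_fit, svr = svr_fit, rfr = rfr_fit), args)
  }
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    err <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- fit_one(grid[g, , drop = FALSE], X[tr, , drop = FALSE], y[tr])
      pred <- predict(model, X[!tr, , drop = FALSE])
      err <- err + if (metric == "mae") sum(abs(pred - y[!tr])) else sum((pred - y[!tr])^2)
    }
    err / n
  }, 0)
  best <- which.min(scores)
  list(best = grid[best, , drop = FALSE],
       scores = cbind(grid, score = scores), metric = metric)
}
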