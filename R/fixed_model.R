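# Fixed-effect stage: contemporary groups, data cleaning for variance
# component estimation, ordinary least squares (minimum-norm), and adjusted
# phenotypes.

#' Attach contemporary-group labels
#'
#' The contemporary group of a record is the concatenation of birth year, sex
#' and registration year.
#'
#' @param tab phenotype table.
#' @return the table with a `cg` column added; level counts per trait are
#'   attached as attribute `cg_report`.
#' @export
build_contemporary_groups <- function(tab) {
  need <- c("birth_year", "sex", "reg_year")
  for (f in need) {
    bad <- which(is.na(tab[[f]]))
    if (length(bad)) {
      stop("missing ", f, " in row(s): ", paste(head(bad, 10L), collapse = ", "))
    }
  }
  tab$cg <- paste(tab$birth_year, tab$sex, tab$reg_year, sep = "_")
  traits <- intersect(gait_traits, names(tab))
  rep_ <- vapply(traits, function(tr) length(unique(tab$cg[!is.na(tab[[tr]])])), 0L)
  attr(tab, "cg_report") <- rep_
  tab
}

#' Clean a phenotype table for variance component estimation
#'
#' Per trait independently: (1) records deviating by more than `sd_limit`
#' standard deviations from the raw trait mean are dropped; (2) contemporary
#' groups and studs with fewer than `min_records` remaining records for that
#' trait, or with no within-level variation, are dropped; step (2) is
#' iterated until stable.  A "dropped" score is set missing; records with all
#' traits missing are removed.  Cleaning is idempotent.
#'
#' @param tab phenotype table with `cg` labels (see
#'   [build_contemporary_groups()]).
#' @param sd_limit outlier threshold in phenotypic SDs (default 3).
#' @param min_records minimum records per CG/stud level (default 5).
#' @return cleaned table; per-trait removal counts in attribute
#'   `clean_report`.
#' @export
clean_for_reml <- function(tab, sd_limit = 3, min_records = 5L) {
  if (is.null(tab$cg)) tab <- build_contemporary_groups(tab)
  traits <- intersect(gait_traits, names(tab))
  report <- matrix(0L, length(traits), 3L,
                   dimnames = list(traits, c("outlier", "small_level", "kept")))
  for (tr in traits) {
    y <- tab[[tr]]
    m <- mean(y, na.rm = TRUE); s <- sd(y, na.rm = TRUE)
    out <- !is.na(y) & abs(y - m) > sd_limit * s
    y[out] <- NA_real_
    report[tr, "outlier"] <- sum(out)
    repeat {
      drop <- rep(FALSE, length(y))
      for (lv in list(tab$cg, tab$stud_id)) {
        ok <- !is.na(y)
        cnt <- table(lv[ok])
        vr <- tapply(y[ok], lv[ok], function(v) if (length(v) > 1) var(v) else 0)
        bad <- names(cnt)[cnt < min_records | vr[names(cnt)] <= 0]
        drop <- drop | (ok & lv %in% bad)
      }
      if (!any(drop)) break
      report[tr, "small_level"] <- report[tr, "small_level"] + sum(drop)
      y[drop] <- NA_real_
    }
    report[tr, "kept"] <- sum(!is.na(y))
    tab[[tr]] <- y
  }
  keep <- rowSums(!is.na(as.matrix(tab[traits]))) > 0L
  if (!any(keep)) stop("cleaning removed every record")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clean_report") <- report
  attr(out, "truth") <- NULL
  out
}

#' Build the fixed-effects design matrix
#'
#' Columns: intercept, age (months), age squared (raw scale, not centered),
#' one indicator per contemporary group, one indicator per stud.  The CG and
#' stud blocks each sum to one within a record, so the design is deliberately
#' rank-deficient; the solver handles that.
#'
#' @param tab phenotype table with `cg` labels.
#' @return list with sparse matrix `X`, `col_map` (effect name -> column
#'   indices), and the level keys for CG and stud.
#' @export
build_design <- function(tab) {
  if (is.null(tab$cg)) tab <- build_contemporary_groups(tab)
  n <- nrow(tab)
  cg <- factor(tab$cg)
  st <- factor(tab$stud_id)
  ncg <- nlevels(cg); nst <- nlevels(st)
  X <- cbind(
    Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1, dims = c(n, 1L)),
    Matrix::Matrix(tab$age, n, 1L, sparse = TRUE),
    Matrix::Matrix(tab$age^2, n, 1L, sparse = TRUE),
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cg), x = 1, dims = c(n, ncg)),
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(st), x = 1, dims = c(n, nst))
  )
  col_map <- list(mu = 1L, age_linear = 2L, age_quadratic = 3L,
                  cg = 3L + seq_len(ncg), stud = 3L + ncg + seq_len(nst))
  colnames(X) <- c("mu", "age", "age2", paste0("cg:", levels(cg)),
                   paste0("stud:", levels(st)))
  list(X = X, col_map = col_map, cg_levels = levels(cg), stud_levels = levels(st))
}

#' Minimum-norm ordinary least squares
#'
#' Solves the normal equations `X'X theta = X'y` by the Moore-Penrose
#' pseudoinverse of `X'X` (eigendecomposition with a relative tolerance), so
#' rank-deficient designs get the minimum-norm solution.  Fitted values
#' `X theta` are invariant to the choice of generalized inverse, which is
#' what the downstream stages consume.  Rows with missing `y` are ignored.
#'
#' @param X design matrix (dense or sparse) or the list from
#'   [build_design()].
#' @param y response vector (NAs allowed).
#' @param tol relative eigenvalue tolerance defining the effective rank.
#' @return list with `theta`, `rank`, `fitted` (NA where `y` was NA),
#'   `residuals`, and `n_used`.
#' @export
solve_ols <- function(X, y, tol = 1e-10) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  obs <- which(!is.na(y))
  if (!length(obs)) stop("no observed responses")
  Xo <- X[obs, , drop = FALSE]
  XtX <- as.matrix(Matrix::crossprod(Xo))
  Xty <- as.numeric(Matrix::crossprod(Xo, y[obs]))
  es <- eigen(XtX, symmetric = TRUE)
  thr <- tol * max(es$values)
  pos <- es$values > thr
  theta <- es$vectors[, pos, drop = FALSE] %*%
    ((t(es$vectors[, pos, drop = FALSE]) %*% Xty) / es$values[pos])
  theta <- as.numeric(theta)
  names(theta) <- colnames(X)
  fit <- rep(NA_real_, length(y))
  fit[obs] <- as.numeric(Xo %*% theta)
  list(theta = theta, rank = sum(pos), fitted = fit,
       residuals = y - fit, n_used = length(obs))
}

#' Adjusted phenotypes
#'
#' `e_hat = y - X theta_hat`: the phenotype with all fixed effects removed.
#'
#' @param y response vector (NAs allowed).
#' @param X design matrix.
#' @param theta fixed-effect solutions.
#' @return vector of adjusted phenotypes (NA where `y` is NA), with the mean
#'   of the observed entries as attribute `mean_adjusted`.
#' @export
adjust_phenotypes <- function(y, X, theta) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  e <- y - as.numeric(X %*% theta)
  structure(e, mean_adjusted = mean(e, na.rm = TRUE))
}

#' Fit the OLS stage for every trait
#'
#' For each trait: minimum-norm OLS on the records observing it, adjusted
#' phenotypes, and the per-effect components of `X theta_hat` (CG, stud,
#' age-linear, age-quadratic) that feed the machine-learning feature matrix.
#'
#' @param tab phenotype table.
#' @return list of class `gait_ols` with `adjusted` (record x trait matrix),
#'   `components` (list per trait: record x 4 matrix), `theta` (list),
#'   `design`, `rank` (per trait).
#' @export
ols_stage <- function(tab) {
  tab <- build_contemporary_groups(tab)
  des <- build_design(tab)
  traits <- intersect(gait_traits, names(tab))
  n <- nrow(tab)
  adjusted <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  components <- list()
  theta <- list()
  rank <- integer(0)
  comp_names <- c("cg", "stud", "age_linear", "age_quadratic")
  for (tr in traits) {
    y <- tab[[tr]]
    fit <- solve_ols(des$X, y)
    theta[[tr]] <- fit$theta
    rank[tr] <- fit$rank
    adjusted[, tr] <- y - as.numeric(des$X %*% fit$theta)
    cm <- matrix(0, n, length(comp_names), dimnames = list(NULL, comp_names))
    for (cn in comp_names) {
      cols <- des$col_map[[cn]]
      cm[, cn] <- as.numeric(des$X[, cols, drop = FALSE] %*% fit$theta[cols])
    }
    components[[tr]] <- cm
  }
  structure(list(adjusted = adjusted, components = components, theta = theta,
                 design = des, rank = rank, tab = tab),
            class = "gait_ols")
}
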