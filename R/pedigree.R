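# Pedigree handling: validation, topological sorting, inbreeding, the
# numerator relationship matrix A and its leading eigenvectors, A-inverse by
# Henderson's rules, and generation-based truncation.

#' Construct a pedigree object
#'
#' A pedigree is a data frame of animal records (`id`, `sire`, `dam`,
#' `birth_year`, `sex`) with unknown parents coded 0.  The constructor inserts
#' phantom founder records for parents that never appear as animals, checks
#' for duplicate ids and cycles, and sorts the records topologically so that
#' parents always precede their offspring — the order assumed by every
#' downstream algorithm.
#'
#' @param df data frame with columns `id`, `sire`, `dam`, `birth_year`, `sex`
#'   (`"M"`/`"F"`); 0 codes an unknown parent.
#' @return An object of class `gait_pedigree`: the sorted data frame with
#'   integer columns `si`/`di` (positional parent indices, 0 = unknown) and an
#'   attribute `phantom_founders` listing inserted ids.
#' @export
pedigree <- function(df) {
  need <- c("id", "sire", "dam", "birth_year", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$id <- as.integer(df$id)
  df$sire <- as.integer(df$sire)
  df$dam <- as.integer(df$dam)
  if (anyNA(df$id) || any(df$id <= 0)) stop("animal ids must be positive integers")
  if (anyDuplicated(df$id)) {
    stop("duplicate animal id(s): ",
         paste(head(unique(df$id[duplicated(df$id)]), 5L), collapse = ", "))
  }
  df$sex <- as.character(df$sex)

  parents <- setdiff(unique(c(df$sire, df$dam)), c(0L, df$id))
  if (length(parents)) {
    phantom <- data.frame(id = parents, sire = 0L, dam = 0L,
                          birth_year = min(df$birth_year, na.rm = TRUE) - 1L,
                          sex = NA_character_)
    df <- rbind(df, phantom)
  }

  n <- nrow(df)
  idx <- match(df$id, df$id)  # identity; used below after reorder
  si <- match(df$sire, df$id, nomatch = 0L)
  di <- match(df$dam, df$id, nomatch = 0L)

  # Kahn topological sort (parents before offspring); detects cycles.
  nchild <- tabulate(c(si[si > 0L], di[di > 0L]), nbins = n)
  npar <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  ord <- integer(n)
  deg <- npar
  queue <- which(deg == 0L)
  # child lists
  ci <- c(which(si > 0L), which(di > 0L))
  pi_ <- c(si[si > 0L], di[di > 0L])
  children <- split(ci, factor(pi_, levels = seq_len(n)))
  k <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    k <- k + 1L
    ord[k] <- v
    for (w in children[[v]]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) {
    bad <- df$id[which(deg > 0L)[1L]]
    stop("pedigree contains a cycle involving animal ", bad)
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$si <- match(df$sire, df$id, nomatch = 0L)
  df$di <- match(df$dam, df$id, nomatch = 0L)
  structure(df, class = c("gait_pedigree", "data.frame"),
            phantom_founders = as.integer(parents))
}

#' Read a pedigree CSV
#'
#' Expects columns `animal,sire,dam,birth_year,sex` with 0 for unknown
#' parents.  Parents referenced but never listed as animals are inserted as
#' phantom founders (birth year one before the earliest year in the file) and
#' reported in the `phantom_founders` attribute.
#'
#' @param path CSV file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  nm[nm == "animal"] <- "id"
  names(df) <- nm
  pedigree(df)
}

#' Write a pedigree to CSV
#' @param ped pedigree object.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[c("id", "sire", "dam", "birth_year", "sex")]
  names(out)[1] <- "animal"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Inbreeding coefficients and Mendelian sampling variances
#'
#' Computes per-animal inbreeding F by the Meuwissen–Luo recursion (ancestor
#' traversal per animal, O(total ancestors) memory) together with the
#' Mendelian sampling variance scale
#' `d_i = 0.5 - 0.25 (F_sire + F_dam)` (with `F = -1` substituted for an
#' unknown parent, so founders get `d = 1` and a single known parent gives
#' `0.75 - 0.25 F`).
#'
#' @param ped pedigree object.
#' @return numeric vector of F, with the `d` vector and `log(det(A)) =
#'   sum(log(d))` attached as attributes `d` and `logdetA`.
#' @export
compute_inbreeding <- function(ped) {
  res <- ml_inbreeding(ped$si, ped$di)
  structure(res$F, d = res$d, logdetA = sum(log(res$d)), names = as.character(ped$id))
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense A by the tabular recursion: processing animals in topological order,
#' `A[1:(i-1), i] = (A[, sire] + A[, dam]) / 2` (unknown-parent terms zero)
#' and `A[i, i] = 1 + 0.5 A[sire, dam]`.
#'
#' @param ped pedigree object.
#' @param dense_limit refuse pedigrees larger than this (dense storage).
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(ped, dense_limit = 20000L) {
  n <- nrow(ped)
  if (n > dense_limit) {
    stop("pedigree has ", n, " animals; dense A is limited to ", dense_limit,
         " — truncate the pedigree first (truncate_pedigree)")
  }
  A <- matrix(0, n, n)
  si <- ped$si; di <- ped$di
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0L) A[prev, s] else 0) + (if (d > 0L) A[prev, d] else 0))
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Submatrix of A for a subset of animals
#'
#' Computes `A[keep, keep]` without forming the full dense A, via the
#' factorization `A = T D T'` where `T` is the (sparse-inverse) gene-flow
#' matrix: rows of `T` are obtained by sparse triangular solves against
#' `I - P` (P = parent-average matrix).
#'
#' @param ped pedigree object.
#' @param ids animal ids to keep (order preserved).
#' @return dense `length(ids)` square matrix with dimnames = ids.
#' @export
A_submatrix <- function(ped, ids) {
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("unknown animal id(s): ", paste(head(ids[is.na(pos)]), collapse = ", "))
  n <- nrow(ped)
  Fv <- compute_inbreeding(ped)
  d <- attr(Fv, "d")
  ii <- c(which(ped$si > 0L), which(ped$di > 0L))
  jj <- c(ped$si[ped$si > 0L], ped$di[ped$di > 0L])
  Tinv <- Matrix::sparseMatrix(i = ii, j = jj, x = -0.5, dims = c(n, n)) +
    Matrix::Diagonal(n)
  Tinv <- methods::as(Tinv, "triangularMatrix")
  E <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1, dims = c(n, length(pos)))
  # columns of X are rows of T for the kept animals: T' e = solve(Tinv', e)
  X <- as.matrix(Matrix::solve(Matrix::t(Tinv), E))
  out <- crossprod(X * sqrt(d))
  dimnames(out) <- list(ids, ids)
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: per-animal contributions
#' `alpha = 1/d_i` to the (animal, animal), (animal, parent) and
#' (parent, parent) cells, with `d` from [compute_inbreeding()].  Never forms
#' dense A, so it scales to large pedigrees.
#'
#' @param ped pedigree object.
#' @return sparse symmetric `dsCMatrix`, with `logdetA` attribute.
#' @export
build_Ainv <- function(ped) {
  n <- nrow(ped)
  Fv <- compute_inbreeding(ped)
  d <- attr(Fv, "d")
  alpha <- 1 / d
  si <- ped$si; di <- ped$di
  I <- integer(0); J <- integer(0); X <- numeric(0)
  add <- function(i, j, x) {
    I <<- c(I, i); J <<- c(J, j); X <<- c(X, x)
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  hs <- si > 0L; hd <- di > 0L
  add(idx[hs], si[hs], -0.5 * alpha[hs])
  add(si[hs], idx[hs], -0.5 * alpha[hs])
  add(idx[hd], di[hd], -0.5 * alpha[hd])
  add(di[hd], idx[hd], -0.5 * alpha[hd])
  add(si[hs], si[hs], 0.25 * alpha[hs])
  add(di[hd], di[hd], 0.25 * alpha[hd])
  both <- hs & hd
  add(si[both], di[both], 0.25 * alpha[both])
  add(di[both], si[both], 0.25 * alpha[both])
  M <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n))
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  attr(M, "logdetA") <- sum(log(d))
  M
}

#' Leading eigenvectors of a relationship matrix
#'
#' Unit-norm eigenvectors of the `k` largest eigenvalues, ordered by
#' decreasing eigenvalue.  The sign of each vector is fixed so that its
#' largest-magnitude component is positive (first such component on ties),
#' making the feature columns reproducible.
#'
#' @param A dense symmetric relationship matrix.
#' @param k number of eigenvectors (default 10).
#' @return `n x k` matrix; eigenvalues attached as attribute `values`.
#' @export
top_eigenvectors <- function(A, k = 10L) {
  n <- nrow(A)
  if (k > n) stop("k = ", k, " exceeds matrix dimension ", n)
  es <- eigen(A, symmetric = TRUE)
  V <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(A)
  structure(V, values = es$values[seq_len(k)])
}

#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps the phenotyped animals plus their ancestors up to `generations`
#' generations back.  Depth is counted as the longest ancestor path from any
#' phenotyped descendant (a phenotyped animal that is itself an ancestor of
#' other phenotyped animals counts at its ancestral position), so no retained
#' animal has an ancestor path longer than `generations` within the output.
#' Parent links beyond the cut are severed, making the oldest retained
#' ancestors founders.  `generations = 0` keeps the phenotyped animals only,
#' all as founders.
#'
#' @param ped pedigree object.
#' @param phenotyped ids of phenotyped animals.
#' @param generations ancestral depth to retain (default 3).
#' @return truncated [pedigree()] object.
#' @export
truncate_pedigree <- function(ped, phenotyped, generations = 3L) {
  if (length(phenotyped) == 0L) stop("empty phenotyped set")
  pos <- match(unique(phenotyped), ped$id)
  if (anyNA(pos)) stop("phenotyped ids not in pedigree")
  n <- nrow(ped)
  # longest ancestor path from any phenotyped descendant; children are
  # processed before their parents (records are sorted parents-first)
  D <- rep(-1L, n)
  D[pos] <- 0L
  for (i in rev(seq_len(n))) {
    if (D[i] >= 0L && D[i] < generations) {
      s <- ped$si[i]; d <- ped$di[i]
      if (s > 0L) D[s] <- max(D[s], D[i] + 1L)
      if (d > 0L) D[d] <- max(D[d], D[i] + 1L)
    }
  }
  keep <- which(D >= 0L)
  out <- as.data.frame(ped)[keep, c("id", "sire", "dam", "birth_year", "sex")]
  # a parent link survives only if the child sits strictly inside the cut
  cut <- D[keep] >= generations
  out$sire[cut] <- 0L
  out$dam[cut] <- 0L
  kept_ids <- out$id
  out$sire[!(out$sire %in% kept_ids)] <- 0L
  out$dam[!(out$dam %in% kept_ids)] <- 0L
  pedigree(out)
}
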