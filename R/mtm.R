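# Multi-trait animal model: Henderson's mixed-model equations with animal and
# technician random effects, EM-REML variance components with exact trace
# terms from a sparse selected inverse (Takahashi equations) of the
# coefficient matrix, BLUP breeding values and theoretical accuracies.
#
# Equation layout: per-trait fixed-effect blocks first (each trait gets its
# own fixed design over the records observing it, with aliased columns
# dropped), then animal equations (traits nested within animal), then
# technician equations (traits within technician).  Residuals are handled per
# record by inverting the residual submatrix of the record's observed-trait
# pattern, so any missing-trait pattern is allowed.

logdet_chol <- function(m) 2 * sum(log(diag(chol(m))))

# ---- structure: everything that does not depend on the covariances --------

mme_structure <- function(tab, ped, traits = gait_traits) {
  tab <- build_contemporary_groups(tab)
  traits <- intersect(traits, names(tab))
  if (!length(traits)) stop("no trait columns found")
  Y <- as.matrix(tab[traits])
  keep <- rowSums(!is.na(Y)) > 0L
  tab <- tab[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  n_rec <- nrow(Y)
  TT <- length(traits)

  apos <- match(tab$animal, ped$id)
  if (anyNA(apos)) {
    stop("phenotyped animal(s) missing from pedigree: ",
         paste(head(tab$animal[is.na(apos)]), collapse = ", "))
  }
  techf <- factor(tab$technician_id)
  tpos <- as.integer(techf)
  ntech <- nlevels(techf)
  na <- nrow(ped)

  des <- build_design(tab)
  W0 <- des$X[, -1L, drop = FALSE]  # drop global intercept; CG spans it

  # per-trait fixed columns: observed-level columns, aliased ones dropped
  kept_cols <- vector("list", TT)
  for (i in seq_len(TT)) {
    obs <- which(!is.na(Y[, i]))
    Xi <- W0[obs, , drop = FALSE]
    nz <- which(Matrix::colSums(Xi != 0) > 0L)
    XtX <- as.matrix(Matrix::crossprod(Xi[, nz, drop = FALSE]))
    dsc <- 1 / sqrt(pmax(diag(XtX), 1e-300))
    XtXs <- XtX * tcrossprod(dsc)
    Q <- suppressWarnings(chol(XtXs, pivot = TRUE, tol = 1e-9))
    rk <- attr(Q, "rank")
    kept_cols[[i]] <- nz[sort(attr(Q, "pivot")[seq_len(rk)])]
  }
  nfix <- vapply(kept_cols, length, 0L)
  offf <- c(0L, cumsum(nfix))[seq_len(TT)]
  NF <- sum(nfix)
  neq <- NF + (na + ntech) * TT
  aeq <- function(a, i) NF + (a - 1L) * TT + i
  teq <- function(k, i) NF + na * TT + (k - 1L) * TT + i

  # observation rows: ordered by record then trait
  om <- !is.na(Y)
  obs_rec <- rep(seq_len(n_rec), times = rowSums(om))
  obs_tr <- unlist(apply(om, 1L, which, simplify = FALSE), use.names = FALSE)
  n_obs <- length(obs_rec)
  yobs <- Y[cbind(obs_rec, obs_tr)]

  # W_big triplets (obs row, equation column, value)
  ti <- tj <- integer(0); tx <- numeric(0)
  for (i in seq_len(TT)) {
    rows <- which(obs_tr == i)
    recs <- obs_rec[rows]
    Xi <- W0[recs, kept_cols[[i]], drop = FALSE]
    tr3 <- Matrix::summary(methods::as(Xi, "TsparseMatrix"))
    ti <- c(ti, rows[tr3$i])
    tj <- c(tj, offf[i] + tr3$j)
    tx <- c(tx, tr3$x)
  }
  ti <- c(ti, seq_len(n_obs), seq_len(n_obs))
  tj <- c(tj, aeq(apos[obs_rec], obs_tr), teq(tpos[obs_rec], obs_tr))
  tx <- c(tx, rep(1, 2L * n_obs))
  Wbig <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_obs, neq))

  # missing-trait patterns
  pat_key <- apply(om, 1L, function(r) paste(which(r), collapse = ","))
  pat_levels <- sort(unique(pat_key))
  pat_id <- match(pat_key, pat_levels)
  patterns <- lapply(strsplit(pat_levels, ","), as.integer)
  n_pat <- length(patterns)
  pat_n <- tabulate(pat_id, n_pat)

  # residual pair map: all ordered pairs of observed traits within a record
  first_obs <- c(1L, cumsum(rowSums(om)) + 1L)[seq_len(n_rec)]
  rw_i <- rw_j <- rw_flat <- integer(0)
  for (s in seq_len(n_pat)) {
    recs <- which(pat_id == s)
    m <- length(patterns[[s]])
    O <- outer(first_obs[recs], 0:(m - 1L), `+`)  # obs rows, one col per trait
    ii <- O[, rep(seq_len(m), times = m), drop = FALSE]
    jj <- O[, rep(seq_len(m), each = m), drop = FALSE]
    pti <- patterns[[s]][rep(seq_len(m), times = m)]
    ptj <- patterns[[s]][rep(seq_len(m), each = m)]
    rw_i <- c(rw_i, as.integer(ii))
    rw_j <- c(rw_j, as.integer(jj))
    rw_flat <- c(rw_flat, rep((s - 1L) * TT * TT + (pti - 1L) * TT + ptj,
                              each = length(recs)))
  }

  Ainv <- build_Ainv(ped)
  # full (both-triangle) triplets: the trace over the animal block runs over
  # every nonzero of A-inverse, not just the stored triangle
  Atrip <- Matrix::summary(methods::as(methods::as(Ainv, "generalMatrix"),
                                       "TsparseMatrix"))
  Fv <- compute_inbreeding(ped)

  list(tab = tab, Y = Y, traits = traits, n_rec = n_rec, TT = TT,
       apos = apos, tpos = tpos, ntech = ntech, na = na, NF = NF, neq = neq,
       nfix = nfix, offf = offf, kept_cols = kept_cols, W0 = W0,
       Wbig = Wbig, yobs = yobs, obs_rec = obs_rec, obs_tr = obs_tr,
       first_obs = first_obs, om = om,
       patterns = patterns, pat_id = pat_id, pat_n = pat_n, n_pat = n_pat,
       rw_i = rw_i, rw_j = rw_j, rw_flat = rw_flat,
       Ainv = Ainv, Atrip = Atrip, logdetA = attr(Ainv, "logdetA"),
       Fvec = as.numeric(Fv), tech_levels = levels(factor(tab$technician_id)),
       aeq = aeq, teq = teq)
}

# residual inverses per pattern, flattened for vectorized lookup
rinv_flat <- function(str, Se) {
  TT <- str$TT
  out <- numeric(str$n_pat * TT * TT)
  ld <- 0
  for (s in seq_len(str$n_pat)) {
    p <- str$patterns[[s]]
    Si <- solve(Se[p, p, drop = FALSE])
    M <- matrix(0, TT, TT)
    M[p, p] <- Si
    out[(s - 1L) * TT * TT + seq_len(TT * TT)] <- t(M)  # row-major (i-1)*T+j
    ld <- ld + str$pat_n[s] * logdet_chol(Se[p, p, drop = FALSE])
  }
  attr(out, "logdetR") <- ld
  out
}

assemble_mme <- function(str, cov, symbolic = FALSE) {
  TT <- str$TT
  if (symbolic) {
    rv <- rep(1, str$n_pat * TT * TT)
    Sui <- matrix(1, TT, TT); Sti <- matrix(1, TT, TT)
  } else {
    rv <- rinv_flat(str, cov$Se)
    Sui <- solve(cov$Su); Sti <- solve(cov$St)
  }
  Rw <- Matrix::sparseMatrix(i = str$rw_i, j = str$rw_j, x = rv[str$rw_flat],
                             dims = c(length(str$yobs), length(str$yobs)))
  RW <- Rw %*% str$Wbig
  Cdata <- Matrix::crossprod(str$Wbig, RW)
  Dkr <- Matrix::bdiag(
    Matrix::Matrix(0, str$NF, str$NF, sparse = TRUE),
    Matrix::kronecker(str$Ainv, Sui),
    Matrix::kronecker(Matrix::Diagonal(str$ntech), Sti))
  C <- Matrix::forceSymmetric(Cdata + Dkr, uplo = "L")
  if (symbolic) {
    # values are irrelevant (only the pattern is analysed), but CHOLMOD needs
    # a factorizable matrix: make it strictly diagonally dominant
    C <- C + Matrix::Diagonal(nrow(C), Matrix::rowSums(abs(C)) + 1)
  }
  rhs <- as.numeric(Matrix::crossprod(RW, str$yobs))
  yRy <- sum(str$yobs * as.numeric(Rw %*% str$yobs))
  list(C = C, rhs = rhs, yRy = yRy,
       logdetR = if (symbolic) NA_real_ else attr(rv, "logdetR"))
}

# ---- selected inverse maps ------------------------------------------------

# position of original-index pairs inside the factor pattern
factor_maps <- function(str, ch) {
  TT <- str$TT; NF <- str$NF; na <- str$na
  perm <- ch@perm + 1L
  invp <- integer(length(perm)); invp[perm] <- seq_along(perm)
  n <- length(perm)
  Lpos <- Matrix::sparseMatrix(i = ch@i + 1L, p = ch@p, x = seq_along(ch@i),
                               dims = c(n, n), index1 = TRUE)
  lookup <- function(r, c) {
    pr <- invp[r]; pc <- invp[c]
    sw <- pr < pc
    tmp <- pr[sw]; pr[sw] <- pc[sw]; pc[sw] <- tmp
    pos <- Lpos[cbind(pr, pc)]
    if (any(pos == 0)) stop("internal error: required inverse entry outside factor pattern")
    pos
  }
  # Tu map: all A-inverse triplets x all trait pairs
  At <- str$Atrip
  k <- At$i; l <- At$j; av <- At$x
  tu_pos <- vector("list", TT * TT)
  for (i in seq_len(TT)) for (j in seq_len(TT)) {
    if (i < j) next  # symmetric; fill later
    tu_pos[[(i - 1L) * TT + j]] <- lookup(NF + (k - 1L) * TT + i,
                                          NF + (l - 1L) * TT + j)
  }
  # Tt map: technician diagonal blocks
  tk <- seq_len(str$ntech)
  tt_pos <- vector("list", TT * TT)
  for (i in seq_len(TT)) for (j in seq_len(TT)) {
    if (i < j) next
    tt_pos[[(i - 1L) * TT + j]] <- lookup(NF + na * TT + (tk - 1L) * TT + i,
                                          NF + na * TT + (tk - 1L) * TT + j)
  }
  # residual trace map: per record, pairs of observed-trait equation entries
  Wt <- Matrix::summary(methods::as(str$Wbig, "TsparseMatrix"))
  ord <- order(Wt$i)
  wrow <- Wt$i[ord]; wcol <- Wt$j[ord]; wval <- Wt$x[ord]
  byrow <- split(seq_along(wrow), wrow)
  n_obs <- length(str$yobs)
  cnt <- lengths(byrow)
  zi <- zj <- integer(0); zc <- numeric(0); ztgt <- integer(0)
  # pairs of obs rows within a record (reuse rw map), expanded over entries
  e1 <- rep(seq_along(str$rw_i), cnt[str$rw_i] * cnt[str$rw_j])
  o1 <- str$rw_i[e1]; o2 <- str$rw_j[e1]
  # entry index expansion
  idx1 <- idx2 <- integer(length(e1))
  pos <- 1L
  for (q in seq_along(str$rw_i)) {
    a <- byrow[[str$rw_i[q]]]; b <- byrow[[str$rw_j[q]]]
    m <- length(a) * length(b)
    idx1[pos:(pos + m - 1L)] <- rep(a, times = length(b))
    idx2[pos:(pos + m - 1L)] <- rep(b, each = length(a))
    pos <- pos + m
  }
  zpos <- lookup(wcol[idx1], wcol[idx2])
  zcoef <- wval[idx1] * wval[idx2]
  ztarget <- str$rw_flat[e1]
  # diagonal (PEV) positions for animal equations
  dg <- matrix(0L, na, TT)
  for (i in seq_len(TT)) dg[, i] <- lookup(NF + (seq_len(na) - 1L) * TT + i,
                                           NF + (seq_len(na) - 1L) * TT + i)
  # diagonal positions of the factor itself (for logdet): first entry per column
  ddiag <- ch@p[seq_len(n)] + 1L
  list(tu_pos = tu_pos, tt_pos = tt_pos, av = av,
       zpos = zpos, zcoef = zcoef, ztarget = ztarget,
       pev_pos = dg, ddiag = ddiag)
}

trace_mats <- function(str, maps, z) {
  TT <- str$TT
  Tu <- Tt <- matrix(0, TT, TT)
  for (i in seq_len(TT)) for (j in seq_len(i)) {
    Tu[i, j] <- Tu[j, i] <- sum(maps$av * z[maps$tu_pos[[(i - 1L) * TT + j]]])
    Tt[i, j] <- Tt[j, i] <- sum(z[maps$tt_pos[[(i - 1L) * TT + j]]])
  }
  list(Tu = Tu, Tt = Tt)
}

# ---- public MME interface -------------------------------------------------

#' Build the mixed-model equations
#'
#' Henderson's MME for the multi-trait animal model with a random technician
#' effect: per-trait fixed blocks (age, age squared, contemporary groups,
#' studs; aliased columns dropped), `A^-1 (x) Su^-1` for the animal block and
#' `I (x) St^-1` for technicians, with per-record residual inverses following
#' each record's observed-trait pattern.
#'
#' @param tab phenotype table.
#' @param ped pedigree object (every phenotyped animal must appear).
#' @param cov list with covariance matrices `Su`, `St`, `Se` (trait subset
#'   taken automatically).
#' @param traits traits to include (default all five).
#' @return object of class `gait_mme`: coefficient matrix `C` (sparse
#'   symmetric), right-hand side `rhs`, and the internal structure.
#' @export
build_mme <- function(tab, ped, cov, traits = gait_traits) {
  traits <- intersect(traits, names(tab))
  str <- mme_structure(tab, ped, traits)
  covs <- lapply(cov[c("Su", "St", "Se")], function(m) {
    m <- as.matrix(m)
    if (!is.null(colnames(m))) m[traits, traits, drop = FALSE] else m
  })
  for (s in covs) if (any(!is.finite(as.matrix(solve(s))))) stop("singular covariance block")
  sys <- assemble_mme(str, covs)
  structure(list(C = sys$C, rhs = sys$rhs, yRy = sys$yRy, str = str, cov = covs),
            class = "gait_mme")
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky solve (default) or Jacobi-preconditioned conjugate
#' gradients.  Errors if the relative residual of the returned solution
#' exceeds `tol`.
#'
#' @param sys a `gait_mme` object from [build_mme()].
#' @param tol relative residual tolerance (default 1e-10).
#' @param method `"direct"` or `"cg"`.
#' @param max_iter CG iteration cap.
#' @return list with the full `solution` vector, the partitions `theta`
#'   (per-trait fixed), `u` (animals x traits), `t` (technicians x traits),
#'   and `rel_residual`.
#' @export
solve_mme <- function(sys, tol = 1e-10, method = c("direct", "cg"), max_iter = 10000L) {
  method <- match.arg(method)
  C <- sys$C; rhs <- sys$rhs; str <- sys$str
  if (method == "direct") {
    ch <- Matrix::Cholesky(C, LDL = TRUE, super = FALSE, perm = TRUE)
    x <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  } else {
    d <- Matrix::diag(C)
    x <- numeric(length(rhs))
    r <- rhs
    zv <- r / d
    p <- zv
    rz <- sum(r * zv)
    nrhs <- sqrt(sum(rhs^2))
    hist <- numeric(0)
    for (it in seq_len(max_iter)) {
      Ap <- as.numeric(C %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      res <- sqrt(sum(r^2)) / nrhs
      hist <- c(hist, res)
      if (res < tol) break
      zv <- r / d
      rz_new <- sum(r * zv)
      p <- zv + (rz_new / rz) * p
      rz <- rz_new
    }
    if (res >= tol) {
      stop("conjugate gradients did not converge; residual history tail: ",
           paste(signif(utils::tail(hist, 5L), 3), collapse = ", "))
    }
  }
  rel <- sqrt(sum((as.numeric(C %*% x) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (rel > max(tol, 1e-8)) stop("MME solution residual ", signif(rel, 3), " exceeds tolerance")
  TT <- str$TT
  u <- matrix(x[str$NF + seq_len(str$na * TT)], str$na, TT, byrow = TRUE)
  tte <- matrix(x[str$NF + str$na * TT + seq_len(str$ntech * TT)], str$ntech, TT,
                byrow = TRUE)
  theta <- lapply(seq_len(TT), function(i) x[str$offf[i] + seq_len(str$nfix[i])])
  names(theta) <- str$traits
  colnames(u) <- colnames(tte) <- str$traits
  list(solution = x, theta = theta, u = u, t = tte, rel_residual = rel)
}

# ---- EM-REML --------------------------------------------------------------

reml_loglik <- function(str, cov, sys = NULL, ch = NULL) {
  if (is.null(sys)) sys <- assemble_mme(str, cov)
  if (is.null(ch)) ch <- Matrix::Cholesky(sys$C, LDL = TRUE, super = FALSE, perm = TRUE)
  x <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
  ldC <- sum(log(ch@x[ch@p[seq_len(length(sys$rhs))] + 1L]))
  ldG <- str$TT * str$logdetA + str$na * logdet_chol(cov$Su) +
    str$ntech * logdet_chol(cov$St)
  yPy <- sys$yRy - sum(sys$rhs * x)
  -0.5 * (sys$logdetR + ldG + ldC + yPy)
}

#' EM-REML variance components for the multi-trait animal model
#'
#' Expectation-maximization REML: each iteration solves the MME at the
#' current covariances, computes the exact trace terms from the Takahashi
#' selected inverse of the coefficient matrix, and updates
#' `Su <- (U' A^-1 U + trace term)/n_animals`, `St <- (T'T + trace)/n_tech`,
#' and `Se` from per-record conditional expectations of the residual
#' cross-products (missing traits completed through the current residual
#' covariance).  The restricted log-likelihood is non-decreasing across
#' iterations; an optional Aitken-style extrapolation is attempted
#' periodically and only accepted when it does not decrease the restricted
#' log-likelihood.
#'
#' @param tab phenotype table (normally cleaned via [clean_for_reml()]).
#' @param ped pedigree (normally truncated via [truncate_pedigree()]).
#' @param init optional list(Su, St, Se) of starting values; default is one
#'   third of the phenotypic covariance each.
#' @param traits traits to analyse (1, 2 or all 5).
#' @param tol convergence threshold on the maximum relative parameter change
#'   (default 1e-6).  Convergence is also declared when the restricted
#'   log-likelihood gain falls below `1e-8 * (1 + |logL|)` on two
#'   consecutive EM steps (a likelihood plateau: the remaining parameter
#'   drift is then along an essentially flat ridge).
#' @param max_iter iteration cap (default 2000).
#' @param accelerate squared extrapolation (SQUAREM-style) every cycle of two
#'   EM steps, accepted only when it does not decrease the restricted
#'   log-likelihood (default TRUE).
#' @param verbose print progress every 25 iterations.
#' @return list of class `gait_reml`: `Su`, `St`, `Se`, `loglik` path,
#'   `iterations`, `converged`, `status`, and the parameter `trace` (matrix,
#'   one row per iteration).
#' @export
em_reml <- function(tab, ped, init = NULL, traits = gait_traits,
                    tol = 1e-6, max_iter = 2000L, accelerate = TRUE,
                    verbose = FALSE) {
  traits <- intersect(traits, names(tab))
  str <- mme_structure(tab, ped, traits)
  TT <- str$TT
  if (is.null(init)) {
    Sp <- cov(str$Y, use = "pairwise.complete.obs")
    Sp[is.na(Sp)] <- 0
    Sp <- psd_project(Sp, floor = 1e-6 * mean(diag(Sp)))
    init <- list(Su = Sp / 3, St = Sp / 3, Se = Sp / 3)
  }
  cov_ <- lapply(init, function(m) {
    m <- as.matrix(m)
    if (!is.null(colnames(m)) && all(traits %in% colnames(m))) m[traits, traits, drop = FALSE]
    else m
  })
  names(cov_) <- c("Su", "St", "Se")

  sym <- assemble_mme(str, cov_, symbolic = TRUE)
  ch <- Matrix::Cholesky(sym$C, LDL = TRUE, super = FALSE, perm = TRUE)
  maps <- factor_maps(str, ch)

  par_vec <- function(cv) c(cv$Su[lower.tri(cv$Su, diag = TRUE)],
                            cv$St[lower.tri(cv$St, diag = TRUE)],
                            cv$Se[lower.tri(cv$Se, diag = TRUE)])
  ll_path <- numeric(0)
  trace_par <- NULL
  prev_delta <- NULL
  prev_par <- par_vec(cov_)
  status <- "max_iter"
  N <- str$n_rec

  em_step <- function(cv) {
    sys <- assemble_mme(str, cv)
    ch <<- Matrix::update(ch, sys$C)
    x <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
    z <- takahashi_inverse(ch@p, ch@i, ch@x)
    ldC <- sum(log(ch@x[maps$ddiag]))
    ldG <- TT * str$logdetA + str$na * logdet_chol(cv$Su) +
      str$ntech * logdet_chol(cv$St)
    yPy <- sys$yRy - sum(sys$rhs * x)
    ll <- -0.5 * (sys$logdetR + ldG + ldC + yPy)

    U <- matrix(x[str$NF + seq_len(str$na * TT)], str$na, TT, byrow = TRUE)
    Tm <- matrix(x[str$NF + str$na * TT + seq_len(str$ntech * TT)], str$ntech, TT,
                 byrow = TRUE)
    tr <- trace_mats(str, maps, z)
    Su_new <- (as.matrix(Matrix::crossprod(U, str$Ainv %*% U)) + tr$Tu) / str$na
    St_new <- (crossprod(Tm) + tr$Tt) / str$ntech

    ehat <- str$yobs - as.numeric(str$Wbig %*% x)
    ee <- rowsum(ehat[str$rw_i] * ehat[str$rw_j], str$rw_flat, reorder = FALSE)
    vv <- rowsum(maps$zcoef * z[maps$zpos], maps$ztarget, reorder = FALSE)
    Eflat <- numeric(str$n_pat * TT * TT)
    Eflat[as.integer(rownames(ee))] <- ee[, 1L]
    Eflat[as.integer(rownames(vv))] <- Eflat[as.integer(rownames(vv))] + vv[, 1L]
    Se_new <- matrix(0, TT, TT)
    for (s in seq_len(str$n_pat)) {
      p <- str$patterns[[s]]
      m <- setdiff(seq_len(TT), p)
      Es <- matrix(Eflat[(s - 1L) * TT * TT + seq_len(TT * TT)], TT, TT, byrow = TRUE)
      Eo <- Es[p, p, drop = FALSE]
      full <- matrix(0, TT, TT)
      full[p, p] <- Eo
      if (length(m)) {
        B <- cv$Se[m, p, drop = FALSE] %*% solve(cv$Se[p, p, drop = FALSE])
        full[m, p] <- B %*% Eo
        full[p, m] <- t(full[m, p])
        full[m, m] <- str$pat_n[s] *
          (cv$Se[m, m, drop = FALSE] - B %*% cv$Se[p, m, drop = FALSE]) +
          B %*% Eo %*% t(B)
      }
      Se_new <- Se_new + full
    }
    Se_new <- Se_new / N
    guard <- function(m) {
      m <- (m + t(m)) / 2
      if (!is_psd(m)) m <- psd_project(m, floor = 1e-10 * mean(diag(m)))
      m
    }
    list(cov = list(Su = guard(Su_new), St = guard(St_new), Se = guard(Se_new)),
         ll = ll)
  }

  k <- TT * (TT + 1) / 2
  unpack <- function(v) {
    m <- matrix(0, TT, TT)
    m[lower.tri(m, diag = TRUE)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  unpack_all <- function(v) list(Su = unpack(v[seq_len(k)]),
                                 St = unpack(v[k + seq_len(k)]),
                                 Se = unpack(v[2 * k + seq_len(k)]))
  strictly_pd <- function(cv) {
    all(vapply(cv, function(m) is_psd(m, 1e-10) &&
                 min(eigen(m, TRUE, TRUE)$values) > 1e-12 * mean(diag(m)), TRUE))
  }

  it <- 0L
  rel <- Inf
  plateau <- 0L
  on_plateau <- function() {
    n <- length(ll_path)
    if (n < 2L) return(FALSE)
    gain <- ll_path[n] - ll_path[n - 1L]
    plateau <<- if (gain < 1e-8 * (1 + abs(ll_path[n]))) plateau + 1L else 0L
    plateau >= 2L
  }
  repeat {
    it <- it + 1L
    stp <- em_step(cov_)
    ll_path <- c(ll_path, stp$ll)
    p0 <- par_vec(cov_)
    p1 <- par_vec(stp$cov)
    rel <- max(abs(p1 - p0) / pmax(abs(p0), 1e-8))
    cov_ <- stp$cov
    trace_par <- rbind(trace_par, p1)
    if (verbose && it %% 25L == 0L) {
      message("iter ", it, "  logL ", signif(stp$ll, 8), "  max rel change ",
              signif(rel, 3))
    }
    if (rel < tol || on_plateau()) { status <- "converged"; break }
    if (it >= max_iter) break

    if (accelerate) {
      # squared extrapolation over a cycle of two EM maps, accepted only if
      # the restricted log-likelihood does not decrease
      it <- it + 1L
      stp2 <- em_step(cov_)       # ll at p1
      ll_path <- c(ll_path, stp2$ll)
      p2 <- par_vec(stp2$cov)
      rel <- max(abs(p2 - p1) / pmax(abs(p1), 1e-8))
      cov_ <- stp2$cov
      trace_par <- rbind(trace_par, p2)
      if (rel < tol || on_plateau()) { status <- "converged"; break }
      if (it >= max_iter) break
      r <- p1 - p0
      v <- (p2 - p1) - r
      nv <- sqrt(sum(v^2))
      if (nv > 0) {
        alpha <- max(-sqrt(sum(r^2)) / nv, -200)
        # backtrack toward -1 while the proposal leaves the PSD cone or
        # decreases the restricted log-likelihood
        while (alpha < -1.01) {
          prop <- p0 - 2 * alpha * r + alpha^2 * v
          cv_prop <- unpack_all(prop)
          if (strictly_pd(cv_prop)) {
            ll_prop <- tryCatch(reml_loglik(str, cv_prop), error = function(e) -Inf)
            if (ll_prop >= stp2$ll) { cov_ <- cv_prop; break }
          }
          alpha <- (alpha - 1) / 2
        }
      }
    }
  }
  if (status != "converged") {
    warning("EM-REML reached max_iter = ", max_iter,
            " (max relative change ", signif(rel, 3), "); returning best estimate")
  }
  dimnames(cov_$Su) <- dimnames(cov_$St) <- dimnames(cov_$Se) <- list(traits, traits)
  structure(list(Su = cov_$Su, St = cov_$St, Se = cov_$Se,
                 loglik = ll_path, iterations = it,
                 converged = status == "converged", status = status,
                 trace = trace_par, traits = traits),
            class = "gait_reml")
}

#' Genetic parameters from a covariance set
#'
#' Heritability `h2_j = Su[j,j] / (Su + St + Se)[j,j]`, the analogous
#' technician fraction, and the correlation matrices of the three components.
#'
#' @param cov list (or `gait_reml`) with `Su`, `St`, `Se`.
#' @return list with `h2`, `tech_frac`, `cor_u`, `cor_t`, `cor_e`,
#'   `phenotypic_var`.
#' @export
genetic_parameters <- function(cov) {
  Su <- as.matrix(cov$Su); St <- as.matrix(cov$St); Se <- as.matrix(cov$Se)
  pv <- diag(Su) + diag(St) + diag(Se)
  if (any(pv <= 0)) stop("zero phenotypic variance for trait(s): ",
                         paste(which(pv <= 0), collapse = ", "))
  list(h2 = diag(Su) / pv, tech_frac = diag(St) / pv,
       cor_u = cov2cor_safe(Su), cor_t = cov2cor_safe(St), cor_e = cov2cor_safe(Se),
       phenotypic_var = pv)
}

#' BLUP breeding values with theoretical accuracy
#'
#' Solves the MME at fixed covariances for every pedigree animal (phenotyped
#' or not) and computes the theoretical accuracy from the prediction-error
#' variance (the animal-block diagonal of the inverse coefficient matrix,
#' obtained exactly from the sparse selected inverse):
#' `r_i = sqrt(1 - PEV_i / ((1 + F_i) sigma_u^2))`.
#'
#' @param tab phenotype table (raw, uncleaned — all information is used for
#'   prediction).
#' @param ped pedigree object.
#' @param cov list with `Su`, `St`, `Se`.
#' @param traits traits to evaluate.
#' @return list of class `gait_ebv`: `ebv` and `accuracy` (animal x trait
#'   matrices, rows named by id), `technician` effects, `theta`, `F`
#'   (inbreeding), `cov`.
#' @export
predict_ebv <- function(tab, ped, cov, traits = gait_traits) {
  traits <- intersect(traits, names(tab))
  str <- mme_structure(tab, ped, traits)
  covs <- lapply(cov[c("Su", "St", "Se")], function(m) {
    m <- as.matrix(m)
    if (!is.null(colnames(m)) && all(traits %in% colnames(m))) m[traits, traits, drop = FALSE]
    else m
  })
  sym <- assemble_mme(str, covs, symbolic = TRUE)
  ch <- Matrix::Cholesky(sym$C, LDL = TRUE, super = FALSE, perm = TRUE)
  maps <- factor_maps(str, ch)
  sys <- assemble_mme(str, covs)
  ch <- Matrix::update(ch, sys$C)
  x <- as.numeric(Matrix::solve(ch, sys$rhs, system = "A"))
  z <- takahashi_inverse(ch@p, ch@i, ch@x)
  TT <- str$TT
  U <- matrix(x[str$NF + seq_len(str$na * TT)], str$na, TT, byrow = TRUE)
  Tm <- matrix(x[str$NF + str$na * TT + seq_len(str$ntech * TT)], str$ntech, TT,
               byrow = TRUE)
  pev <- matrix(z[maps$pev_pos], str$na, TT)
  denom <- outer(1 + str$Fvec, diag(covs$Su))
  acc <- sqrt(pmin(pmax(1 - pev / denom, 0), 1))
  dimnames(U) <- dimnames(acc) <- list(ped$id, traits)
  rownames(Tm) <- str$tech_levels
  colnames(Tm) <- traits
  theta <- lapply(seq_len(TT), function(i) x[str$offf[i] + seq_len(str$nfix[i])])
  names(theta) <- traits
  structure(list(ebv = U, accuracy = acc, technician = Tm, theta = theta,
                 F = setNames(str$Fvec, ped$id), cov = covs, pev = pev),
            class = "gait_ebv")
}
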