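# gait-score covariances restricted to a trait subset
cov_subset <- function(traits) {
  cc <- campolina_covariances()
  list(Su = cc$Su[traits, traits, drop = FALSE],
       St = cc$St[traits, traits, drop = FALSE],
       Se = cc$Se[traits, traits, drop = FALSE])
}

test_that("the smallest MME reproduces the scalar single-record BLUP", {
  # one animal, one record, one technician: shrinkage toward zero with
  # k = (se2 + st2-free?) -- technician absorbs nothing here since it has its
  # own variance; verify against the 3x3 dense solution
  ped <- pedigree(data.frame(id = 1, sire = 0, dam = 0, birth_year = 2000,
                             sex = "M"))
  tab <- data.frame(animal = 1, Di = 33, age = 39, birth_year = 2000,
                    sex = "M", reg_year = 2003, stud_id = 1, technician_id = 1)
  cov <- list(Su = matrix(4), St = matrix(2), Se = matrix(10))
  sys <- build_mme(tab, ped, cov, traits = "Di")
  sol <- solve_mme(sys)
  # fixed part is a single CG level (intercept dropped, age aliased out):
  # with one record everything is absorbed by the CG mean, u = 0
  expect_equal(as.numeric(sol$u), 0, tolerance = 1e-10)
  expect_equal(sol$rel_residual, 0, tolerance = 1e-10)
})

test_that("MME equals the dense joint-GLS oracle, direct equals CG", {
  st <- small_study(seed = 11, n_years = 6, n_per_year = 12, n_technicians = 4,
                    n_studs = 3)
  tab <- st$tab[seq_len(min(55, nrow(st$tab))), ]
  ped <- st$ped
  traits <- c("R", "De")
  cov <- cov_subset(traits)
  sys <- build_mme(tab, ped, cov, traits = traits)
  sol <- solve_mme(sys)
  expect_lt(sol$rel_residual, 1e-10)

  # dense joint-GLS on observed scalars
  str <- sys$str
  A <- build_A(ped)
  TT <- 2L
  n_obs <- length(str$yobs)
  Zu <- matrix(0, n_obs, nrow(ped) * TT)
  Zt <- matrix(0, n_obs, str$ntech * TT)
  for (o in seq_len(n_obs)) {
    r <- str$obs_rec[o]; i <- str$obs_tr[o]
    Zu[o, (str$apos[r] - 1L) * TT + i] <- 1
    Zt[o, (str$tpos[r] - 1L) * TT + i] <- 1
  }
  Re <- matrix(0, n_obs, n_obs)
  for (r in seq_len(str$n_rec)) {
    oo <- which(str$obs_rec == r)
    Re[oo, oo] <- cov$Se[str$obs_tr[oo], str$obs_tr[oo]]
  }
  V <- Zu %*% kronecker(A, cov$Su) %*% t(Zu) +
    Zt %*% kronecker(diag(str$ntech), cov$St) %*% t(Zt) + Re
  Xf <- as.matrix(str$Wbig[, seq_len(str$NF), drop = FALSE])
  Vi <- solve(V)
  th <- solve(t(Xf) %*% Vi %*% Xf, t(Xf) %*% Vi %*% str$yobs)
  resid <- str$yobs - Xf %*% th
  uo <- kronecker(A, cov$Su) %*% t(Zu) %*% Vi %*% resid
  expect_equal(unname(sol$u), matrix(uo, nrow(ped), TT, byrow = TRUE),
               tolerance = 1e-6)

  # iterative solver agrees with the direct one
  sol_cg <- solve_mme(sys, method = "cg", tol = 1e-12)
  expect_equal(sol_cg$solution, sol$solution, tolerance = 1e-6)

  # complete-record residual blocks are the full Se inverse
  complete <- which(vapply(str$patterns, length, 0L) == TT)
  expect_true(length(complete) >= 1L)
  rv <- gaitbv:::rinv_flat(str, cov$Se)
  blk <- matrix(rv[(complete[1] - 1) * TT * TT + seq_len(TT * TT)], TT, TT,
                byrow = TRUE)
  expect_equal(blk, solve(cov$Se), ignore_attr = TRUE)
})

test_that("EM-REML matches the closed-form balanced one-way components", {
  set.seed(5)
  ntech <- 30; npg <- 20; n <- ntech * npg
  ped <- pedigree(data.frame(id = 1:n, sire = 0, dam = 0, birth_year = 2000,
                             sex = "F"))
  tech <- rep(1:ntech, each = npg)
  y <- 20 + rnorm(ntech, 0, 2)[tech] + rnorm(n, 0, 3)
  tab <- data.frame(animal = 1:n, Di = y, age = 39, birth_year = 2000,
                    sex = "F", reg_year = 2003, stud_id = 1,
                    technician_id = tech)
  fit <- em_reml(tab, ped, traits = "Di", tol = 1e-9, max_iter = 500)
  gm <- tapply(y, tech, mean)
  MSB <- npg * var(gm)
  MSW <- sum((y - gm[tech])^2) / (n - ntech)
  # with unrelated once-recorded animals only st2 and (su2 + se2) are
  # identified; both must equal the closed-form REML components
  expect_equal(fit$St[1, 1], (MSB - MSW) / npg, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$Su[1, 1] + fit$Se[1, 1], MSW, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("EM-REML finds the restricted-likelihood optimum on pedigree data", {
  st <- small_study(seed = 21, n_years = 8, n_per_year = 40, n_technicians = 8)
  tab <- build_contemporary_groups(st$tab)
  ped <- st$ped
  fit <- em_reml(tab, ped, traits = "R", tol = 1e-7, max_iter = 600)
  expect_true(all(diff(fit$loglik) > -1e-8))

  # dense restricted-likelihood oracle maximized numerically
  str <- gaitbv:::mme_structure(tab, ped, "R")
  A <- build_A(ped)
  n_obs <- length(str$yobs)
  Zu <- matrix(0, n_obs, nrow(ped)); Zt <- matrix(0, n_obs, str$ntech)
  for (o in seq_len(n_obs)) {
    Zu[o, str$apos[str$obs_rec[o]]] <- 1
    Zt[o, str$tpos[str$obs_rec[o]]] <- 1
  }
  Xf <- as.matrix(str$Wbig[, seq_len(str$NF), drop = FALSE])
  ZAZ <- Zu %*% A %*% t(Zu); ZZt <- Zt %*% t(Zt)
  negll <- function(lp) {
    V <- exp(lp[1]) * ZAZ + exp(lp[2]) * ZZt + diag(exp(lp[3]), n_obs)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    XtViX <- t(Xf) %*% Vi %*% Xf
    cX <- chol(XtViX)
    th <- backsolve(cX, forwardsolve(t(cX), t(Xf) %*% Vi %*% str$yobs))
    r <- str$yobs - Xf %*% th
    0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + sum(r * (Vi %*% r)))
  }
  v0 <- var(str$yobs)
  opt <- optim(log(c(v0, v0, v0) / 3), negll, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  expect_equal(fit$Su[1, 1], exp(opt$par[1]), tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_equal(fit$St[1, 1], exp(opt$par[2]), tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_equal(fit$Se[1, 1], exp(opt$par[3]), tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("a null genetic simulation yields a near-zero heritability", {
  cc <- campolina_covariances()
  Su0 <- matrix(0, 5, 5); Su0[1, 1] <- 1e-8  # essentially no genetic variance
  cfg <- sim_config(n_founders = 120, n_years = 12, n_per_year = 170,
                    pheno_year_first = 5, pheno_rate = 1,
                    Su = diag(1e-6, 5), n_technicians = 25,
                    missing_rate = rep(0, 5), seed = 77)
  st <- sim_gait_study(cfg)
  tab <- build_contemporary_groups(st$tab)
  ped_t <- truncate_pedigree(st$ped, unique(tab$animal), 3L)
  fit <- em_reml(tab, ped_t, traits = "Di", tol = 1e-4, max_iter = 300)
  h2 <- genetic_parameters(fit)$h2
  expect_lt(unname(h2), 0.02)
})

test_that("genetic_parameters computes ratios and correlations", {
  gp <- genetic_parameters(list(Su = diag(5), St = diag(5), Se = diag(5)))
  expect_equal(unname(gp$h2), rep(1 / 3, 5))
  expect_true(all(gp$cor_u[upper.tri(gp$cor_u)] == 0))
  gp2 <- genetic_parameters(list(Su = diag(5), St = matrix(0, 5, 5),
                                 Se = diag(5)))
  expect_equal(unname(gp2$tech_frac), rep(0, 5))
  expect_error(genetic_parameters(list(Su = matrix(0, 2, 2),
                                       St = matrix(0, 2, 2),
                                       Se = matrix(0, 2, 2))),
               "zero phenotypic variance")
})

test_that("predict_ebv covers every animal with sensible accuracies", {
  st <- small_study(seed = 41, n_years = 8, n_per_year = 40)
  tab <- st$tab; ped <- st$ped
  cov <- cov_subset(c("R", "De"))
  ebv <- predict_ebv(tab, ped, cov, traits = c("R", "De"))
  expect_equal(nrow(ebv$ebv), nrow(ped))  # unphenotyped animals included
  expect_true(all(ebv$accuracy >= 0 & ebv$accuracy <= 1))

  # an isolated animal with no data and no phenotyped relatives: u = 0, r = 0
  iso <- pedigree(rbind(as.data.frame(ped)[c("id", "sire", "dam", "birth_year", "sex")],
                        data.frame(id = 999999L, sire = 0L, dam = 0L,
                                   birth_year = 2000L, sex = "M")))
  ebv2 <- predict_ebv(tab, iso, cov, traits = c("R", "De"))
  expect_equal(unname(ebv2$ebv["999999", ]), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(ebv2$accuracy["999999", ]), c(0, 0), tolerance = 1e-6)

  # phenotyped animals are better evaluated than unphenotyped ones on average
  phen <- as.character(ped$id) %in% as.character(tab$animal)
  expect_gt(mean(ebv$accuracy[phen, "R"]), mean(ebv$accuracy[!phen, "R"]))

  # an unrecorded offspring of two parents equals their parent average
  ped_po <- pedigree(rbind(as.data.frame(ped)[c("id", "sire", "dam", "birth_year", "sex")],
                           data.frame(id = 888888L, sire = tab$animal[1],
                                      dam = tab$animal[2], birth_year = 2012L,
                                      sex = "F")))
  ebv3 <- predict_ebv(tab, ped_po, cov, traits = c("R", "De"))
  pa <- (ebv3$ebv[as.character(tab$animal[1]), ] +
           ebv3$ebv[as.character(tab$animal[2]), ]) / 2
  expect_equal(ebv3$ebv["888888", ], pa, tolerance = 1e-6)
})

test_that("estimates are invariant to animal reordering", {
  st <- small_study(seed = 51, n_years = 6, n_per_year = 25, n_technicians = 5)
  tab <- st$tab
  ped_df <- as.data.frame(st$ped)[c("id", "sire", "dam", "birth_year", "sex")]
  set.seed(1)
  ped_shuf <- pedigree(ped_df[sample(nrow(ped_df)), ])
  fit1 <- em_reml(tab, st$ped, traits = "C", tol = 3e-8, max_iter = 2000)
  fit2 <- em_reml(tab, ped_shuf, traits = "C", tol = 3e-8, max_iter = 2000)
  # agreement is limited by the EM stopping rule, not by the ordering;
  # compare on the phenotypic-variance scale
  pv <- fit1$Su[1, 1] + fit1$St[1, 1] + fit1$Se[1, 1]
  expect_lt(abs(fit1$Su[1, 1] - fit2$Su[1, 1]) / pv, 1e-3)
  expect_lt(abs(fit1$St[1, 1] - fit2$St[1, 1]) / pv, 1e-3)
  expect_lt(abs(fit1$Se[1, 1] - fit2$Se[1, 1]) / pv, 1e-3)
})
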