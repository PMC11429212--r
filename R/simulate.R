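# Synthetic data generator: multi-generation pedigrees with overlapping
# generations, breeding values by recursive Mendelian sampling, and five-trait
# gait-score phenotypes with contemporary-group, stud, age, technician and
# residual components.

#' Trait names used throughout the package
#'
#' Dissociation (Di), comfort (C), style (S), regularity (R) and
#' development (De) — the five visual gait scores.
#' @export
gait_traits <- c("Di", "C", "S", "R", "De")

#' Default genetic, technician and residual covariance matrices
#'
#' Five-trait covariance matrices on the score scale, built from published
#' Campolina gait-score parameter estimates: heritabilities 0.08 (Di, C, De),
#' 0.09 (S) and 0.11 (R); technician variance fractions between 0.33 (S) and
#' 0.43 (C); genetic correlations between 0.65 (Di, C) and 0.95 (R, De);
#' residual correlations between 0.34 (De, C) and 0.78 (De, R); technician
#' correlations between 0.52 (C, R) and 0.98 (R, De), with 0.91 for (Di, S).
#' Cells not individually published are fixed inside the published ranges
#' (see the methods vignette).  Phenotypic scales are the raw-score standard
#' deviations (3.70, 5.10, 5.36, 2.54, 2.57).
#'
#' @return list with 5x5 matrices `Su` (additive genetic), `St` (technician),
#'   `Se` (residual), plus the vectors `h2`, `tech_frac`, `sigma_p` used to
#'   build them.
#' @export
campolina_covariances <- function() {
  tr <- gait_traits
  sigma_p <- c(3.70, 5.10, 5.36, 2.54, 2.57)
  h2 <- c(0.08, 0.08, 0.09, 0.11, 0.08)
  tech_frac <- c(0.40, 0.43, 0.33, 0.36, 0.38)
  mkcor <- function(v) {
    M <- diag(5)
    M[upper.tri(M)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(tr, tr)
    M
  }
  # upper triangle column-wise: (Di,C) (Di,S) (C,S) (Di,R) (C,R) (S,R)
  #                             (Di,De) (C,De) (S,De) (R,De)
  Rg <- mkcor(c(.65, .80, .70, .70, .68, .75, .70, .66, .72, .95))
  Re <- mkcor(c(.45, .60, .50, .50, .40, .55, .48, .34, .50, .78))
  Rt <- mkcor(c(.60, .91, .62, .70, .52, .72, .70, .55, .70, .98))
  su <- sigma_p * sqrt(h2)
  st <- sigma_p * sqrt(tech_frac)
  se <- sigma_p * sqrt(1 - h2 - tech_frac)
  out <- list(Su = Rg * tcrossprod(su), St = Rt * tcrossprod(st),
              Se = Re * tcrossprod(se),
              h2 = setNames(h2, tr), tech_frac = setNames(tech_frac, tr),
              sigma_p = setNames(sigma_p, tr))
  stopifnot(is_psd(out$Su), is_psd(out$St), is_psd(out$Se))
  out
}

#' Simulation configuration
#'
#' Defaults emulate the structure of the Campolina gait-score study: a
#' multi-decade pedigree with overlapping generations, a few heavily used
#' stallions per year against many mares, phenotyping of the most recent
#' cohorts around 36-45 months of age, 30 technicians with skewed workloads,
#' contemporary groups from birth year x sex x registration year, and the
#' default covariance matrices of [campolina_covariances()].
#'
#' @param n_founders founder animals (years 1-3 of the simulation).
#' @param n_years calendar years simulated.
#' @param n_per_year matings (= offspring) per year.
#' @param pheno_year_first first birth year whose animals are phenotyped.
#' @param pheno_rate probability a candidate animal is scored.
#' @param n_studs,n_technicians numbers of studs and technicians.
#' @param Su,St,Se 5x5 genetic / technician / residual covariance matrices.
#' @param mu per-trait intercepts (score units).
#' @param beta1,beta2 per-trait linear and quadratic age coefficients
#'   (score units per month, per month squared; raw age scale).
#' @param age_mean,age_sd age at measurement, months.
#' @param cg_effect_sd,stud_effect_sd per-trait SDs of the contemporary-group
#'   and stud fixed effects.
#' @param missing_rate per-trait probability a score is missing (MCAR).
#' @param round_scores round phenotypes to integers (off by default: the
#'   analysis treats scores as continuous).
#' @param seed master seed for the simulation streams.
#' @return list of class `gait_simconfig`.
#' @export
sim_config <- function(n_founders = 200L, n_years = 30L, n_per_year = 200L,
                       pheno_year_first = 7L, pheno_rate = 0.65,
                       n_studs = 60L, n_technicians = 30L,
                       Su = NULL, St = NULL, Se = NULL,
                       mu = c(30.73, 47.66, 30.34, 22.76, 22.82),
                       beta1 = NULL, beta2 = NULL,
                       age_mean = 39.65, age_sd = 3.39,
                       cg_effect_sd = NULL, stud_effect_sd = NULL,
                       missing_rate = c(0.26, 0, 0.23, 0.25, 0.25),
                       round_scores = FALSE, seed = 20240901L) {
  defc <- campolina_covariances()
  if (is.null(Su)) Su <- defc$Su
  if (is.null(St)) St <- defc$St
  if (is.null(Se)) Se <- defc$Se
  ntr <- ncol(Su)
  sigma_p <- sqrt(diag(Su) + diag(St) + diag(Se))
  if (is.null(beta1)) beta1 <- 0.08 * sigma_p
  if (is.null(beta2)) beta2 <- -0.0012 * sigma_p
  if (is.null(cg_effect_sd)) cg_effect_sd <- 0.4 * sigma_p
  if (is.null(stud_effect_sd)) stud_effect_sd <- 0.3 * sigma_p
  stopifnot(n_founders >= 2L, is_psd(Su), is_psd(St), is_psd(Se),
            length(mu) == ntr, length(missing_rate) == ntr)
  h2 <- diag(Su) / sigma_p^2
  stopifnot(all(h2 > 0 | diag(Su) == 0), all(h2 < 1))
  structure(list(n_founders = as.integer(n_founders), n_years = as.integer(n_years),
                 n_per_year = as.integer(n_per_year),
                 pheno_year_first = as.integer(pheno_year_first),
                 pheno_rate = pheno_rate, n_studs = as.integer(n_studs),
                 n_technicians = as.integer(n_technicians),
                 Su = Su, St = St, Se = Se, mu = mu, beta1 = beta1, beta2 = beta2,
                 age_mean = age_mean, age_sd = age_sd,
                 cg_effect_sd = cg_effect_sd, stud_effect_sd = stud_effect_sd,
                 missing_rate = missing_rate, round_scores = round_scores,
                 seed = as.integer(seed)),
            class = "gait_simconfig")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are spread over the nine cohorts preceding the first mating year
#' (60% females).  Each
#' subsequent year, `n_per_year` matings are formed: every mating uses a
#' distinct dam (females aged 4-16) and a stallion drawn with replacement
#' from a small active-sire pool with rank-skewed usage weights, so stallions
#' average far more offspring than mares, as in real stud books.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] object.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "pedigree"))
  nf <- cfg$n_founders
  id <- seq_len(nf)
  sex <- rep(c("F", "M"), length.out = nf)
  sex[seq_len(round(0.6 * nf))] <- "F"
  sex <- sample(sex)
  by <- sort(rep_len(-6:2, nf))  # founder cohorts precede the first mating year
  sire <- dam <- rep(0L, nf)
  nxt <- nf + 1L
  if (cfg$n_years > 0L) {
    for (yr in 4:(3L + cfg$n_years)) {
      age <- yr - by
      dams <- id[sex == "F" & age >= 4L & age <= 16L]
      males <- id[sex == "M" & age >= 4L & age <= 16L]
      if (length(dams) < 2L || length(males) < 1L) {
        stop("infeasible mating parameters: no available dams or sires in year ", yr)
      }
      nm <- min(cfg$n_per_year, length(dams))
      use_dam <- sample(dams, nm)
      nsire <- max(2L, min(length(males), ceiling(nm / 12)))
      pool <- sample(males, nsire)
      w <- 1 / seq_len(nsire)^0.8
      use_sire <- sample(pool, nm, replace = TRUE, prob = w)
      kid <- seq.int(nxt, nxt + nm - 1L)
      id <- c(id, kid)
      sire <- c(sire, use_sire)
      dam <- c(dam, use_dam)
      by <- c(by, rep.int(yr, nm))
      sex <- c(sex, sample(c("F", "M"), nm, replace = TRUE))
      nxt <- nxt + nm
    }
  }
  pedigree(data.frame(id = id, sire = sire, dam = dam, birth_year = by, sex = sex))
}

#' Simulate breeding values by recursive Mendelian sampling
#'
#' Founders draw from MVN(0, Su); an offspring's breeding value is the parent
#' average plus a Mendelian sampling deviation with covariance `d_i * Su`,
#' where `d_i = 0.5 - 0.25 (F_sire + F_dam)` (unknown-parent conventions as in
#' [compute_inbreeding()]).  Marginally `Var(u_i) = (1 + F_i) Su`.
#'
#' @param ped pedigree object.
#' @param Su additive genetic covariance matrix.
#' @param seed integer seed.
#' @return `n x ntrait` matrix of true breeding values, rows named by id.
#' @export
simulate_breeding_values <- function(ped, Su, seed = 1L) {
  if (!is_psd(Su)) stop("Su is not positive semi-definite")
  set.seed(seed)
  n <- nrow(ped)
  ntr <- ncol(Su)
  Fv <- compute_inbreeding(ped)
  d <- attr(Fv, "d")
  M <- rmvn(n, Su) * sqrt(d)
  u <- matrix(0, n, ntr)
  si <- ped$si; di <- ped$di
  for (i in seq_len(n)) {
    pa <- 0
    if (si[i] > 0L) pa <- pa + 0.5 * u[si[i], ]
    if (di[i] > 0L) pa <- pa + 0.5 * u[di[i], ]
    u[i, ] <- pa + M[i, ]
  }
  dimnames(u) <- list(ped$id, colnames(Su) %||% gait_traits[seq_len(ntr)])
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate gait-score phenotypes
#'
#' Generates one scoring record per phenotyped animal under the evaluation
#' model: intercept + linear and quadratic age + contemporary group
#' (birth year x sex x registration year) + stud + animal additive + technician
#' + residual.  Registration happens around 36 months after birth
#' (`reg_year = birth_year + 3 +/- 1`), technicians and studs have skewed
#' workload distributions, and per-trait missingness is completely at random.
#'
#' @param ped pedigree object.
#' @param u matrix of true breeding values aligned to `ped` rows.
#' @param cfg a [sim_config()].
#' @return data frame (`gait_phenotypes`) with columns `animal`, one column
#'   per trait (NA = missing), `age`, `birth_year`, `sex`, `reg_year`,
#'   `stud_id`, `technician_id`.  The latent components (breeding values,
#'   technician effects, residuals, fixed parts) are attached as attribute
#'   `truth` for simulation-based checks.
#' @export
simulate_phenotypes <- function(ped, u, cfg) {
  stopifnot(nrow(u) == nrow(ped))
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  ntr <- ncol(u)
  trn <- colnames(u)
  last_year <- max(ped$birth_year)
  cand <- which(ped$birth_year >= cfg$pheno_year_first &
                  ped$birth_year <= last_year - 0L & ped$si > 0L)
  if (!length(cand)) stop("config inconsistent with pedigree years: no candidate cohort")
  meas <- cand[runif(length(cand)) < cfg$pheno_rate]
  n <- length(meas)
  if (n < 2L) stop("fewer than two phenotyped animals; raise pheno_rate or n_per_year")

  age <- pmax(30, rnorm(n, cfg$age_mean, cfg$age_sd))
  reg_year <- ped$birth_year[meas] + 3L +
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  stud <- sample.int(cfg$n_studs, n, replace = TRUE,
                     prob = 1 / seq_len(cfg$n_studs)^0.7)
  tech <- sample.int(cfg$n_technicians, n, replace = TRUE,
                     prob = 1 / seq_len(cfg$n_technicians)^0.6)

  cg_label <- paste(ped$birth_year[meas], ped$sex[meas], reg_year, sep = "_")
  cg_levels <- unique(cg_label)
  cg_eff <- matrix(rnorm(length(cg_levels) * ntr), length(cg_levels), ntr)
  cg_eff <- sweep(cg_eff, 2L, cfg$cg_effect_sd, `*`)
  stud_eff <- matrix(rnorm(cfg$n_studs * ntr), cfg$n_studs, ntr)
  stud_eff <- sweep(stud_eff, 2L, cfg$stud_effect_sd, `*`)
  tech_eff <- rmvn(cfg$n_technicians, cfg$St)
  e <- rmvn(n, cfg$Se)

  fixed <- matrix(cfg$mu, n, ntr, byrow = TRUE) +
    outer(age, cfg$beta1) + outer(age^2, cfg$beta2) +
    cg_eff[match(cg_label, cg_levels), , drop = FALSE] +
    stud_eff[stud, , drop = FALSE]
  y <- fixed + u[meas, , drop = FALSE] + tech_eff[tech, , drop = FALSE] + e
  if (cfg$round_scores) y <- round(y)
  for (j in seq_len(ntr)) {
    if (cfg$missing_rate[j] > 0) {
      y[runif(n) < cfg$missing_rate[j], j] <- NA_real_
    }
  }
  tab <- data.frame(animal = ped$id[meas])
  for (j in seq_len(ntr)) tab[[trn[j]]] <- y[, j]
  tab$age <- age
  tab$birth_year <- ped$birth_year[meas]
  tab$sex <- ped$sex[meas]
  tab$reg_year <- reg_year
  tab$stud_id <- stud
  tab$technician_id <- tech
  structure(tab, class = c("gait_phenotypes", "data.frame"),
            truth = list(u = u[meas, , drop = FALSE], tech_eff = tech_eff,
                         tech = tech, e = e, fixed = fixed))
}

#' Simulate a complete gait-score study
#'
#' Convenience wrapper: pedigree, breeding values and phenotypes in one call.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped` (pedigree), `u` (true breeding values for all
#'   animals), `tab` (phenotype table) and `cfg`.
#' @export
sim_gait_study <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  u <- simulate_breeding_values(ped, cfg$Su, seed = derive_seed(cfg$seed, "breeding_values"))
  tab <- simulate_phenotypes(ped, u, cfg)
  list(ped = ped, u = u, tab = tab, cfg = cfg)
}
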