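# Parameter-recovery experiments: simulate replicates under the published
# Campolina gait-score variance-component ratios and re-estimate them with
# EM-REML, the standard way to validate a variance-component pipeline when
# the original data are proprietary.

#' Simulate-and-re-estimate parameter recovery
#'
#' For each replicate: simulate a multi-generation pedigree with overlapping
#' generations, breeding values by Mendelian sampling and phenotypes under
#' the evaluation model, using the published parameter ratios
#' ([campolina_covariances()]) restricted to `traits` as simulation truth;
#' clean the records, truncate the pedigree to `generations` ancestral
#' generations, and run EM-REML with animal and technician random effects.
#'
#' @param traits one or more of the five gait scores; a single trait gives a
#'   univariate analysis, two a bivariate one.
#' @param n_replicates number of simulation replicates.
#' @param seed master seed; replicate r uses the derived stream
#'   `recovery_<r>`.
#' @param n_founders,n_years,n_per_year,pheno_year_first,pheno_rate,n_technicians
#'   simulation scale (defaults give roughly 1,900 phenotyped animals).
#' @param generations pedigree truncation depth for REML (default 3).
#' @param tol,max_iter EM-REML settings.
#' @return data frame with one row per replicate: `n_records`, `n_pedigree`,
#'   `iterations`, `converged`, `h2_<trait>` and `tech_<trait>` per trait,
#'   and `r_g` (genetic correlation of the first trait pair) when more than
#'   one trait is analysed.
#' @export
recovery_experiment <- function(traits = "R", n_replicates = 10L, seed = 1L,
                                n_founders = 200L, n_years = 17L,
                                n_per_year = 200L, pheno_year_first = 8L,
                                pheno_rate = 0.72, n_technicians = 30L,
                                generations = 3L, tol = 1e-5,
                                max_iter = 400L) {
  cc <- campolina_covariances()
  k <- match(traits, gait_traits)
  if (anyNA(k)) stop("unknown trait(s): ", paste(traits[is.na(k)], collapse = ", "))
  mu_all <- c(30.73, 47.66, 30.34, 22.76, 22.82)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(
      n_founders = n_founders, n_years = n_years, n_per_year = n_per_year,
      pheno_year_first = pheno_year_first, pheno_rate = pheno_rate,
      n_technicians = n_technicians,
      Su = cc$Su[k, k, drop = FALSE], St = cc$St[k, k, drop = FALSE],
      Se = cc$Se[k, k, drop = FALSE], mu = mu_all[k],
      missing_rate = rep(0, length(k)),
      seed = derive_seed(seed, paste0("recovery_", r)))
    st <- sim_gait_study(cfg)
    tab <- build_contemporary_groups(st$tab)
    clean <- clean_for_reml(tab)
    ped_t <- truncate_pedigree(st$ped, unique(clean$animal), generations)
    fit <- em_reml(clean, ped_t, traits = traits, tol = tol,
                   max_iter = max_iter)
    gp <- genetic_parameters(fit)
    row <- data.frame(replicate = r, n_records = nrow(clean),
                      n_pedigree = nrow(ped_t), iterations = fit$iterations,
                      converged = fit$converged)
    for (j in seq_along(traits)) {
      row[[paste0("h2_", traits[j])]] <- unname(gp$h2[j])
      row[[paste0("tech_", traits[j])]] <- unname(gp$tech_frac[j])
    }
    if (length(traits) >= 2L) row$r_g <- gp$cor_u[1L, 2L]
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}
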