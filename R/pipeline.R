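# End-to-end orchestration: simulate (or ingest) -> clean -> OLS -> EM-REML
# -> BLUP -> features -> machine-learning models -> validation -> trends,
# with every stage seeded from the master seed by name and all artifacts
# written as plain-text files.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic study (set `ped_file`
#'   / `pheno_file` instead to ingest CSV data).
#' @param ped_file,pheno_file optional CSV inputs replacing simulation.
#' @param traits traits to analyse.
#' @param reml_generations pedigree truncation depth for REML (default 3).
#' @param reml_tol,reml_max_iter EM-REML convergence settings.
#' @param eigen_k eigenvectors of A used as features (default 10).
#' @param cutoff last training birth year (default: three years before the
#'   newest phenotyped cohort).
#' @param n_focal_years validation cohorts after the cutoff (default 3).
#' @param base_year genetic-base year for trends (default: earliest cohort).
#' @param ml run the machine-learning stage (default TRUE).
#' @param ann,svr,rfr named lists of hyperparameter overrides.
#' @param seed master seed; every stage derives its own stream via
#'   [derive_seed()].
#' @param out_dir output directory (created); NULL = no files written.
#' @return list of class `gait_runconfig`.
#' @export
run_config <- function(sim = sim_config(), ped_file = NULL, pheno_file = NULL,
                       traits = gait_traits, reml_generations = 3L,
                       reml_tol = 1e-5, reml_max_iter = 500L, eigen_k = 10L,
                       cutoff = NULL, n_focal_years = 3L, base_year = NULL,
                       ml = TRUE, ann = list(), svr = list(), rfr = list(),
                       seed = 1L, out_dir = NULL) {
  structure(list(sim = sim, ped_file = ped_file, pheno_file = pheno_file,
                 traits = traits, reml_generations = as.integer(reml_generations),
                 reml_tol = reml_tol, reml_max_iter = as.integer(reml_max_iter),
                 eigen_k = as.integer(eigen_k), cutoff = cutoff,
                 n_focal_years = as.integer(n_focal_years),
                 base_year = base_year, ml = ml,
                 ann = ann, svr = svr, rfr = rfr,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "gait_runconfig")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the complete evaluation pipeline
#'
#' Executes, in order: data simulation (or CSV ingestion), contemporary-group
#' construction, cleaning and pedigree truncation for REML, EM-REML variance
#' components, whole-data BLUP on the raw data and full pedigree, OLS
#' adjusted phenotypes and per-effect components, feature assembly
#' (training-centered), ANN / SVR / RFR training per trait on the training
#' animals with the whole-data MTM EBVs as targets, LR-method validation and
#' genetic trends.  All stochastic stages derive their seeds from the master
#' seed by stage name, so a rerun with the same configuration reproduces
#' every artifact.
#'
#' @param cfg a [run_config()].
#' @return list of class `gait_run` with `ped`, `tab`, `reml`, `cov`,
#'   `params`, `ebv_whole`, `ols`, `features`, `models`, `split`,
#'   `validation`, `trend`, `manifest`; artifacts written to `cfg$out_dir`
#'   when set.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "gait_runconfig"))
  traits <- cfg$traits

  # ---- data ----
  if (!is.null(cfg$ped_file)) {
    ped <- read_pedigree(cfg$ped_file)
    tab <- read.csv(cfg$pheno_file, stringsAsFactors = FALSE)
  } else {
    sim <- cfg$sim
    sim$seed <- derive_seed(cfg$seed, "simulate")
    study <- sim_gait_study(sim)
    ped <- study$ped
    tab <- study$tab
  }
  tab <- build_contemporary_groups(tab)

  # ---- REML on cleaned data, truncated pedigree ----
  clean <- clean_for_reml(tab)
  ped_reml <- truncate_pedigree(ped, unique(clean$animal), cfg$reml_generations)
  reml <- em_reml(clean, ped_reml, traits = traits,
                  tol = cfg$reml_tol, max_iter = cfg$reml_max_iter)
  cov <- list(Su = reml$Su, St = reml$St, Se = reml$Se)
  params <- genetic_parameters(cov)

  # ---- whole-data BLUP on raw data ----
  ebv_whole <- predict_ebv(tab, ped, cov, traits = traits)

  # ---- OLS stage ----
  ols <- ols_stage(tab)

  # ---- split and features ----
  years <- sort(unique(tab$birth_year))
  cutoff <- cfg$cutoff %||% years[max(1L, length(years) - cfg$n_focal_years)]
  split <- split_by_year(tab, ped, cutoff,
                         focal_years = years[years > cutoff])
  train_rows <- which(tab$animal %in% split$training)
  focal_rows <- which(tab$animal %in% split$focal)

  models <- NULL; features <- NULL; features_focal <- NULL
  validation <- NULL
  if (isTRUE(cfg$ml)) {
    pheno_ids <- tab$animal
    Asub <- A_submatrix(ped, pheno_ids)
    eig <- top_eigenvectors(Asub, k = cfg$eigen_k)
    dum <- encode_technicians(tab[train_rows, , drop = FALSE])
    features <- assemble_features(
      ols$adjusted[train_rows, , drop = FALSE],
      lapply(ols$components, function(m) m[train_rows, , drop = FALSE]),
      dum, eig[train_rows, , drop = FALSE],
      animals = tab$animal[train_rows])
    features_focal <- transform_new(
      features,
      ols$adjusted[focal_rows, , drop = FALSE],
      lapply(ols$components, function(m) m[focal_rows, , drop = FALSE]),
      tab$technician_id[focal_rows],
      eig[focal_rows, , drop = FALSE])
    rownames(features_focal) <- tab$animal[focal_rows]

    target <- ebv_whole$ebv[as.character(tab$animal[train_rows]), , drop = FALSE]
    models <- list(ann = list(), svr = list(), rfr = list())
    for (tr in traits) {
      y <- target[, tr]
      models$ann[[tr]] <- do.call(ann_fit, c(
        list(features$X, y, seed = derive_seed(cfg$seed, paste0("ann_", tr))),
        cfg$ann))
      models$svr[[tr]] <- do.call(svr_fit, c(list(features$X, y), cfg$svr))
      models$rfr[[tr]] <- do.call(rfr_fit, c(
        list(features$X, y, seed = derive_seed(cfg$seed, paste0("rfr_", tr))),
        cfg$rfr))
    }
    validation <- run_validation(
      list(tab = tab, ped = ped, cov = cov, ebv_whole = ebv_whole,
           features_focal = features_focal, models = models),
      split)
  } else {
    validation <- run_validation(
      list(tab = tab, ped = ped, cov = cov, ebv_whole = ebv_whole,
           models = list()),
      split)
  }

  trend <- genetic_trend(ebv_whole, ped, base_year = cfg$base_year)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitbv")),
    seed = cfg$seed,
    stage_seeds = list(simulate = derive_seed(cfg$seed, "simulate")),
    n_animals = nrow(ped), n_records = nrow(tab),
    traits = traits, cutoff = cutoff,
    reml_iterations = reml$iterations, reml_status = reml$status,
    config_hash = derive_seed(1L, paste(deparse(cfg[setdiff(names(cfg), "out_dir")]),
                                        collapse = "")))

  out <- structure(list(ped = ped, tab = tab, clean = clean, reml = reml,
                        cov = cov, params = params, ebv_whole = ebv_whole,
                        ols = ols, features = features,
                        features_focal = features_focal, models = models,
                        split = split, validation = validation, trend = trend,
                        manifest = manifest, cfg = cfg),
                   class = "gait_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$out_dir
    write_pedigree(ped, file.path(od, "pedigree.csv"))
    write.csv(as.data.frame(tab), file.path(od, "phenotypes.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(cov, function(m) unclass(as.matrix(m))),
                         file.path(od, "covariances.json"), digits = NA)
    write.csv(data.frame(iteration = seq_along(reml$loglik), loglik = reml$loglik),
              file.path(od, "reml_log.csv"), row.names = FALSE)
    ebv_df <- data.frame(animal = rep(rownames(ebv_whole$ebv), length(traits)),
                         trait = rep(traits, each = nrow(ebv_whole$ebv)),
                         ebv = as.vector(ebv_whole$ebv),
                         accuracy = as.vector(ebv_whole$accuracy))
    write_tsv(ebv_df, file.path(od, "ebv.tsv"))
    if (!is.null(features)) {
      write_tsv(cbind(animal = tab$animal[train_rows],
                      as.data.frame(features$X)),
                file.path(od, "features.tsv"))
      jsonlite::write_json(features$layout, file.path(od, "feature_layout.json"))
    }
    write.csv(as.data.frame(validation), file.path(od, "validation.csv"),
              row.names = FALSE)
    write.csv(data.frame(trait = names(trend$slope), slope = trend$slope,
                         intercept = trend$intercept),
              file.path(od, "trends.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
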