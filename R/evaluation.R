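# Validation by the LR (linear regression) method — accuracy, level bias and
# dispersion from whole- versus partial-data predictions — plus correlation,
# mean squared error and genetic trends.

#' Split animals into training and focal (validation) sets by birth year
#'
#' @param tab phenotype table (or any data frame with `animal`).
#' @param ped pedigree (supplies birth years).
#' @param cutoff last birth year of the training set.
#' @param focal_years birth years forming the focal/validation set (default:
#'   the three years after `cutoff`).
#' @return list with `training` and `focal` id vectors (disjoint).
#' @export
split_by_year <- function(tab, ped, cutoff, focal_years = cutoff + 1:3) {
  by <- ped$birth_year[match(tab$animal, ped$id)]
  training <- tab$animal[by <= cutoff]
  focal <- tab$animal[by %in% focal_years]
  if (!length(focal)) stop("no focal animals born in ", paste(focal_years, collapse = ", "))
  list(training = training, focal = focal)
}

#' LR-method validation statistics
#'
#' For aligned whole- and partial-data EBV vectors over the focal animals:
#' accuracy `acc = cov(w, p) / ((1 - Fbar) sigma_u^2)` (as printed in the
#' source formulation; `sqrt_acc = TRUE` applies the square root of the
#' canonical LR accuracy), level bias `delta = (mean(p) - mean(w)) / sigma_u`
#' in genetic standard deviations, and dispersion `b1 = cov(w, p) / var(p)`
#' (expected value 1; smaller means over-dispersed partial predictions).
#' Covariances use the n-1 denominator.
#'
#' @param u_whole,u_partial aligned EBV vectors (length >= 2).
#' @param Fbar mean pedigree inbreeding of the focal animals.
#' @param sigma_u2 additive genetic variance of the trait.
#' @param sqrt_acc take the square root of the accuracy ratio (canonical LR
#'   form); default FALSE.
#' @return named vector with `acc`, `delta`, `b1`.
#' @export
lr_statistics <- function(u_whole, u_partial, Fbar = 0, sigma_u2, sqrt_acc = FALSE) {
  stopifnot(length(u_whole) == length(u_partial), length(u_whole) >= 2L,
            sigma_u2 > 0)
  u_whole <- unname(u_whole); u_partial <- unname(u_partial)
  Fbar <- unname(Fbar); sigma_u2 <- unname(sigma_u2)
  vp <- var(u_partial)
  if (vp == 0) stop("var(u_partial) is zero; b1 undefined")
  cwp <- cov(u_whole, u_partial)
  acc <- cwp / ((1 - Fbar) * sigma_u2)
  if (sqrt_acc) acc <- sqrt(pmax(acc, 0))
  c(acc = acc,
    delta = (mean(u_partial) - mean(u_whole)) / sqrt(sigma_u2),
    b1 = cwp / vp)
}

#' Correlation and mean squared error between whole and partial predictions
#'
#' @param u_whole,u_partial aligned EBV vectors (length >= 2).
#' @return named vector with `COR` (Pearson) and `MSE`.
#' @export
cor_mse <- function(u_whole, u_partial) {
  stopifnot(length(u_whole) == length(u_partial), length(u_whole) >= 2L)
  if (var(u_whole) == 0 || var(u_partial) == 0) {
    stop("zero variance in a prediction vector; correlation undefined")
  }
  c(COR = cor(u_whole, u_partial),
    MSE = mean((u_whole - u_partial)^2))
}

#' Genetic trends from estimated breeding values
#'
#' EBVs are expressed relative to a genetic base (the mean EBV of the
#' base-year cohort is subtracted per trait), then regressed on birth year by
#' ordinary least squares.
#'
#' @param ebv `gait_ebv` object or an animal x trait EBV matrix with rownames.
#' @param ped pedigree (supplies birth years).
#' @param base_year base cohort; default = earliest birth year in the
#'   pedigree.
#' @return list of class `gait_trend`: `slope` and `intercept` per trait,
#'   `yearly` (year x trait matrix of adjusted-EBV means), `base_year`.
#' @export
genetic_trend <- function(ebv, ped, base_year = NULL) {
  U <- if (inherits(ebv, "gait_ebv")) ebv$ebv else as.matrix(ebv)
  by <- ped$birth_year[match(rownames(U), as.character(ped$id))]
  if (anyNA(by)) stop("EBV rows without a birth year in the pedigree")
  if (is.null(base_year)) base_year <- min(by)
  base <- by == base_year
  if (!any(base)) {
    stop("no animals born in base year ", base_year,
         "; pick one of ", min(by), "-", max(by))
  }
  Uadj <- sweep(U, 2L, colMeans(U[base, , drop = FALSE]))
  slope <- intercept <- setNames(numeric(ncol(U)), colnames(U))
  for (j in seq_len(ncol(U))) {
    fit <- lm(Uadj[, j] ~ by)
    intercept[j] <- coef(fit)[1L]
    slope[j] <- coef(fit)[2L]
  }
  yearly <- rowsum(Uadj, by) / as.vector(table(by))
  structure(list(slope = slope, intercept = intercept, yearly = yearly,
                 base_year = base_year), class = "gait_trend")
}

#' Run the full LR-method validation across models
#'
#' Reproduces the whole/partial comparison design: the multi-trait model
#' (MTM) is validated by refitting the MME on the training records only and
#' comparing focal-animal EBVs against the whole-data EBVs; each
#' machine-learning model is trained on the training animals' feature rows
#' (targets = whole-data MTM EBVs of the training animals) and its focal-row
#' predictions are compared against the whole-data MTM EBVs.
#'
#' @param state pipeline state: list with `tab`, `ped`, `cov`, `ebv_whole`
#'   (a `gait_ebv`), `features_focal` (focal-animal feature rows transformed
#'   with the training centering, rownames = animal ids), and per-trait ML
#'   models in `models` (named list of lists, e.g. `models$ann$Di`); any
#'   missing model family is skipped with a warning.
#' @param split list from [split_by_year()].
#' @param sqrt_acc passed to [lr_statistics()].
#' @return data frame of class `gait_validation`: one row per trait x model
#'   with `acc`, `delta`, `b1`, `COR`, `MSE`, `n_focal`, plus attributes
#'   `Fbar` and `sigma_u`.
#' @export
run_validation <- function(state, split, sqrt_acc = FALSE) {
  tab <- state$tab; ped <- state$ped
  traits <- colnames(state$ebv_whole$ebv)
  focal <- intersect(split$focal, tab$animal)
  if (!is.null(state$features_focal)) {
    focal <- intersect(focal, rownames(state$features_focal))
  }
  train_rows <- which(tab$animal %in% split$training)
  Fv <- state$ebv_whole$F[as.character(focal)]
  Fbar <- mean(Fv)
  sigma_u2 <- diag(as.matrix(state$cov$Su))[traits]

  tab_train <- tab[train_rows, , drop = FALSE]
  ebv_partial <- predict_ebv(tab_train, ped, state$cov, traits = traits)

  rows <- list()
  for (tr in traits) {
    w <- state$ebv_whole$ebv[as.character(focal), tr]
    p <- ebv_partial$ebv[as.character(focal), tr]
    rows[[paste(tr, "MTM")]] <- data.frame(
      trait = tr, model = "MTM",
      t(lr_statistics(w, p, Fbar, sigma_u2[tr], sqrt_acc)),
      t(cor_mse(w, p)), n_focal = length(focal))
    for (fam in intersect(c("ann", "svr", "rfr"), names(state$models))) {
      model <- state$models[[fam]][[tr]]
      if (is.null(model)) {
        warning("no ", toupper(fam), " model for trait ", tr, "; cell omitted")
        next
      }
      pm <- predict(model, state$features_focal[as.character(focal), , drop = FALSE])
      rows[[paste(tr, fam)]] <- data.frame(
        trait = tr, model = toupper(fam),
        t(lr_statistics(w, pm, Fbar, sigma_u2[tr], sqrt_acc)),
        t(cor_mse(w, pm)), n_focal = length(focal))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gait_validation", "data.frame"),
            Fbar = Fbar, sigma_u = sqrt(sigma_u2))
}
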