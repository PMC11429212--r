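# Machine-learning feature matrix: adjusted phenotypes, per-effect OLS fitted
# components, technician dummy variables (most frequent technician dropped),
# and the leading eigenvectors of the relationship matrix, with column
# centering stored for transforming new animals.

#' Technician dummy variables
#'
#' One 0/1 column per technician except the one with the most records (ties
#' broken by the smallest id), which is dropped; a record scored by the
#' dropped technician gets an all-zero dummy row.
#'
#' @param tab phenotype table with `technician_id`.
#' @return list with `dummies` (n x (n_tech - 1) matrix, columns
#'   `tech_<id>`), `dropped` (the dropped id) and `levels` (retained ids in
#'   column order).
#' @export
encode_technicians <- function(tab) {
  id <- tab$technician_id
  cnt <- table(id)
  ids <- names(cnt)
  # most records; ties -> smallest id (numeric order when possible)
  ord <- order(-as.integer(cnt), suppressWarnings(as.numeric(ids)))
  dropped <- ids[ord[1L]]
  kept <- ids[ids != dropped]
  if (!length(kept)) {
    warning("single technician: empty dummy block")
    return(list(dummies = matrix(0, nrow(tab), 0), dropped = dropped,
                levels = character(0)))
  }
  D <- matrix(0, nrow(tab), length(kept),
              dimnames = list(NULL, paste0("tech_", kept)))
  hit <- match(as.character(id), kept)
  ok <- !is.na(hit)
  D[cbind(which(ok), hit[ok])] <- 1
  list(dummies = D, dropped = dropped, levels = kept)
}

#' Assemble the machine-learning feature matrix
#'
#' Horizontal concatenation, in this order: one column per adjusted
#' phenotype; the per-effect fitted components (CG, stud, age-linear,
#' age-quadratic) for each trait; technician dummies; eigenvector
#' coordinates.  Missing adjusted phenotypes are set to zero (the
#' adjusted-phenotype scale is mean-zero) before centering.  Every column is
#' then centered to mean zero; the centering vector is stored so validation
#' animals can be transformed with the training means.
#'
#' @param adj record x trait matrix of adjusted phenotypes (NAs allowed).
#' @param components list per trait of record x 4 component matrices
#'   (as produced by [ols_stage()]).
#' @param dummies technician dummy block from [encode_technicians()].
#' @param eigvecs record-aligned eigenvector coordinates (n x k).
#' @param animals optional id vector used for alignment error messages.
#' @return object of class `gait_features`: `X` (centered), `centers`,
#'   `layout` (block name -> column indices), `dropped_tech`, `tech_levels`.
#' @export
assemble_features <- function(adj, components, dummies, eigvecs, animals = NULL) {
  if (is.list(dummies)) {
    dropped <- dummies$dropped; tech_levels <- dummies$levels
    dummies <- dummies$dummies
  } else {
    dropped <- NA; tech_levels <- colnames(dummies)
  }
  n <- nrow(adj)
  blocks <- list(adj = adj, components = components, dummies = dummies,
                 eigvecs = eigvecs)
  sizes <- c(nrow(adj), vapply(components, nrow, 0L), nrow(dummies), nrow(eigvecs))
  if (length(unique(sizes)) != 1L) {
    bad <- which(sizes != n)[1L]
    who <- if (!is.null(animals)) paste0(" (first animal ", animals[1L], ")") else ""
    stop("feature blocks are not row-aligned", who, ": block ", bad,
         " has ", sizes[bad], " rows, expected ", n)
  }
  traits <- colnames(adj)
  A <- adj
  A[is.na(A)] <- 0
  colnames(A) <- paste0("adj_", traits)
  comp <- do.call(cbind, lapply(traits, function(tr) {
    m <- components[[tr]]
    colnames(m) <- paste0(tr, "_", colnames(m))
    m
  }))
  X <- cbind(A, comp, dummies, eigvecs)
  if (is.null(colnames(eigvecs))) {
    colnames(X)[(ncol(X) - ncol(eigvecs) + 1L):ncol(X)] <-
      paste0("eig", seq_len(ncol(eigvecs)))
  }
  layout <- list(adj = seq_len(ncol(A)),
                 components = ncol(A) + seq_len(ncol(comp)),
                 dummies = ncol(A) + ncol(comp) + seq_len(ncol(dummies)),
                 eigvecs = ncol(A) + ncol(comp) + ncol(dummies) + seq_len(ncol(eigvecs)))
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  structure(list(X = Xc, centers = centers, layout = layout,
                 colnames = colnames(X), dropped_tech = dropped,
                 tech_levels = tech_levels, traits = traits),
            class = "gait_features")
}

#' Transform new animals into an existing feature layout
#'
#' Builds rows with the stored column layout and subtracts the stored
#' training means (no re-centering), so validation rows are expressed on the
#' training scale.  Records scored by a technician unseen in training get an
#' all-zero dummy row with a warning.
#'
#' @param feat `gait_features` object (training layout).
#' @param adj adjusted phenotypes for the new animals (same trait columns).
#' @param components per-trait component matrices for the new animals.
#' @param tech_ids technician ids of the new animals.
#' @param eigvecs eigenvector coordinates for the new animals.
#' @return matrix of transformed rows (training-centered).
#' @export
transform_new <- function(feat, adj, components, tech_ids, eigvecs) {
  n <- nrow(adj)
  A <- adj
  A[is.na(A)] <- 0
  comp <- do.call(cbind, lapply(feat$traits, function(tr) components[[tr]]))
  D <- matrix(0, n, length(feat$tech_levels))
  hit <- match(as.character(tech_ids), feat$tech_levels)
  unknown <- is.na(hit) & !(as.character(tech_ids) %in% feat$dropped_tech)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) scored by technician(s) unseen in training; ",
            "their dummy rows are all zero")
  }
  ok <- !is.na(hit)
  D[cbind(which(ok), hit[ok])] <- 1
  X <- cbind(A, comp, D, eigvecs)
  colnames(X) <- feat$colnames
  sweep(X, 2L, feat$centers)
}
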