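#' Fit a principal component model
#'
#' Column-centers `X` and extracts the leading eigenvectors of its covariance
#' matrix (via [stats::prcomp()]). Loadings follow a fixed sign convention:
#' within each component the largest-magnitude loading is positive, so fitted
#' models are reproducible across platforms. If the matrix rank falls below
#' `n_components` the model is padded with zero-variance components (with a
#' warning).
#'
#' @param X Numeric matrix (rows = observations).
#' @param n_components Number of components to keep; default 2, the standard
#'   projection used by this pipeline.
#' @return An object of class `pca_model`: list with `mean` (column means),
#'   `components` (p x k loading matrix, orthonormal columns), and
#'   `explained_variance` (descending eigenvalues, n-1 divisor).
#' @export
fit_pca <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("fit_pca needs at least 2 rows")
  if (ncol(X) < n_components) stop("X has fewer columns than n_components")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k_avail <- ncol(pc$rotation)
  ev <- pc$sdev^2
  rank_eff <- sum(ev > max(ev[1L], 0) * 1e-12)
  comps <- matrix(0, nrow = ncol(X), ncol = n_components)
  evar <- numeric(n_components)
  k_use <- min(n_components, k_avail, max(rank_eff, 1L))
  comps[, seq_len(k_use)] <- pc$rotation[, seq_len(k_use), drop = FALSE]
  evar[seq_len(k_use)] <- ev[seq_len(k_use)]
  if (rank_eff < n_components) {
    warning(sprintf("rank %d below n_components = %d; padding with zero-variance components",
                    rank_eff, n_components))
    if (k_use > rank_eff) evar[seq(rank_eff + 1L, k_use)] <- 0
  }
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(n_components)) {
    col <- comps[, j]
    if (any(col != 0)) {
      i_max <- which.max(abs(col))
      if (col[i_max] < 0) comps[, j] <- -col
    }
  }
  structure(list(mean = colMeans(X), components = comps,
                 explained_variance = evar),
            class = "pca_model")
}

#' Project data onto a fitted principal component model
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param X Numeric matrix with the same column count the model was fit on.
#' @return An n x k score matrix: `(X - mean) %*% components`.
#' @export
transform_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop(sprintf("dimension mismatch: model fitted on %d columns, X has %d",
                 length(model$mean), ncol(X)))
  }
  sweep(X, 2L, model$mean, "-") %*% model$components
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d -> %d dimensions; explained variance: %s\n",
              length(x$mean), ncol(x$components),
              paste(signif(x$explained_variance, 4), collapse = ", ")))
  invisible(x)
}

#' Rank factors by random-forest Gini importance
#'
#' Fits a seeded random forest ([randomForest::randomForest()]) and orders
#' the factors by decreasing mean decrease in Gini impurity, the standard
#' impurity-based importance. Ties are broken by ascending factor number.
#'
#' @param X Numeric predictor matrix.
#' @param y Binary 0/1 vector.
#' @param n_trees Number of trees; default 500.
#' @param seed Integer seed; rankings are deterministic given it.
#' @param factor_ids 1-based factor numbers labelling the columns of `X`
#'   (default `1:ncol(X)`). Used so rankings refer to the canonical factor
#'   numbering even after columns were dropped upstream.
#' @param target Optional target name recorded on the ranking.
#' @return An object of class `importance_ranking`: list with `target`,
#'   `ordered_factor_ids`, `scores` (matching importance values, descending)
#'   and `source = "recompute"`.
#' @export
rank_importance <- function(X, y, n_trees = 500L, seed = 1L,
                            factor_ids = seq_len(ncol(X)), target = NA_character_) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), length(factor_ids) == ncol(X))
  if (length(unique(y)) < 2L) stop("rank_importance requires both classes present")
  fit <- with_seed(derive_seed(seed, "rf_importance"),
                   randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                                              ntree = n_trees))
  scores <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-scores, factor_ids)
  structure(list(target = target,
                 ordered_factor_ids = as.integer(factor_ids[ord]),
                 scores = unname(scores[ord]),
                 source = "recompute"),
            class = "importance_ranking")
}

#' Packaged random-forest importance rankings
#'
#' Returns the package's reference top-k factor rankings for the four
#' screening-test targets, by their canonical 1-based factor numbers. These
#' are the published orderings this pipeline family uses to define its
#' top-18 and top-10 feature-selection scenarios; the top-10 list is always
#' the prefix of the top-18 list.
#'
#' @param target One of `"Hinselmann"`, `"Schiller"`, `"Cytology"`, `"Biopsy"`.
#' @param k Ranking length, 10 or 18.
#' @return An `importance_ranking` with `source = "fixture"` and no scores.
#' @export
get_fixture_ranking <- function(target, k = 18L) {
  targets <- target_names()
  if (!(is.character(target) && length(target) == 1L && target %in% targets)) {
    stop("unknown target: ", paste(target, collapse = ", "),
         " (expected one of ", paste(targets, collapse = ", "), ")")
  }
  k <- as.integer(k)
  if (!k %in% c(10L, 18L)) stop("k must be 10 or 18")
  tab <- fixture_ranking_table()
  rows <- tab[tab$target == target, , drop = FALSE]
  rows <- rows[order(rows$rank), , drop = FALSE]
  structure(list(target = target,
                 ordered_factor_ids = as.integer(rows$factor_id[seq_len(k)]),
                 scores = NULL,
                 source = "fixture"),
            class = "importance_ranking")
}

fixture_ranking_table <- function() {
  path <- system.file("extdata", "rf_importance_rankings.csv", package = "gamlp")
  if (!nzchar(path)) stop("packaged ranking table not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking (%s, %s): %s\n",
              x$target %||% "?", x$source,
              paste(x$ordered_factor_ids, collapse = ", ")))
  invisible(x)
}

#' Describe a feature-selection mode
#'
#' The pipeline evaluates four modes per target: `pca2` (two-component PCA
#' scores), `all30` (every retained factor), and `top18` / `top10` (the
#' leading factors of a random-forest importance ranking, either the
#' packaged reference ranking or one recomputed from data).
#'
#' @param mode One of `"pca2"`, `"all30"`, `"top18"`, `"top10"`.
#' @param ranking_source `"fixture"` (default) or `"recompute"`; meaningful
#'   only for the top-k modes.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(mode = c("pca2", "all30", "top18", "top10"),
                         ranking_source = c("fixture", "recompute")) {
  mode <- match.arg(mode)
  ranking_source <- match.arg(ranking_source)
  structure(list(mode = mode, ranking_source = ranking_source),
            class = "feature_spec")
}

feature_modes <- function() c("pca2", "all30", "top18", "top10")

#' Apply a feature-selection mode to a dataset
#'
#' @param data A `clean_dataset`, `balanced_dataset`, or plain numeric matrix.
#'   Matrices are assumed to carry factors `1:ncol` unless `factor_ids` says
#'   otherwise.
#' @param spec A [feature_spec()].
#' @param context The fitted context matching the mode: a `pca_model` for
#'   `pca2`, an `importance_ranking` for `top18`/`top10`, nothing for `all30`.
#' @param factor_ids 1-based factor numbers of the columns of `data` (taken
#'   from `retained_factor_ids` for a `clean_dataset`).
#' @return The selected/transformed numeric matrix. For top-k modes, columns
#'   appear in ranking order.
#' @export
select_features <- function(data, spec, context = NULL, factor_ids = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  if (inherits(data, "clean_dataset")) {
    X <- data$X
    factor_ids <- factor_ids %||% data$retained_factor_ids
  } else if (inherits(data, "balanced_dataset")) {
    X <- data$X
  } else {
    X <- as.matrix(data)
  }
  factor_ids <- factor_ids %||% seq_len(ncol(X))
  switch(spec$mode,
    all30 = X,
    pca2 = {
      if (!inherits(context, "pca_model")) stop("pca2 mode needs a pca_model context")
      transform_pca(context, X)
    },
    top18 = ,
    top10 = {
      if (!inherits(context, "importance_ranking")) {
        stop(spec$mode, " mode needs an importance_ranking context")
      }
      k <- if (spec$mode == "top18") 18L else 10L
      ids <- context$ordered_factor_ids
      if (length(ids) < k) stop(sprintf("ranking has %d entries, need %d", length(ids), k))
      ids <- ids[seq_len(k)]
      pos <- match(ids, factor_ids)
      if (anyNA(pos)) {
        stop("ranking refers to factors absent from the data: ",
             paste(ids[is.na(pos)], collapse = ", "))
      }
      X[, pos, drop = FALSE]
    })
}
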