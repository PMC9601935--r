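#' Confusion-matrix counts for a binary screening test
#'
#' Positive class (1) is "disease present". TP/TN are correct positive and
#' negative calls; FP/FN the corresponding errors.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @return An object of class `confusion_counts`: list with `TN`, `FP`,
#'   `FN`, `TP` (integers summing to `length(y_true)`).
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(list(TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L),
                 TP = sum(y_true == 1L & y_pred == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2L, 2L, byrow = TRUE,
              dimnames = list(actual = c("negative", "positive"),
                              predicted = c("negative", "positive")))
  print(m)
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' The five standard screening metrics, each as a percentage:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), and
#' F1 = 2 * sensitivity * precision / (sensitivity + precision).
#' A zero denominator yields 0 with the metric name recorded in the
#' `undefined` field.
#'
#' @param counts A [confusion_counts()] (or list with TN/FP/FN/TP).
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1` (percentages) and
#'   `undefined` (character vector of flagged metrics).
#' @export
compute_metrics <- function(counts) {
  tn <- counts$TN; fp <- counts$FP; fn <- counts$FN; tp <- counts$TP
  total <- tn + fp + fn + tp
  if (total <= 0) stop("all confusion counts are zero")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else {
      num / den * 100
    }
  }
  acc <- (tp + tn) / total * 100
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  f1 <- if (sens + prec == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * sens * prec / (sens + prec)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity", "precision", "f1")])
  cat("metrics (%):\n")
  print(round(v, 2))
  if (length(x$undefined)) cat("undefined (reported as 0):",
                               paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, precision = x$precision,
             f1 = x$f1)
}

#' Cross-validation configuration
#'
#' @param k Number of folds. Default 5, the protocol this pipeline reports.
#' @param stratified Preserve class ratios across folds. Default `TRUE`.
#' @param seed Fold-assignment seed.
#' @param aggregation `"macro_mean"` (average per-fold metrics; default) or
#'   `"pooled_counts"` (sum fold confusion matrices, then compute metrics).
#' @param leakage_mode Where balancing and feature fitting happen relative
#'   to the fold split: `"fold_safe"` (fit on training folds only; default)
#'   or `"paper_global"` (balance and fit features on the full dataset
#'   before splitting, mirroring pipelines that balance upstream of CV —
#'   optimistic because duplicated and transformed rows leak across folds).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k = 5L, stratified = TRUE, seed = 1L,
                      aggregation = c("macro_mean", "pooled_counts"),
                      leakage_mode = c("fold_safe", "paper_global")) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  structure(list(k = k, stratified = isTRUE(stratified), seed = as.integer(seed),
                 aggregation = match.arg(aggregation),
                 leakage_mode = match.arg(leakage_mode)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Assigns each instance to exactly one of `k` test folds. Under
#' stratification, indices are shuffled within class and dealt round-robin,
#' so fold class counts differ by at most one per class.
#'
#' @param y Binary 0/1 vector.
#' @param k Number of folds.
#' @param seed Assignment seed.
#' @param stratified Logical.
#' @return Integer vector of fold ids in `1..k`, one per instance.
#' @export
stratified_folds <- function(y, k, seed = 1L, stratified = TRUE) {
  y <- as.integer(y)
  n <- length(y)
  if (k > n) stop("more folds than instances")
  folds <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  folds
}

#' The classifier registry
#'
#' The ten methods of the experiment grid: the GA-optimised MLP plus nine
#' baselines.
#'
#' @return Character vector of method names.
#' @export
method_registry <- function() {
  c("GA-MLP", "RF", "LDA", "SVM", "LR", "GaussianNB", "KNN", "DT",
    "AdaBoost", "CD-KNN")
}

#' Enumerate the experiment grid
#'
#' The full evaluation design crosses the four screening-test targets with
#' the four feature-selection modes (16 scenarios) and each scenario with
#' every method in the registry (160 experiments), in a deterministic
#' order.
#'
#' @param targets Targets to include. Default all four.
#' @param modes Feature modes to include. Default all four.
#' @param methods Methods to include. Default the full registry.
#' @return A data frame with columns `scenario`, `target`, `feature_mode`,
#'   `method`, one row per experiment; attribute `n_scenarios` carries the
#'   scenario count.
#' @export
enumerate_grid <- function(targets = target_names(), modes = feature_modes(),
                           methods = method_registry()) {
  stopifnot(all(targets %in% target_names()), all(modes %in% feature_modes()),
            all(methods %in% method_registry()))
  grid <- expand.grid(method = methods, feature_mode = modes, target = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("target", "feature_mode", "method")]
  grid$scenario <- paste(grid$target, grid$feature_mode, sep = "/")
  grid <- grid[, c("scenario", "target", "feature_mode", "method")]
  rownames(grid) <- NULL
  attr(grid, "n_scenarios") <- length(unique(grid$scenario))
  grid
}

# Assemble the per-fold train/test matrices for one CV fold under the
# configured leakage placement and feature mode. `prep` carries the
# globally fitted context for paper_global mode.
prepare_fold <- function(X, y, folds, f, cv, fspec, ranking_fixture,
                         factor_ids, target, global_ctx) {
  te <- folds == f
  if (cv$leakage_mode == "paper_global") {
    # X, y, folds here already refer to the balanced, globally transformed data
    list(X_tr = X[!te, , drop = FALSE], y_tr = y[!te],
         X_te = X[te, , drop = FALSE], y_te = y[te])
  } else {
    bal <- oversample(X[!te, , drop = FALSE], y[!te],
                      seed = derive_seed(cv$seed, paste0("bal", f)))
    ctx <- fit_feature_context(bal$X, bal$y, fspec, ranking_fixture, factor_ids,
                               target, seed = derive_seed(cv$seed, paste0("ctx", f)))
    list(X_tr = select_features(bal$X, fspec, ctx, factor_ids = factor_ids),
         y_tr = bal$y,
         X_te = select_features(X[te, , drop = FALSE], fspec, ctx,
                                factor_ids = factor_ids),
         y_te = y[te])
  }
}

fit_feature_context <- function(X, y, fspec, ranking_fixture, factor_ids,
                                target, seed = 1L, n_trees = 500L) {
  switch(fspec$mode,
         all30 = NULL,
         pca2 = fit_pca(X, 2L),
         top18 = ,
         top10 = {
           if (fspec$ranking_source == "fixture") {
             ranking_fixture %||% get_fixture_ranking(target, if (fspec$mode == "top18") 18L else 10L)
           } else {
             rank_importance(X, y, n_trees = n_trees, seed = seed,
                             factor_ids = factor_ids, target = target)
           }
         })
}

#' Cross-validate a classifier under a feature-selection mode
#'
#' Runs the stratified k-fold protocol for one method on one target's data.
#' Under `fold_safe` leakage placement, oversampling, PCA fitting, and
#' importance ranking are fitted on the training folds only and applied to
#' the test fold; under `paper_global`, the dataset is balanced and the
#' feature context fitted once on all data before splitting, so fold
#' metrics are optimistic (duplicates of a test row can sit in the training
#' folds).
#'
#' @param method A registry method name, or `"MLP"` with `genotype` to
#'   evaluate one fixed chromosome (used as the GA's fitness and for the
#'   final report of a GA run).
#' @param X Predictor matrix (preprocessed, unbalanced).
#' @param y Binary 0/1 target vector.
#' @param cv A [cv_config()].
#' @param features A [feature_spec()]. Default all factors.
#' @param factor_ids Canonical factor numbers of the columns of `X`.
#' @param target Target name (used to look up fixture rankings).
#' @param ranking Optional pre-fitted `importance_ranking` to use for top-k
#'   modes instead of refitting/looking up.
#' @param genotype For `method = "MLP"`/`"GA-MLP"`: the chromosome to
#'   evaluate.
#' @param mlp_overrides Named overrides for [mlp_train_config()].
#' @return A `metrics_report` with attributes `fold_metrics` (data frame of
#'   per-fold metrics) and `pooled_counts` (summed `confusion_counts`).
#' @export
cross_validate <- function(method, X, y, cv = cv_config(),
                           features = feature_spec("all30"),
                           factor_ids = seq_len(ncol(X)),
                           target = NA_character_, ranking = NULL,
                           genotype = NULL, mlp_overrides = list()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")

  if (cv$leakage_mode == "paper_global") {
    bal <- oversample(X, y, seed = derive_seed(cv$seed, "bal_global"))
    ctx <- fit_feature_context(bal$X, bal$y, features, ranking, factor_ids,
                               target, seed = derive_seed(cv$seed, "ctx_global"))
    Xw <- select_features(bal$X, features, ctx, factor_ids = factor_ids)
    yw <- bal$y
  } else {
    Xw <- X
    yw <- y
  }
  folds <- stratified_folds(yw, cv$k, seed = cv$seed, stratified = cv$stratified)
  for (f in seq_len(cv$k)) {
    if (length(unique(yw[folds == f])) < 2L && cv$stratified) {
      stop("fold ", f, " is missing a class under stratification")
    }
  }

  fold_counts <- vector("list", cv$k)
  for (f in seq_len(cv$k)) {
    fd <- prepare_fold(Xw, yw, folds, f, cv, features, ranking, factor_ids,
                       target, NULL)
    pred <- fit_predict_method(method, fd$X_tr, fd$y_tr, fd$X_te,
                               seed = derive_seed(cv$seed, paste0("fit", f)),
                               genotype = genotype, mlp_overrides = mlp_overrides)
    fold_counts[[f]] <- confusion_counts(fd$y_te, pred)
  }

  fold_metrics <- do.call(rbind, lapply(fold_counts, function(cc) {
    as.data.frame(compute_metrics(cc))
  }))
  pooled <- structure(list(TN = sum(vapply(fold_counts, `[[`, integer(1), "TN")),
                           FP = sum(vapply(fold_counts, `[[`, integer(1), "FP")),
                           FN = sum(vapply(fold_counts, `[[`, integer(1), "FN")),
                           TP = sum(vapply(fold_counts, `[[`, integer(1), "TP"))),
                      class = "confusion_counts")
  report <- if (cv$aggregation == "pooled_counts") {
    compute_metrics(pooled)
  } else {
    undef <- unique(unlist(lapply(fold_counts, function(cc) compute_metrics(cc)$undefined)))
    structure(c(as.list(colMeans(fold_metrics)), list(undefined = undef)),
              class = "metrics_report")
  }
  attr(report, "fold_metrics") <- fold_metrics
  attr(report, "pooled_counts") <- pooled
  report
}

# Dispatch one train/predict round for a registry method.
fit_predict_method <- function(method, X_tr, y_tr, X_te, seed = 1L,
                               genotype = NULL, mlp_overrides = list()) {
  if (method %in% c("MLP", "GA-MLP")) {
    if (is.null(genotype)) stop("method ", method, " needs a genotype")
    cfg <- do.call(mlp_config_from_genotype,
                   c(list(genotype = genotype, seed = seed), mlp_overrides))
    fit <- train_mlp(cfg, X_tr, y_tr)
    return(predict(fit, X_te))
  }
  baseline_fit_predict(method, X_tr, y_tr, X_te, seed = seed)
}

#' Run one experiment of the grid
#'
#' For `method = "GA-MLP"`, runs the genetic algorithm with fitness =
#' cross-validated accuracy of each chromosome under this experiment's
#' feature mode and leakage placement, then reports the best chromosome's
#' cross-validated metrics. Baseline methods are cross-validated directly.
#'
#' @param target Target name (one of [target_names()]).
#' @param features A [feature_spec()] (or mode string).
#' @param method A registry method name.
#' @param data A `clean_dataset`.
#' @param cv A [cv_config()].
#' @param ga A [ga_config()] (used by GA-MLP only).
#' @param mlp_overrides Named overrides for [mlp_train_config()].
#' @return A `metrics_report`; for GA-MLP it carries attributes `ga_result`
#'   and `best_genotype`. All runs carry attribute `fingerprint`, a list of
#'   every setting needed to reproduce the run.
#' @export
run_experiment <- function(target, features, method, data,
                           cv = cv_config(), ga = ga_config(),
                           mlp_overrides = list()) {
  stopifnot(inherits(data, "clean_dataset"))
  if (is.character(features)) features <- feature_spec(features)
  if (!target %in% names(data$y)) stop("unknown target: ", target)
  if (!method %in% method_registry()) stop("unknown method: ", method)
  X <- data$X
  y <- data$y[[target]]
  fids <- data$retained_factor_ids

  ga_res <- NULL
  if (method == "GA-MLP") {
    fitness_fn <- function(genotype) {
      cross_validate("MLP", X, y, cv = cv, features = features,
                     factor_ids = fids, target = target,
                     genotype = genotype, mlp_overrides = mlp_overrides)$accuracy
    }
    ga_res <- run_ga(ga, fitness_fn)
    report <- cross_validate("MLP", X, y, cv = cv, features = features,
                             factor_ids = fids, target = target,
                             genotype = ga_res$best$genotype,
                             mlp_overrides = mlp_overrides)
    attr(report, "ga_result") <- ga_res
    attr(report, "best_genotype") <- ga_res$best$decoded
  } else {
    report <- cross_validate(method, X, y, cv = cv, features = features,
                             factor_ids = fids, target = target)
  }
  attr(report, "fingerprint") <- list(
    target = target, feature_mode = features$mode,
    ranking_source = features$ranking_source, method = method,
    cv = unclass(cv), ga = if (method == "GA-MLP") unclass(ga),
    mlp_overrides = mlp_overrides)
  report
}
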