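# Baseline classifier registry: one train/predict round per method, all
# seeded. Hyperparameters are the libraries' defaults (recorded in run
# fingerprints); KNN-family methods use k = 5.

baseline_fit_predict <- function(method, X_tr, y_tr, X_te, seed = 1L) {
  X_tr <- as.matrix(X_tr); X_te <- as.matrix(X_te)
  y_tr <- as.integer(y_tr)
  with_seed(derive_seed(seed, method), {
    switch(method,
      RF = predict_rf(X_tr, y_tr, X_te),
      LDA = predict_lda(X_tr, y_tr, X_te),
      SVM = predict_svm(X_tr, y_tr, X_te),
      LR = predict_lr(X_tr, y_tr, X_te),
      GaussianNB = predict_nb(X_tr, y_tr, X_te),
      KNN = predict_knn(X_tr, y_tr, X_te, k = 5L),
      DT = predict_dt(X_tr, y_tr, X_te),
      AdaBoost = predict_adaboost(X_tr, y_tr, X_te),
      `CD-KNN` = predict_cdknn(X_tr, y_tr, X_te, k = 5L),
      stop("unknown baseline method: ", method))
  })
}

predict_rf <- function(X_tr, y_tr, X_te) {
  fit <- randomForest::randomForest(x = X_tr, y = factor(y_tr, levels = c(0L, 1L)))
  as.integer(as.character(predict(fit, X_te)))
}

predict_lda <- function(X_tr, y_tr, X_te) {
  # drop constant columns: lda cannot handle zero within-group variance
  keep <- apply(X_tr, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) return(rep(as.integer(majority_class(y_tr)), nrow(X_te)))
  fit <- tryCatch(
    suppressWarnings(MASS::lda(X_tr[, keep, drop = FALSE], grouping = factor(y_tr))),
    error = function(e) NULL)
  if (is.null(fit)) return(rep(as.integer(majority_class(y_tr)), nrow(X_te)))
  as.integer(as.character(predict(fit, X_te[, keep, drop = FALSE])$class))
}

predict_svm <- function(X_tr, y_tr, X_te) {
  fit <- e1071::svm(X_tr, factor(y_tr, levels = c(0L, 1L)),
                    kernel = "radial", scale = FALSE)
  as.integer(as.character(predict(fit, X_te)))
}

predict_lr <- function(X_tr, y_tr, X_te) {
  df_tr <- as.data.frame(X_tr)
  names(df_tr) <- paste0("x", seq_len(ncol(X_tr)))
  df_tr$.y <- y_tr
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df_tr, family = stats::binomial()))
  df_te <- as.data.frame(X_te)
  names(df_te) <- paste0("x", seq_len(ncol(X_te)))
  p <- suppressWarnings(stats::predict(fit, newdata = df_te, type = "response"))
  as.integer(p > 0.5)
}

predict_nb <- function(X_tr, y_tr, X_te) {
  df_tr <- as.data.frame(X_tr)
  names(df_tr) <- paste0("x", seq_len(ncol(X_tr)))
  fit <- e1071::naiveBayes(df_tr, factor(y_tr, levels = c(0L, 1L)))
  df_te <- as.data.frame(X_te)
  names(df_te) <- names(df_tr)
  as.integer(as.character(predict(fit, df_te)))
}

predict_knn <- function(X_tr, y_tr, X_te, k = 5L) {
  k <- min(k, nrow(X_tr))
  as.integer(as.character(class::knn(X_tr, X_te, factor(y_tr, levels = c(0L, 1L)), k = k)))
}

predict_dt <- function(X_tr, y_tr, X_te) {
  df_tr <- as.data.frame(X_tr)
  names(df_tr) <- paste0("x", seq_len(ncol(X_tr)))
  df_tr$.y <- factor(y_tr, levels = c(0L, 1L))
  fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
  df_te <- as.data.frame(X_te)
  names(df_te) <- paste0("x", seq_len(ncol(X_te)))
  as.integer(as.character(predict(fit, df_te, type = "class")))
}

# Discrete AdaBoost (SAMME) over depth-1 rpart stumps.
predict_adaboost <- function(X_tr, y_tr, X_te, n_rounds = 50L) {
  n <- nrow(X_tr)
  df_tr <- as.data.frame(X_tr)
  names(df_tr) <- paste0("x", seq_len(ncol(X_tr)))
  df_te <- as.data.frame(X_te)
  names(df_te) <- names(df_tr)
  yy <- ifelse(y_tr == 1L, 1, -1)
  w <- rep(1 / n, n)
  score <- numeric(nrow(X_te))
  df_fit <- df_tr
  df_fit$.y <- factor(y_tr, levels = c(0L, 1L))
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(.y ~ ., data = df_fit, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                         minsplit = 2L, xval = 0L))
    pred_tr <- ifelse(predict(stump, df_tr, type = "class") == "1", 1, -1)
    err <- sum(w * (pred_tr != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (err >= 0.5) break
    pred_te <- ifelse(predict(stump, df_te, type = "class") == "1", 1, -1)
    score <- score + alpha * pred_te
    w <- w * exp(-alpha * yy * pred_tr)
    w <- w / sum(w)
  }
  as.integer(score > 0)
}

# Centroid-displacement-based k-NN: among the k nearest training neighbours
# of a query, assign the class whose local centroid moves least when the
# query is added to it. Ties fall back to the larger neighbour count, then
# the lower class label.
predict_cdknn <- function(X_tr, y_tr, X_te, k = 5L) {
  k <- min(k, nrow(X_tr))
  n_te <- nrow(X_te)
  out <- integer(n_te)
  for (i in seq_len(n_te)) {
    q <- X_te[i, ]
    d2 <- colSums((t(X_tr) - q)^2)
    nn <- order(d2)[seq_len(k)]
    cls <- sort(unique(y_tr[nn]))
    disp <- vapply(cls, function(cl) {
      members <- X_tr[nn[y_tr[nn] == cl], , drop = FALSE]
      cen <- colMeans(members)
      cen_aug <- (cen * nrow(members) + q) / (nrow(members) + 1)
      sqrt(sum((cen - cen_aug)^2))
    }, numeric(1))
    counts <- vapply(cls, function(cl) sum(y_tr[nn] == cl), integer(1))
    ord <- order(disp, -counts, cls)
    out[i] <- cls[ord[1L]]
  }
  out
}

majority_class <- function(y) {
  if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
}
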