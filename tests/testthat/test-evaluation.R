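test_that("confusion counts follow the screening-table orientation", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cc[c("TP", "TN", "FP", "FN")], list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(cc2[c("TP", "TN", "FP", "FN")], list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  cc3 <- confusion_counts(c(1, 1, 1, 0, 0, 0, 0, 0), c(1, 1, 0, 1, 0, 0, 0, 0))
  expect_equal(cc3[c("TP", "FN", "FP", "TN")], list(TP = 2L, FN = 1L, FP = 1L, TN = 4L))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 0)), "lengths differ")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("compute_metrics reproduces hand arithmetic and flags degenerate ratios", {
  perfect <- compute_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "precision", "f1")]),
               c(accuracy = 100, sensitivity = 100, specificity = 100,
                 precision = 100, f1 = 100))
  m <- compute_metrics(list(TP = 35, TN = 50, FP = 10, FN = 5))
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 87.5)
  expect_equal(m$specificity, 83.33, tolerance = 1e-4)
  expect_equal(m$precision, 77.78, tolerance = 1e-4)
  expect_equal(m$f1, 82.35, tolerance = 1e-4)
  deg <- compute_metrics(list(TP = 0, FN = 5, FP = 0, TN = 5))
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$precision, 0)
  expect_equal(deg$f1, 0)
  expect_true(all(c("precision", "f1") %in% deg$undefined))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("metric identities hold for random confusion counts", {
  withr::with_seed(31, {
    for (i in 1:50) {
      cc <- list(TN = sample(0:50, 1), FP = sample(0:50, 1),
                 FN = sample(0:50, 1), TP = sample(0:50, 1))
      if (sum(unlist(cc)) == 0) next
      m <- compute_metrics(cc)
      expect_equal(m$accuracy, (cc$TP + cc$TN) / sum(unlist(cc)) * 100,
                   tolerance = 1e-9)
      if (m$sensitivity + m$precision > 0) {
        expect_equal(m$f1,
                     2 * m$sensitivity * m$precision / (m$sensitivity + m$precision),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("stratified folds partition instances and preserve class ratios", {
  y <- rep(c(0L, 1L), each = 50)
  folds <- stratified_folds(y, 5, seed = 2)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100L)
  for (f in 1:5) {
    expect_equal(sum(folds == f), 20L)
    expect_equal(sum(folds == f & y == 1L), 10L)
  }
  # partition: each instance in exactly one test fold (vector assignment)
  expect_true(all(folds %in% 1:5))
  expect_identical(stratified_folds(y, 5, seed = 2), folds)
  expect_error(stratified_folds(y[1:3], 5), "more folds")
})

test_that("the experiment grid enumerates 16 scenarios and 160 experiments", {
  grid <- enumerate_grid()
  expect_equal(nrow(grid), 160L)
  expect_equal(attr(grid, "n_scenarios"), 16L)
  expect_equal(length(unique(grid$scenario)), 16L)
  sub <- enumerate_grid(targets = "Biopsy", modes = "pca2")
  expect_equal(nrow(sub), length(method_registry()))
  expect_error(enumerate_grid(targets = "Foo"), "targets")
})

test_that("pooled-counts aggregation equals metrics of the summed fold matrices", {
  spec <- synthetic_spec(n_rows = 200, prevalence = c(Biopsy = 0.25),
                         signal_factors = list(Biopsy = list(ids = c(2L, 9L),
                                                             effects = c(1.5, 1.5))),
                         seed = 13)
  raw <- generate_synthetic(spec)
  clean <- preprocess(raw, drop_factors = integer(0))
  rep <- cross_validate("KNN", clean$X, clean$y$Biopsy,
                        cv_config(seed = 3, aggregation = "pooled_counts"))
  pooled <- attr(rep, "pooled_counts")
  expect_equal(as.data.frame(rep), as.data.frame(compute_metrics(pooled)))
  expect_equal(pooled$TN + pooled$FP + pooled$FN + pooled$TP, length(clean$y$Biopsy))
})

test_that("all baseline methods produce valid fold-safe CV reports", {
  spec <- synthetic_spec(n_rows = 160, n_factors = 10,
                         prevalence = c(Biopsy = 0.25),
                         signal_factors = list(Biopsy = list(ids = c(2L, 9L),
                                                             effects = c(1.5, 1.5))),
                         seed = 17)
  raw <- generate_synthetic(spec)
  clean <- preprocess(raw, drop_factors = integer(0))
  for (method in setdiff(method_registry(), "GA-MLP")) {
    rep <- cross_validate(method, clean$X, clean$y$Biopsy, cv_config(seed = 5))
    v <- unlist(as.data.frame(rep))
    expect_true(all(v >= 0 & v <= 100), info = method)
  }
})

test_that("global balancing before the split inflates leakage-prone methods", {
  wins <- 0L
  for (s in 1:10) {
    spec <- synthetic_spec(n_rows = 250, prevalence = c(Biopsy = 0.1),
                           signal_factors = list(Biopsy = list(ids = c(2L, 9L),
                                                               effects = c(1, 1))),
                           seed = s)
    raw <- generate_synthetic(spec)
    clean <- preprocess(raw, drop_factors = integer(0))
    a_safe <- cross_validate("KNN", clean$X, clean$y$Biopsy,
                             cv_config(seed = s, leakage_mode = "fold_safe"))$accuracy
    a_glob <- cross_validate("KNN", clean$X, clean$y$Biopsy,
                             cv_config(seed = s, leakage_mode = "paper_global"))$accuracy
    if (a_safe <= a_glob) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("run_experiment dispatches baselines without the GA and is reproducible", {
  spec <- synthetic_spec(n_rows = 150, prevalence = c(Hinselmann = 0.2,
                                                      Schiller = 0.2,
                                                      Cytology = 0.2,
                                                      Biopsy = 0.2),
                         seed = 19)
  raw <- generate_synthetic(spec)
  clean <- preprocess(raw)
  r1 <- run_experiment("Hinselmann", "all30", "RF", clean, cv_config(seed = 4))
  expect_null(attr(r1, "ga_result"))
  expect_s3_class(r1, "metrics_report")
  fp <- attr(r1, "fingerprint")
  expect_equal(fp$method, "RF")
  expect_equal(fp$target, "Hinselmann")
  r2 <- run_experiment("Hinselmann", "all30", "RF", clean, cv_config(seed = 4))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_error(run_experiment("Hinselmann", "all30", "NotAMethod", clean),
               "unknown method")
})

test_that("a scaled-down GA-MLP experiment runs end to end on easy data", {
  sep <- make_separable(160, n_factors = 6, margin = 6, seed = 23)
  # wrap as a clean_dataset with one easy target
  clean <- structure(list(X = sep$X,
                          y = list(Biopsy = sep$y,
                                   Hinselmann = sep$y, Schiller = sep$y,
                                   Cytology = sep$y),
                          retained_factor_ids = 1:6,
                          report = NULL),
                     class = "clean_dataset")
  rep <- run_experiment("Biopsy", "pca2", "GA-MLP", clean,
                        cv = cv_config(seed = 2),
                        ga = ga_config(population_size = 4, generations = 2, seed = 2),
                        mlp_overrides = list(max_iterations = 60))
  expect_s3_class(rep, "metrics_report")
  expect_gte(rep$accuracy, 90)
  ga_res <- attr(rep, "ga_result")
  expect_s3_class(ga_res, "ga_result")
  expect_equal(nrow(ga_res$history), 2L)
})
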