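test_that("the built-in extractor is deterministic and discriminative", {
  const <- ct_slice(matrix(5, 16, 16))
  f <- extract_features(const)
  hist_part <- f[1:32]
  expect_equal(sum(hist_part), 1)
  expect_equal(sum(hist_part > 0), 1L)  # all mass in one bin
  expect_equal(unname(f["sd"]), 0)

  ph <- generate_phantom(tiny_spec(seed = 1))
  expect_identical(extract_features(ph$slice), extract_features(ph$slice))

  # noiseless lung slice has strictly more low-intensity pixels than the
  # matching non-lung slice (oracle: direct pixel count)
  sp0 <- tiny_spec(seed = 2, sigma_noise = 0)
  lung <- generate_phantom(sp0)$slice
  nonlung <- generate_nonlung_phantom(sp0)
  fl <- extract_features(lung)["frac_low"]
  fn <- extract_features(nonlung)["frac_low"]
  expect_gt(fl, fn)
  count_low <- function(s) mean(s$pixels / max(s$pixels) < 0.25)
  expect_equal(unname(fl), count_low(lung))

  expect_error(extract_features(lung, "no_such_extractor"), "unknown")
})

test_that("z-score normaliser learns training statistics and drops constants", {
  X <- matrix(c(2, 4, 6), 3, 1)
  norm <- fit_normalizer(X)
  out <- apply_normalizer(norm, X)
  expect_equal(as.vector(out), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # a held-out vector equal to the training mean maps to 0
  expect_equal(unname(apply_normalizer(norm, 4)), 0)

  # constant features are dropped and recorded
  X2 <- cbind(a = c(1, 2, 3), b = c(7, 7, 7))
  n2 <- fit_normalizer(X2)
  expect_identical(n2$dropped, "b")
  expect_identical(ncol(apply_normalizer(n2, X2)), 1L)

  expect_error(fit_normalizer(matrix(1, 1, 3)), "at least 2")

  # transformed training set: mean 0, population sd 1 per feature
  set.seed(4)
  X3 <- matrix(rnorm(60), 20, 3)
  t3 <- apply_normalizer(fit_normalizer(X3), X3)
  expect_true(all(abs(colMeans(t3)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(t3^2))) - 1 < 1e-9))

  # the fitted normaliser depends on the training set only
  set.seed(5); perm <- sample(nrow(X3))
  expect_identical(fit_normalizer(X3), fit_normalizer(X3))
  expect_equal(fit_normalizer(X3)$mean, fit_normalizer(X3[perm, ])$mean)
})

test_that("random search CV is seeded, stratified, and finds separating models", {
  # linearly separable 2-D toy set
  set.seed(1)
  x <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("nonlung", "lung"), each = 30)

  sp <- hyperparameter_space("svm_linear")
  r1 <- random_search_cv(x, y, sp, k = 5, n_draws = 5, seed = 42)
  r2 <- random_search_cv(x, y, sp, k = 5, n_draws = 5, seed = 42)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$draws, r2$draws)
  expect_equal(r1$cv_accuracy, 1.0)

  one <- random_search_cv(x, y, hyperparameter_space("knn"), k = 5,
                          n_draws = 1, seed = 7)
  expect_identical(nrow(one$draws), 1L)
  expect_true(one$params$k %in% c(1, 3, 5, 7, 9))

  expect_error(random_search_cv(x, rep("lung", 60), sp),
               "stratification")
})

test_that("sampled hyperparameters always lie inside the published ranges", {
  set.seed(3)
  for (fam in c("mlp", "knn", "random_forest", "svm_linear", "svm_poly",
                "svm_rbf")) {
    draws <- sample_hyperparameters(hyperparameter_space(fam), 40)
    for (p in draws) {
      if (fam == "mlp") expect_true(p$size >= 2 && p$size <= 1001)
      if (fam == "knn") expect_true(p$k %in% c(1, 3, 5, 7, 9))
      if (fam == "random_forest") expect_true(p$ntree >= 1 && p$ntree <= 1500)
      if (grepl("svm", fam))
        expect_true(p$cost >= 2^-5 && p$cost <= 2^15)
      if (fam == "svm_poly") expect_true(p$degree %in% c(3, 5, 7, 9))
      if (fam == "svm_rbf")
        expect_true(p$gamma >= 2^-15 && p$gamma <= 2^3)
    }
  }
})

test_that("classification metrics reproduce printed per-combination scores", {
  # published SEN/PREC pairs and their printed F-scores (harmonic mean)
  expect_equal(round(f1_harmonic(97.62, 93.18), 2), 95.35)
  expect_equal(round(f1_harmonic(96.00, 92.31), 2), 94.12)
  expect_equal(round(f1_harmonic(94.00, 92.16), 2), 93.07)

  cm <- classification_metrics(1, 1, 1, 1)
  expect_equal(c(cm$acc, cm$sen, cm$prec, cm$f1), c(50, 50, 50, 50))

  # always-majority prediction on a balanced test set: accuracy 50%
  maj <- classification_metrics(tp = 50, fp = 50, tn = 0, fn = 0)
  expect_equal(maj$acc, 50)

  perfect <- classification_metrics(50, 0, 50, 0)
  expect_equal(c(perfect$acc, perfect$sen, perfect$prec, perfect$spe,
                 perfect$f1), rep(100, 5))

  # undefined ratios are missing, not zero
  expect_true(is.na(classification_metrics(0, 0, 5, 5)$prec))
  expect_true(is.na(classification_metrics(0, 0, 5, 5)$f1))
  expect_true(is.na(classification_metrics(5, 0, 0, 5)$spe))

  # consistency: metrics reproducible from counts to 1e-9 (0-1 scale)
  set.seed(8)
  for (i in 1:20) {
    cts <- as.list(rmultinom(1, 200, c(0.3, 0.2, 0.4, 0.1)))
    names(cts) <- c("tp", "fp", "tn", "fn")
    m <- do.call(classification_metrics, cts)
    expect_lt(abs(m$acc / 100 - (cts$tp + cts$tn) / 200), 1e-9)
    if (cts$tp + cts$fn > 0)
      expect_lt(abs(m$sen / 100 - cts$tp / (cts$tp + cts$fn)), 1e-9)
    if (cts$tp + cts$fp > 0)
      expect_lt(abs(m$prec / 100 - cts$tp / (cts$tp + cts$fp)), 1e-9)
  }
})

test_that("best-combination selection maximises F1 with documented tie-breaks", {
  rep1 <- data.frame(extractor = "histo32", classifier = "knn",
                     acc = 97, f1 = 94.12, params = "{}")
  expect_identical(select_best_combination(rep1)$classifier_family, "knn")

  rep3 <- data.frame(extractor = c("a", "b", "c"),
                     classifier = c("knn", "mlp", "svm_rbf"),
                     acc = c(96, 98.42, 97.63),
                     f1 = c(90, 95.35, 94.12),
                     params = "{}")
  expect_equal(select_best_combination(rep3)$metrics$f1, 95.35)

  tie <- data.frame(extractor = c("a", "a"), classifier = c("knn", "svm_rbf"),
                    acc = c(97, 98), f1 = c(95, 95), params = "{}")
  expect_equal(select_best_combination(tie)$metrics$acc, 98)

  allna <- data.frame(extractor = "a", classifier = "knn", acc = 50,
                      f1 = NA_real_, params = "{}")
  expect_error(select_best_combination(allna), "selection error")
})

test_that("the full gate protocol separates phantom classes and is deterministic", {
  train <- generate_classification_dataset(25, 25, tiny_spec(seed = 3))
  test <- generate_classification_dataset(25, 25, tiny_spec(seed = 30))

  row <- train_and_evaluate(train, test, family = "knn", n_draws = 5, seed = 3)
  expect_gte(row$f1, 95)
  expect_identical(row$tp + row$fp + row$tn + row$fn, 50L)

  row2 <- train_and_evaluate(train, test, family = "knn", n_draws = 5, seed = 3)
  attr(row, "model") <- attr(row, "normalizer") <- NULL
  attr(row2, "model") <- attr(row2, "normalizer") <- NULL
  expect_identical(row, row2)

  # MLP trains within the protocol on a narrowed neuron range
  mrow <- train_and_evaluate(train, test, family = "mlp",
                             space = hyperparameter_space("mlp",
                                                          mlp_neurons = c(2L, 8L)),
                             n_draws = 2, seed = 5)
  expect_gte(mrow$f1, 95)
})

test_that("a trained gate routes phantom slices correctly", {
  train <- generate_classification_dataset(30, 30, tiny_spec(seed = 21))
  gate <- train_gate(train, families = c("bayes", "knn"), n_draws = 3, seed = 2)
  fresh <- generate_classification_dataset(8, 8, tiny_spec(seed = 99))
  pred <- predict_gate(gate, fresh$slices)
  expect_gte(mean(pred == fresh$labels), 0.9)
})
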