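# Phase 1: slice-level lung-presence gate.
#
# Protocol: features are z-score normalised with statistics learned on the
# training set only; hyperparameters are tuned by random search with
# stratified 5-fold cross-validation on the training set (selection by mean
# validation accuracy); the final extractor/classifier combination is chosen
# by the highest test F1 (precision-sensitivity harmonic mean), ties broken
# by accuracy, then lexicographically.

.extractor_registry <- new.env(parent = emptyenv())

#' Register a feature extractor
#'
#' Extractors are plugins mapping a [ct_slice()] to a fixed-length numeric
#' feature vector; deep extractors can be plugged in here without the package
#' shipping any weights. The built-in `"histo32"` extractor is registered at
#' load time.
#'
#' @param id extractor identifier.
#' @param fn function of one argument (a `ct_slice`) returning a numeric
#'   vector of constant length.
#' @param overwrite allow replacing an existing registration.
#' @return `id`, invisibly.
#' @export
register_extractor <- function(id, fn, overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  if (!overwrite && !is.null(.extractor_registry[[id]]))
    stop("extractor already registered: ", id, call. = FALSE)
  assign(id, fn, envir = .extractor_registry)
  invisible(id)
}

#' List registered feature extractors
#' @return character vector of extractor ids.
#' @export
list_extractors <- function() sort(ls(.extractor_registry))

# Built-in deterministic extractor: 32-bin intensity histogram on the
# min-max-normalised slice, plus mean, sd, skewness, excess kurtosis,
# histogram entropy (bits) and the fraction of pixels below a quarter of the
# intensity range (lung fields fall below it, soft tissue does not).
.histo32_extract <- function(slice) {
  v <- as.vector(as_pixels(normalize_intensity(slice, "minmax")))
  breaks <- seq(0, 1, length.out = 33L)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), 32L),
                nbins = 32L) / length(v)
  m <- mean(v); s <- sd(v)
  skew <- if (s > 0) mean((v - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((v - m)^4) / s^4 - 3 else 0
  nz <- h[h > 0]
  entropy <- -sum(nz * log2(nz))
  frac_low <- mean(v < 0.25)
  out <- c(h, m, s, skew, kurt, entropy, frac_low)
  names(out) <- c(sprintf("hist%02d", 1:32), "mean", "sd", "skew", "kurt",
                  "entropy", "frac_low")
  out
}

.onLoad <- function(libname, pkgname) {
  if (is.null(.extractor_registry[["histo32"]]))
    register_extractor("histo32", .histo32_extract)
}

#' Extract a feature vector from a slice
#'
#' @param slice a [ct_slice()].
#' @param extractor_id a registered extractor id (see [list_extractors()]).
#' @return a named numeric vector with attribute `extractor_id`.
#' @export
extract_features <- function(slice, extractor_id = "histo32") {
  fn <- .extractor_registry[[extractor_id]]
  if (is.null(fn)) stop("unknown extractor: ", extractor_id, call. = FALSE)
  v <- fn(slice)
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("extractor returned non-finite features", call. = FALSE)
  attr(v, "extractor_id") <- extractor_id
  v
}

.feature_matrix <- function(slices, extractor_id) {
  t(vapply(slices, function(s) as.numeric(extract_features(s, extractor_id)),
           numeric(length(extract_features(slices[[1L]], extractor_id)))))
}

#' Fit a z-score feature normaliser on the training set
#'
#' Learns per-feature mean and population standard deviation (so the
#' transformed training set has population sd exactly 1). Constant features
#' (sd = 0) are dropped and recorded in `dropped`; applying the normaliser
#' removes them from any vector it transforms, so the test set is mapped
#' with training statistics only.
#'
#' @param x numeric matrix (samples in rows) or list of feature vectors;
#'   at least 2 samples.
#' @return an object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(x) {
  X <- if (is.matrix(x)) x else do.call(rbind, x)
  if (nrow(X) < 2L)
    stop("need at least 2 training vectors to normalise", call. = FALSE)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  keep <- sdv > 0
  structure(list(mean = mu[keep], sd = sdv[keep], keep = which(keep),
                 dropped = colnames(X)[!keep] %||% which(!keep)),
            class = "feature_normalizer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted normaliser to feature vectors
#'
#' @param norm a [fit_normalizer()] result.
#' @param x a numeric vector, matrix (samples in rows) or list of vectors.
#' @return transformed matrix (or vector when `x` was a vector).
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "feature_normalizer"))
  one <- is.numeric(x) && is.null(dim(x))
  X <- if (one) matrix(x, nrow = 1L) else if (is.matrix(x)) x else do.call(rbind, x)
  Xk <- X[, norm$keep, drop = FALSE]
  out <- sweep(sweep(Xk, 2L, norm$mean, "-"), 2L, norm$sd, "/")
  if (one) drop(out) else out
}

#' Hyperparameter search space for one classifier family
#'
#' Ranges follow the published protocol: MLP hidden neurons in
#' `[2, 1001]` (training capped at 4000 iterations or absolute tolerance
#' 1e-3), KNN neighbours in \{1,3,5,7,9\}, at most 1500 random-forest trees,
#' SVM cost `C` in `[2^-5, 2^15]` (log-uniform), polynomial degree in
#' \{3,5,7,9\}, RBF `gamma` in `[2^-15, 2^3]` (log-uniform). Narrower ranges
#' may be supplied; sampled points always lie inside the range given.
#'
#' @param family one of `"bayes"`, `"mlp"`, `"knn"`, `"random_forest"`,
#'   `"svm_linear"`, `"svm_poly"`, `"svm_rbf"`.
#' @param mlp_neurons integer range (min, max) of hidden neurons.
#' @param mlp_maxit,mlp_tol MLP iteration cap and absolute stopping tolerance.
#' @param knn_k candidate neighbour counts.
#' @param rf_max_trees maximum number of trees.
#' @param C_range,gamma_range numeric (min, max), sampled log-uniformly.
#' @param degrees candidate polynomial degrees.
#' @return an object of class `hyperparameter_space`.
#' @export
hyperparameter_space <- function(family = c("bayes", "mlp", "knn",
                                            "random_forest", "svm_linear",
                                            "svm_poly", "svm_rbf"),
                                 mlp_neurons = c(2L, 1001L),
                                 mlp_maxit = 4000L, mlp_tol = 1e-3,
                                 knn_k = c(1L, 3L, 5L, 7L, 9L),
                                 rf_max_trees = 1500L,
                                 C_range = c(2^-5, 2^15),
                                 gamma_range = c(2^-15, 2^3),
                                 degrees = c(3L, 5L, 7L, 9L)) {
  family <- match.arg(family)
  structure(list(family = family, mlp_neurons = mlp_neurons,
                 mlp_maxit = mlp_maxit, mlp_tol = mlp_tol, knn_k = knn_k,
                 rf_max_trees = rf_max_trees, C_range = C_range,
                 gamma_range = gamma_range, degrees = degrees),
            class = "hyperparameter_space")
}

.log_unif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# Draw n hyperparameter settings from the space (uses the current RNG state).
sample_hyperparameters <- function(space, n_draws) {
  f <- space$family
  lapply(seq_len(n_draws), function(i) {
    switch(f,
      bayes = list(),
      mlp = list(size = sample(space$mlp_neurons[1]:space$mlp_neurons[2], 1L),
                 maxit = space$mlp_maxit, abstol = space$mlp_tol),
      knn = list(k = sample(space$knn_k, 1L)),
      random_forest = list(ntree = sample.int(space$rf_max_trees, 1L)),
      svm_linear = list(cost = .log_unif(1L, space$C_range)),
      svm_poly = list(cost = .log_unif(1L, space$C_range),
                      degree = sample(space$degrees, 1L)),
      svm_rbf = list(cost = .log_unif(1L, space$C_range),
                     gamma = .log_unif(1L, space$gamma_range)))
  })
}

.fit_classifier <- function(family, params, x, y, fit_seed = 0L) {
  y <- factor(y, levels = c("nonlung", "lung"))
  df <- as.data.frame(x)
  fit <- local_seed(fit_seed, switch(family,
    bayes = e1071::naiveBayes(x = df, y = y),
    mlp = nnet::nnet(x = x, y = cbind(lung = as.numeric(y == "lung")),
                     size = params$size, maxit = params$maxit,
                     abstol = params$abstol, entropy = TRUE, trace = FALSE,
                     MaxNWts = 1e6),
    knn = list(train = x, cl = y, k = params$k),
    random_forest = randomForest::randomForest(x = df, y = y,
                                               ntree = params$ntree),
    svm_linear = e1071::svm(x = x, y = y, kernel = "linear",
                            cost = params$cost, scale = FALSE),
    svm_poly = e1071::svm(x = x, y = y, kernel = "polynomial",
                          degree = params$degree, cost = params$cost,
                          scale = FALSE),
    svm_rbf = e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                         gamma = params$gamma, scale = FALSE)))
  structure(list(family = family, params = params, fit = fit),
            class = "gate_classifier")
}

.predict_classifier <- function(model, x) {
  fit <- model$fit
  out <- switch(model$family,
    bayes = as.character(predict(fit, as.data.frame(x))),
    mlp = ifelse(drop(predict(fit, x)) >= 0.5, "lung", "nonlung"),
    knn = as.character(class::knn(fit$train, x, fit$cl, k = fit$k)),
    random_forest = as.character(predict(fit, as.data.frame(x))),
    svm_linear = ,
    svm_poly = ,
    svm_rbf = as.character(predict(fit, x)))
  out
}

#' Random-search hyperparameter tuning with stratified k-fold CV
#'
#' Draws `n_draws` hyperparameter settings from the space and scores each by
#' the mean validation accuracy over `k` stratified folds (each fold's
#' normaliser is fitted on that fold's training portion only). The draw with
#' the highest mean validation accuracy wins; ties go to the earliest draw.
#' Fully deterministic given `seed`.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y labels, `"lung"`/`"nonlung"`; both classes must be present at
#'   least `k` times.
#' @param space a [hyperparameter_space()].
#' @param k number of folds.
#' @param n_draws number of random draws (>= 1).
#' @param seed RNG seed.
#' @return a list with `params` (best draw), `cv_accuracy`, and `draws`
#'   (data frame of every draw with its mean validation accuracy).
#' @export
random_search_cv <- function(x, y, space, k = 5L, n_draws = 60L, seed = 0L) {
  stopifnot(inherits(space, "hyperparameter_space"), n_draws >= 1)
  y <- as.character(y)
  classes <- c("nonlung", "lung")
  if (!all(classes %in% y))
    stop("stratification error: a class is absent from the data", call. = FALSE)
  if (min(table(y)) < k)
    stop("stratification error: a class has fewer samples than folds",
         call. = FALSE)

  fold <- integer(length(y))
  local_seed(derive_seed(seed, 1L), {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  draws <- local_seed(derive_seed(seed, 2L),
                      sample_hyperparameters(space, n_draws))

  acc <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      norm <- fit_normalizer(x[tr, , drop = FALSE])
      xtr <- apply_normalizer(norm, x[tr, , drop = FALSE])
      xva <- apply_normalizer(norm, x[!tr, , drop = FALSE])
      model <- .fit_classifier(space$family, draws[[d]], xtr, y[tr],
                               fit_seed = derive_seed(seed, 100L + d * k + f))
      fold_acc[f] <- mean(.predict_classifier(model, xva) == y[!tr])
    }
    acc[d] <- mean(fold_acc)
  }
  best <- which.max(acc)  # first index on ties
  list(params = draws[[best]], cv_accuracy = acc[best],
       draws = data.frame(draw = seq_len(n_draws), cv_accuracy = acc,
                          params = vapply(draws, function(p)
                            as.character(jsonlite::toJSON(p, auto_unbox = TRUE,
                                                          digits = NA)),
                            character(1))))
}

#' F1 score as the precision-sensitivity harmonic mean
#'
#' @param prec,sen precision and sensitivity, both on the same scale
#'   (fraction or percent).
#' @return F1 on that scale; `NA` if either input is `NA`; 0 when both are 0.
#' @export
f1_harmonic <- function(prec, sen) {
  if (is.na(prec) || is.na(sen)) return(NA_real_)
  if (prec + sen == 0) return(0)
  2 * prec * sen / (prec + sen)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, precision, specificity and F1 as percentages, with
#' the counts retained. F1 is the harmonic mean of precision and sensitivity
#' (the definition consistent with published per-combination score tables).
#' Undefined ratios (e.g. precision with no positive predictions, or
#' sensitivity/specificity on a single-class test set) are reported as `NA`,
#' never as 0.
#'
#' @param tp,fp,tn,fn nonnegative counts, positive class = lung.
#' @return a one-row data frame with columns `acc`, `sen`, `prec`, `spe`,
#'   `f1` (percent) and `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  acc <- (tp + tn) / n
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- f1_harmonic(prec, sen)
  data.frame(acc = 100 * acc, sen = 100 * sen, prec = 100 * prec,
             spe = 100 * spe, f1 = 100 * f1, tp = tp, fp = fp, tn = tn,
             fn = fn)
}

#' Train one extractor/classifier combination and score it on the test set
#'
#' Implements the full per-combination protocol: extract features, tune the
#' classifier by [random_search_cv()] on the training set, z-score normalise
#' with training statistics only, refit on the whole training set and report
#' test-set [classification_metrics()].
#'
#' @param train,test labelled datasets as returned by
#'   [generate_classification_dataset()] (lists with `slices` and `labels`);
#'   must be disjoint.
#' @param extractor_id registered extractor id.
#' @param family classifier family (see [hyperparameter_space()]).
#' @param space optional [hyperparameter_space()]; default the family's
#'   published ranges.
#' @param k,n_draws,seed tuning protocol controls.
#' @return a one-row data frame report row (metrics, counts, CV accuracy,
#'   chosen hyperparameters as JSON) with the fitted model and normaliser
#'   attached as attributes `model` and `normalizer`.
#' @export
train_and_evaluate <- function(train, test, extractor_id = "histo32",
                               family = "knn", space = NULL, k = 5L,
                               n_draws = 60L, seed = 0L) {
  if (is.null(space)) space <- hyperparameter_space(family)
  stopifnot(identical(space$family, family))
  xtr <- .feature_matrix(train$slices, extractor_id)
  xte <- .feature_matrix(test$slices, extractor_id)
  ytr <- as.character(train$labels); yte <- as.character(test$labels)

  tuned <- random_search_cv(xtr, ytr, space, k = k, n_draws = n_draws,
                            seed = seed)
  norm <- fit_normalizer(xtr)
  model <- .fit_classifier(family, tuned$params, apply_normalizer(norm, xtr),
                           ytr, fit_seed = derive_seed(seed, 999L))
  pred <- .predict_classifier(model, apply_normalizer(norm, xte))

  cm <- classification_metrics(tp = sum(pred == "lung" & yte == "lung"),
                               fp = sum(pred == "lung" & yte == "nonlung"),
                               tn = sum(pred == "nonlung" & yte == "nonlung"),
                               fn = sum(pred == "nonlung" & yte == "lung"))
  row <- cbind(data.frame(extractor = extractor_id, classifier = family),
               cm,
               data.frame(cv_accuracy = 100 * tuned$cv_accuracy,
                          params = as.character(jsonlite::toJSON(tuned$params,
                                                auto_unbox = TRUE, digits = NA))))
  attr(row, "model") <- model
  attr(row, "normalizer") <- norm
  row
}

#' Evaluate every extractor/classifier combination
#'
#' @param train,test labelled datasets (see [train_and_evaluate()]).
#' @param extractors character vector of registered extractor ids.
#' @param families character vector of classifier families.
#' @param k,n_draws,seed protocol controls, applied per combination with
#'   per-combination derived seeds.
#' @return a list with `report` (one row per combination) and `fits` (named
#'   list of `model`/`normalizer` pairs keyed `extractor/classifier`).
#' @export
run_gate_protocol <- function(train, test, extractors = "histo32",
                              families = c("bayes", "knn", "random_forest",
                                           "svm_linear", "svm_rbf"),
                              k = 5L, n_draws = 60L, seed = 0L) {
  rows <- list(); fits <- list()
  i <- 0L
  for (ex in extractors) for (fam in families) {
    i <- i + 1L
    row <- train_and_evaluate(train, test, extractor_id = ex, family = fam,
                              k = k, n_draws = n_draws,
                              seed = derive_seed(seed, i))
    fits[[paste(ex, fam, sep = "/")]] <-
      list(model = attr(row, "model"), normalizer = attr(row, "normalizer"))
    attr(row, "model") <- NULL; attr(row, "normalizer") <- NULL
    rows[[i]] <- row
  }
  list(report = do.call(rbind, rows), fits = fits)
}

#' Select the best extractor/classifier combination from a report table
#'
#' The winning row maximises F1; ties are broken by higher accuracy, then by
#' lexicographic extractor id, then classifier name.
#'
#' @param report data frame as produced by [run_gate_protocol()] (columns
#'   `extractor`, `classifier`, `acc`, `f1`, ...).
#' @return a list with `extractor_id`, `classifier_family`, `params`,
#'   `metrics` (the winning row) and `report` (the full table).
#' @export
select_best_combination <- function(report) {
  if (is.list(report) && !is.data.frame(report)) report <- report$report
  if (is.null(report) || nrow(report) == 0)
    stop("empty report", call. = FALSE)
  if (all(is.na(report$f1)))
    stop("selection error: F1 missing for every row", call. = FALSE)
  ord <- order(-report$f1, -report$acc, report$extractor, report$classifier,
               na.last = TRUE)
  best <- report[ord[1L], , drop = FALSE]
  list(extractor_id = best$extractor, classifier_family = best$classifier,
       params = jsonlite::fromJSON(best$params), metrics = best,
       report = report)
}

#' Train the lung-presence gate end to end
#'
#' Runs [run_gate_protocol()] and [select_best_combination()], returning a
#' ready-to-use gate: the selected extractor, its training normaliser and the
#' fitted classifier.
#'
#' @inheritParams run_gate_protocol
#' @param test optional held-out labelled set; when `NULL`, a stratified
#'   80/20 split of `train` is used for selection.
#' @return an object of class `lung_gate`.
#' @export
train_gate <- function(train, test = NULL, extractors = "histo32",
                       families = c("bayes", "knn", "random_forest",
                                    "svm_linear", "svm_rbf"),
                       k = 5L, n_draws = 60L, seed = 0L) {
  if (is.null(test)) {
    y <- as.character(train$labels)
    test_idx <- local_seed(derive_seed(seed, 77L), {
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(0.2 * length(idx))))
      }))
    })
    subset_ds <- function(ds, idx)
      list(slices = ds$slices[idx], labels = ds$labels[idx])
    test <- subset_ds(train, test_idx)
    train <- subset_ds(train, setdiff(seq_along(y), test_idx))
  }
  prot <- run_gate_protocol(train, test, extractors = extractors,
                            families = families, k = k, n_draws = n_draws,
                            seed = seed)
  sel <- select_best_combination(prot$report)
  fit <- prot$fits[[paste(sel$extractor_id, sel$classifier_family, sep = "/")]]
  structure(list(extractor_id = sel$extractor_id,
                 classifier_family = sel$classifier_family,
                 params = sel$params, normalizer = fit$normalizer,
                 model = fit$model, selection = sel),
            class = "lung_gate")
}

#' @export
print.lung_gate <- function(x, ...) {
  cat(sprintf("<lung_gate> %s + %s (test F1 %.2f%%, acc %.2f%%)\n",
              x$extractor_id, x$classifier_family,
              x$selection$metrics$f1, x$selection$metrics$acc))
  invisible(x)
}

#' Classify slices with a trained gate
#'
#' @param gate a [train_gate()] result.
#' @param slices a single [ct_slice()] or a list of them.
#' @return character vector of `"lung"`/`"nonlung"` labels.
#' @export
predict_gate <- function(gate, slices) {
  stopifnot(inherits(gate, "lung_gate"))
  if (inherits(slices, "ct_slice")) slices <- list(slices)
  x <- .feature_matrix(slices, gate$extractor_id)
  .predict_classifier(gate$model, apply_normalizer(gate$normalizer, x))
}
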