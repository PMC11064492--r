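# In-package k-nearest-neighbours baseline plus a uniform contract over
# established classifier implementations, and the leakage-aware
# cross-validation driver.

.KNN_EPS <- 1e-12  # added to distances in inverse-distance weights

#' Fit the k-nearest-neighbours baseline
#'
#' KNN over binary pair vectors is the simplest supervised classifier for
#' this problem and serves as the reference baseline. Distances are either
#' Euclidean or cosine on the raw 0/1 vectors; votes are uniform or weighted
#' by inverse distance (`1/(d + 1e-12)`).
#'
#' @param x Numeric/integer matrix of training vectors (one per row).
#' @param y Character vector of labels (`"cross_feeding"` /
#'   `"competition"`).
#' @param k Number of neighbours (default 3).
#' @param metric `"euclidean"` or `"cosine"`.
#' @param weighting `"uniform"` or `"distance"`.
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(x, y, k = 3L, metric = c("euclidean", "cosine"),
                    weighting = c("uniform", "distance")) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!all(y %in% .LABELS)) {
    stop("labels must be one of: ", paste(.LABELS, collapse = ", "),
         call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) {
    stop("k must be in [1, ", nrow(x), "]", call. = FALSE)
  }
  structure(list(x = x, y = y, k = k, metric = metric,
                 weighting = weighting, row_norms = sqrt(rowSums(x^2))),
            class = "knn_model")
}

# Distances are snapped to 12 significant digits before ranking so that
# exact ties (frequent on binary data) are detected identically regardless
# of the floating-point summation order of the underlying BLAS; ties are
# then resolved by stable training-row order.
.snap <- function(d) signif(d, 12)

# Distance matrix queries x training, chunk-free (callers chunk queries).
.knn_dist <- function(model, q) {
  g <- tcrossprod(q, model$x)
  if (model$metric == "euclidean") {
    d2 <- outer(rowSums(q^2), rep(1, nrow(model$x))) +
      outer(rep(1, nrow(q)), model$row_norms^2) - 2 * g
    sqrt(pmax(d2, 0))
  } else {
    qn <- sqrt(rowSums(q^2))
    if (any(qn == 0) || any(model$row_norms == 0)) {
      stop("cosine distance undefined for all-zero vectors", call. = FALSE)
    }
    1 - g / outer(qn, model$row_norms)
  }
}

#' Predict with a fitted KNN model
#'
#' The score is the (possibly distance-weighted) fraction of the k nearest
#' training vectors labelled cross-feeding; the label is cross-feeding when
#' the score reaches `threshold`. Distance ties at the k-th neighbour are
#' resolved by stable training-row order; an exact vote tie predicts
#' cross-feeding (the majority class under the curated prevalence).
#'
#' @param object A `knn_model`.
#' @param newx Matrix of query vectors (one per row) of the training width.
#' @param threshold Decision threshold on the cross-feeding score
#'   (default 0.5).
#' @param chunk Queries are scored in blocks of this many rows.
#' @param ... Unused.
#' @return Data frame with columns `score` (probability of cross-feeding)
#'   and `label`.
#' @export
predict.knn_model <- function(object, newx, threshold = 0.5, chunk = 512L,
                              ...) {
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  if (ncol(newx) != ncol(object$x)) {
    stop("query width ", ncol(newx), " does not match training width ",
         ncol(object$x), call. = FALSE)
  }
  is_cf <- object$y == .CF
  n <- nrow(newx)
  score <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- .snap(.knn_dist(object, newx[idx, , drop = FALSE]))
    for (i in seq_along(idx)) {
      nb <- order(d[i, ])[seq_len(object$k)]  # stable: ties by row order
      if (object$weighting == "uniform") {
        score[idx[i]] <- mean(is_cf[nb])
      } else {
        w <- 1 / (d[i, nb] + .KNN_EPS)
        score[idx[i]] <- sum(w * is_cf[nb]) / sum(w)
      }
    }
  }
  data.frame(score = score,
             label = ifelse(score >= threshold, .CF, .CO),
             stringsAsFactors = FALSE)
}

#' Describe a classifier for the comparison suite
#'
#' One contract covers the in-package KNN baseline and adapters over
#' established implementations: random forest (randomForest), support
#' vector machines with linear/RBF/polynomial/sigmoid kernels (e1071) and
#' gradient boosting (xgboost).
#'
#' @param family One of `"knn"`, `"random_forest"`, `"svm_linear"`,
#'   `"svm_rbf"`, `"svm_poly"`, `"svm_sigmoid"`, `"gradient_boosting"`.
#' @param hyperparameters Named list (e.g. `list(k = 3, metric =
#'   "euclidean")` for KNN, `list(nrounds = 100)` for gradient boosting).
#' @param seed Integer seed; mandatory for every family except `knn`
#'   (stochastic training, and SVM probability calibration uses internal
#'   random splits).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "random_forest", "svm_linear",
                                       "svm_rbf", "svm_poly", "svm_sigmoid",
                                       "gradient_boosting"),
                            hyperparameters = list(), seed = NULL) {
  family <- match.arg(family)
  if (family != "knn" && is.null(seed)) {
    stop("seed is mandatory for stochastic family ", dQuote(family),
         call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = seed),
            class = "classifier_spec")
}

.SVM_KERNELS <- c(svm_linear = "linear", svm_rbf = "radial",
                  svm_poly = "polynomial", svm_sigmoid = "sigmoid")

# Fit the requested family on a label/feature matrix. Missing optional
# engines raise an explicit capability error rather than falling back.
fit_engine <- function(spec, x, y) {
  hp <- spec$hyperparameters
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yf <- factor(y, levels = .LABELS)
  fit <- switch(
    spec$family,
    knn = knn_fit(x, y, k = hp$k %||% 3L,
                  metric = hp$metric %||% "euclidean",
                  weighting = hp$weighting %||% "uniform"),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("family 'random_forest' needs the randomForest package",
             call. = FALSE)
      }
      set.seed(spec$seed)
      randomForest::randomForest(x = x, y = yf,
                                 ntree = hp$ntree %||% 500L)
    },
    gradient_boosting = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("family 'gradient_boosting' needs the xgboost package",
             call. = FALSE)
      }
      set.seed(spec$seed)
      dtrain <- xgboost::xgb.DMatrix(data = x,
                                     label = as.numeric(y == .CF))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 6L,
                      eta = hp$eta %||% 0.3,
                      nthread = 1L,
                      seed = spec$seed),
        data = dtrain,
        nrounds = hp$nrounds %||% 100L,
        verbose = 0)
    },
    {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("family '", spec$family, "' needs the e1071 package",
             call. = FALSE)
      }
      set.seed(spec$seed)
      e1071::svm(x = x, y = yf, kernel = .SVM_KERNELS[[spec$family]],
                 cost = hp$cost %||% 1, probability = TRUE, scale = FALSE)
    }
  )
  structure(list(spec = spec, fit = fit, width = ncol(x)),
            class = "interaction_model")
}

# Cross-feeding probability for query rows under a fitted engine.
score_engine <- function(model, newx) {
  newx <- as.matrix(newx)
  storage.mode(newx) <- "double"
  if (ncol(newx) != model$width) {
    stop("query width does not match the fitted model", call. = FALSE)
  }
  switch(
    model$spec$family,
    knn = predict(model$fit, newx)$score,
    random_forest =
      unname(predict(model$fit, newx, type = "prob")[, .CF]),
    gradient_boosting =
      as.numeric(predict(model$fit, xgboost::xgb.DMatrix(newx))),
    {
      pr <- predict(model$fit, newx, probability = TRUE)
      unname(attr(pr, "probabilities")[, .CF])
    }
  )
}

#' Train a classifier on a full pair dataset
#'
#' @param spec A [classifier_spec()].
#' @param dataset A `pair_dataset`.
#' @return An object of class `interaction_model` carrying the fitted
#'   engine and the dataset's pool hash (predictions on profiles from a
#'   different pool are refused).
#' @export
train_classifier <- function(spec, dataset) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(dataset, "pair_dataset"))
  model <- fit_engine(spec, dataset$x, dataset$label)
  model$pool_hash <- dataset$pool_hash
  model
}

#' Leakage-aware cross-validation of one classifier
#'
#' For every fold, trains on all other folds and predicts the fold's
#' oriented vectors; predictions and confusion counts are pooled over folds
#' (per-fold averaging of metrics is available downstream via
#' [panel_from_counts()] on per-fold counts). The fold assignment is audited
#' first and any orientation leakage aborts the run.
#'
#' @param spec A [classifier_spec()].
#' @param dataset A `pair_dataset`.
#' @param folds A `fold_assignment` covering the dataset.
#' @param threshold Decision threshold on the cross-feeding score.
#' @return An object of class `cv_result`: `predictions` (data frame with
#'   `pair_key`, `first_id`, `second_id`, `fold`, `truth`, `score`,
#'   `label`), pooled `counts` (a `confusion_counts`), and `panel`.
#' @export
cross_validate <- function(spec, dataset, folds, threshold = 0.5) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(dataset, "pair_dataset"),
            inherits(folds, "fold_assignment"))
  audit <- audit_leakage(folds, dataset)
  if (nrow(audit) > 0L) {
    stop("fold assignment fails the leakage audit (", nrow(audit),
         " issue(s)); refusing to cross-validate", call. = FALSE)
  }
  vec_fold <- fold_of_vectors(folds, dataset)
  n <- nrow(dataset$x)
  score <- numeric(n)
  for (f in seq_len(folds$n_folds)) {
    test <- which(vec_fold == f)
    train <- which(vec_fold != f)
    if (length(test) == 0L) next
    model <- fit_engine(spec, dataset$x[train, , drop = FALSE],
                        dataset$label[train])
    score[test] <- score_engine(model, dataset$x[test, , drop = FALSE])
  }
  label <- ifelse(score >= threshold, .CF, .CO)
  predictions <- data.frame(
    pair_key = dataset$pair_key, first_id = dataset$first_id,
    second_id = dataset$second_id, fold = vec_fold,
    truth = dataset$label, score = score, label = label,
    stringsAsFactors = FALSE)
  counts <- counts_from_predictions(predictions$truth, predictions$label)
  structure(list(spec = spec, predictions = predictions, counts = counts,
                 panel = panel_from_counts(counts)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$spec$family, "\n", sep = "")
  print(x$counts)
  print(x$panel)
  invisible(x)
}

#' Select k for the KNN baseline on a held-out split
#'
#' Evaluates candidate neighbour counts on a single train/test split that
#' keeps both orientations of a pair on the same side, optionally on a
#' random subsample of pairs. Returns the accuracy-maximising k, ties broken
#' toward smaller k, plus the full accuracy-versus-k table.
#'
#' @param dataset A `pair_dataset`.
#' @param k_values Candidate k values (default 1:30).
#' @param train_fraction Fraction of pairs used for training (default 0.67).
#' @param subset_fraction Fraction of pairs to subsample before splitting
#'   (default 1; 0.1 mimics tuning on a 10% sample).
#' @param metric,weighting Passed to [knn_fit()].
#' @param seed Integer seed for the subsample and split.
#' @return List with `best_k` and `accuracy` (data frame `k`, `accuracy`).
#' @export
select_k <- function(dataset, k_values = 1:30, train_fraction = 0.67,
                     subset_fraction = 1, metric = "euclidean",
                     weighting = "uniform", seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  keys <- unique(dataset$pair_key)
  set.seed(sub_seed(seed, "select_k"))
  if (subset_fraction < 1) {
    keys <- sample(keys, max(2L, round(subset_fraction * length(keys))))
  }
  n_train <- round(train_fraction * length(keys))
  if (n_train < 1L || n_train >= length(keys)) {
    stop("train_fraction leaves an empty train or test side", call. = FALSE)
  }
  train_keys <- sample(keys, n_train)
  train_rows <- which(dataset$pair_key %in% train_keys)
  test_rows <- which(dataset$pair_key %in% setdiff(keys, train_keys))
  if (max(k_values) > length(train_rows)) {
    stop("largest k (", max(k_values), ") exceeds the training size (",
         length(train_rows), ")", call. = FALSE)
  }
  xtr <- dataset$x[train_rows, , drop = FALSE]
  ytr <- dataset$label[train_rows]
  xte <- dataset$x[test_rows, , drop = FALSE]
  yte <- dataset$label[test_rows]
  # one distance computation, reused across k
  base <- knn_fit(xtr, ytr, k = 1L, metric = metric, weighting = weighting)
  d <- .snap(.knn_dist(base, {
    q <- as.matrix(xte); storage.mode(q) <- "double"; q
  }))
  is_cf <- ytr == .CF
  acc <- vapply(k_values, function(k) {
    correct <- 0L
    for (i in seq_len(nrow(d))) {
      nb <- order(d[i, ])[seq_len(k)]
      if (weighting == "uniform") {
        s <- mean(is_cf[nb])
      } else {
        w <- 1 / (d[i, nb] + .KNN_EPS)
        s <- sum(w * is_cf[nb]) / sum(w)
      }
      pred <- if (s >= 0.5) .CF else .CO
      correct <- correct + (pred == yte[i])
    }
    correct / nrow(d)
  }, numeric(1))
  best_k <- k_values[which.max(acc)]  # which.max: first max -> smallest k
  list(best_k = as.integer(best_k),
       accuracy = data.frame(k = as.integer(k_values), accuracy = acc))
}

#' Orientation-invariant prediction for one pair of organisms
#'
#' Scores both concatenation orders (A then B, and B then A) and averages,
#' so the returned score and label do not depend on argument order.
#'
#' @param model An `interaction_model` from [train_classifier()].
#' @param a,b `organism_profile` objects on the model's pool.
#' @param threshold Decision threshold on the mean cross-feeding score.
#' @return List with `label`, `score`, and the two per-orientation scores.
#' @export
predict_pair <- function(model, a, b, threshold = 0.5) {
  stopifnot(inherits(model, "interaction_model"),
            inherits(a, "organism_profile"),
            inherits(b, "organism_profile"))
  if (!is.null(model$pool_hash) &&
      (!identical(a$pool_hash, model$pool_hash) ||
       !identical(b$pool_hash, model$pool_hash))) {
    stop("profiles were encoded on a different pool than the model",
         call. = FALSE)
  }
  q <- rbind(c(a$bits, b$bits), c(b$bits, a$bits))
  s <- score_engine(model, q)
  score <- mean(s)
  list(label = if (score >= threshold) .CF else .CO, score = score,
       orientation_scores = s)
}

#' Predict all unordered pairs of a profile collection
#'
#' Applies [predict_pair()] to every unordered pair of the supplied
#' profiles: m organisms yield exactly `choose(m, 2)` predictions.
#'
#' @param model An `interaction_model`.
#' @param profiles Named list of `organism_profile` objects.
#' @param threshold Decision threshold.
#' @return Data frame with `organism_a`, `organism_b`, `score`, `label`.
#' @export
predict_all_pairs <- function(model, profiles, threshold = 0.5) {
  ids <- names(profiles)
  stopifnot(length(ids) >= 2L)
  idx <- combn(length(ids), 2L)
  # score both orientations of every pair in one pass
  q <- matrix(0L, nrow = 2L * ncol(idx), ncol = 2L * length(profiles[[1]]$bits))
  for (j in seq_len(ncol(idx))) {
    a <- profiles[[idx[1, j]]]$bits
    b <- profiles[[idx[2, j]]]$bits
    q[2L * j - 1L, ] <- c(a, b)
    q[2L * j, ] <- c(b, a)
  }
  s <- score_engine(model, q)
  score <- (s[seq(1L, length(s), 2L)] + s[seq(2L, length(s), 2L)]) / 2
  data.frame(organism_a = ids[idx[1, ]], organism_b = ids[idx[2, ]],
             score = score,
             label = ifelse(score >= threshold, .CF, .CO),
             stringsAsFactors = FALSE)
}
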