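# Task classification: feature-table assembly, the seven-classifier roster,
# leave-one-subject-out cross-validation, exhaustive feature-subset search,
# and temporal generalization from trial 1 to later trials.

#' Classifier specification
#'
#' The seven families evaluated: 1-nearest-neighbor (Euclidean, on
#' standardized features), linear and Gaussian-kernel SVM (C = 1; gamma =
#' 2.6 for the Gaussian kernel, `exp(-gamma ||x - x'||^2)` convention),
#' CART decision tree, and linear, quadratic and Mahalanobis-distance
#' quadratic discriminant analysis (uniform priors).
#'
#' @param family One of `"KNN"`, `"LSVM"`, `"GSVM"`, `"TREE"`, `"LDA"`,
#'   `"QDA"`, `"MQDA"`.
#' @param k,cost,gamma Hyperparameters (defaults: k = 1, C = 1,
#'   gamma = 2.6).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("KNN", "LSVM", "GSVM", "TREE",
                                       "LDA", "QDA", "MQDA"),
                            k = 1, cost = 1, gamma = 2.6) {
  family <- match.arg(family)
  structure(list(family = family, k = k, cost = cost, gamma = gamma),
            class = "classifier_spec")
}

#' The full seven-classifier roster
#' @return Named list of `classifier_spec`s.
#' @export
classifier_roster <- function() {
  fam <- c("KNN", "LSVM", "GSVM", "TREE", "LDA", "QDA", "MQDA")
  stats::setNames(lapply(fam, classifier_spec), fam)
}

#' Assemble the labelled feature table from a cohort
#'
#' Extracts all eight autonomic indices for every recording; rows whose
#' extraction fails (signal-quality errors) are dropped with a logged
#' reason.
#'
#' @param cohort An `ans_cohort` (or plain list of recordings with
#'   `subject_id`, `trial`, `condition`, `ecg`, `eda`).
#' @param bands A [spectral_bands()].
#' @param ecg_window_s,eda_window_s Analysis windows, s.
#' @param verbose Print a note per dropped recording.
#' @return data.frame with columns `subject_id`, `trial`, `condition` and
#'   the eight canonical feature columns; attribute `"dropped"` lists any
#'   failures.
#' @export
assemble_features <- function(cohort, bands = spectral_bands(),
                              ecg_window_s = 240, eda_window_s = 120,
                              verbose = FALSE) {
  recs <- if (inherits(cohort, "ans_cohort")) cohort$recordings else cohort
  if (!length(recs)) stop("assemble_features: empty recording set")
  rows <- list()
  dropped <- character(0)
  for (r in recs) {
    row <- tryCatch(
      extract_recording_features(r, bands = bands,
                                 ecg_window_s = ecg_window_s,
                                 eda_window_s = eda_window_s),
      error = function(e) e)
    if (inherits(row, "error")) {
      msg <- sprintf("s%s t%s %s: %s", r$subject_id, r$trial, r$condition,
                     conditionMessage(row))
      dropped <- c(dropped, msg)
      if (verbose) message("assemble_features: dropped ", msg)
    } else rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("assemble_features: no recording could be processed")
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[, c("subject_id", "trial", "condition")]))
    stop("assemble_features: duplicate (subject, trial, condition)")
  attr(out, "dropped") <- dropped
  out
}

# One feature row for one recording.
extract_recording_features <- function(r, bands = spectral_bands(),
                                       ecg_window_s = 240,
                                       eda_window_s = 120) {
  ecg <- r$ecg
  n_keep <- min(length(ecg$samples), round(ecg_window_s * ecg$fs))
  ecg <- raw_signal(ecg$samples[seq_len(n_keep)], fs = ecg$fs,
                    channel = "ECG")
  hrv <- hrv_features(ecg, bands = bands)
  eda <- eda_features(r$eda, bands = bands, window_s = eda_window_s)
  data.frame(subject_id = r$subject_id, trial = r$trial,
             condition = r$condition,
             SCL = eda$SCL, NS_SCRs = eda$NS_SCRs,
             EDASymp = eda$EDASymp, TVSymp = eda$TVSymp,
             HRVLF = hrv$HRVLF, HRVLFn = hrv$HRVLFn,
             HRVHF = hrv$HRVHF, HRVHFn = hrv$HRVHFn)
}

# Standardize by train-fold statistics only.
standardize_fold <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(train = scale(train_x, center = mu, scale = sdv),
       test = scale(test_x, center = mu, scale = sdv))
}

#' Train one classifier and predict test labels
#'
#' Restricts features to `subset`, standardizes by the training fold's
#' mean/SD, trains the requested classifier on the training samples only,
#' and returns predictions for the test samples. Mahalanobis-QDA assigns
#' the class minimizing Mahalanobis distance under class-specific
#' covariance (ridge-regularized when near-singular); LDA/QDA use uniform
#' priors; SVMs use one-vs-one with majority vote.
#'
#' @param spec A [classifier_spec()].
#' @param train,test data.frames with the feature columns and a `condition`
#'   column (train).
#' @param subset Character vector of feature names to use.
#' @return Factor of predicted condition labels for `test`, with attribute
#'   `"spec"` echoing the hyperparameters used.
#' @export
fit_predict <- function(spec, train, test, subset = feature_names()) {
  stopifnot(inherits(spec, "classifier_spec"), length(subset) >= 1)
  if (!all(subset %in% names(train)))
    stop("fit_predict: unknown feature in subset")
  lv <- intersect(condition_levels(), unique(as.character(train$condition)))
  if (length(lv) < length(unique(as.character(train$condition))))
    lv <- unique(as.character(train$condition))
  y <- factor(as.character(train$condition), levels = lv)
  if (nlevels(y) < 2) stop("fit_predict: training data needs >= 2 classes")
  sx <- standardize_fold(as.matrix(train[, subset, drop = FALSE]),
                         as.matrix(test[, subset, drop = FALSE]))
  xtr <- sx$train; xte <- sx$test
  pred <- switch(spec$family,
    KNN = class::knn(xtr, xte, y, k = spec$k),
    LSVM = {
      m <- e1071::svm(xtr, y, kernel = "linear", cost = spec$cost,
                      scale = FALSE)
      stats::predict(m, xte)
    },
    GSVM = {
      m <- e1071::svm(xtr, y, kernel = "radial", cost = spec$cost,
                      gamma = spec$gamma, scale = FALSE)
      stats::predict(m, xte)
    },
    TREE = {
      d <- data.frame(.y = y, xtr, check.names = FALSE)
      m <- rpart::rpart(.y ~ ., data = d, method = "class")
      stats::predict(m, data.frame(xte, check.names = FALSE),
                     type = "class")
    },
    LDA = {
      m <- MASS::lda(xtr, grouping = y,
                     prior = rep(1 / nlevels(y), nlevels(y)))
      stats::predict(m, xte)$class
    },
    QDA = {
      m <- MASS::qda(xtr, grouping = y,
                     prior = rep(1 / nlevels(y), nlevels(y)))
      stats::predict(m, xte)$class
    },
    MQDA = mqda_predict(xtr, y, xte))
  pred <- factor(as.character(pred), levels = lv)
  attr(pred, "spec") <- unclass(spec)
  pred
}

# Mahalanobis-distance quadratic classifier with class-specific covariance.
mqda_predict <- function(xtr, y, xte, ridge = 1e-6) {
  classes <- levels(y)
  params <- lapply(classes, function(cl) {
    xc <- xtr[y == cl, , drop = FALSE]
    if (nrow(xc) < 2)
      stop("mqda: class '", cl, "' has fewer than 2 training samples")
    S <- stats::cov(xc)
    if (rcond_safe(S) < 1e-10)
      S <- S + diag(ridge * max(1, mean(diag(S))), ncol(S))
    Si <- tryCatch(solve(S), error = function(e)
      stop("mqda: singular covariance for class '", cl,
           "' even after regularization"))
    list(mu = colMeans(xc), Si = Si)
  })
  d2 <- vapply(params, function(p) {
    dx <- sweep(xte, 2, p$mu)
    rowSums((dx %*% p$Si) * dx)
  }, numeric(nrow(xte)))
  d2 <- matrix(d2, nrow = nrow(xte))
  factor(classes[max.col(-d2, ties.method = "first")], levels = classes)
}

rcond_safe <- function(S) {
  tryCatch(rcond(S), error = function(e) 0)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: all of that subject's samples form the test set,
#' everything else the training set. Accuracy and the 4x4 confusion matrix
#' (rows = true condition) are aggregated over folds.
#'
#' @param samples Labelled feature table (see [assemble_features()]).
#' @param spec A [classifier_spec()].
#' @param subset Feature names to use.
#' @return Object of class `cv_result`: `accuracy`, `confusion`,
#'   `predictions` (data.frame with subject, trial, condition, predicted),
#'   `spec`, `subset`.
#' @export
loso_cv <- function(samples, spec, subset = feature_names()) {
  subjects <- unique(samples$subject_id)
  if (length(subjects) < 2) stop("loso_cv: need >= 2 subjects")
  lv <- condition_levels()
  preds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr <- samples[samples$subject_id != s, , drop = FALSE]
    te <- samples[samples$subject_id == s, , drop = FALSE]
    missing <- setdiff(unique(as.character(samples$condition)),
                       unique(as.character(tr$condition)))
    if (length(missing))
      stop("loso_cv: training fold for subject ", s,
           " is missing class(es): ", paste(missing, collapse = ", "))
    p <- fit_predict(spec, tr, te, subset)
    preds[[i]] <- data.frame(subject_id = te$subject_id, trial = te$trial,
                             condition = as.character(te$condition),
                             predicted = as.character(p))
  }
  preds <- do.call(rbind, preds)
  truef <- factor(preds$condition, levels = lv)
  predf <- factor(preds$predicted, levels = lv)
  confusion <- table(true = truef, predicted = predf)
  structure(list(accuracy = mean(preds$condition == preds$predicted),
                 confusion = confusion, predictions = preds,
                 spec = spec, subset = subset),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on {%s}: accuracy %.1f%% (%d samples)\n",
              x$spec$family, paste(x$subset, collapse = ", "),
              100 * x$accuracy, nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

# Enumerate all non-empty subsets of the canonical features as bitmask rows.
all_feature_subsets <- function(features = feature_names()) {
  p <- length(features)
  lapply(seq_len(2^p - 1), function(mask)
    features[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0])
}

#' Exhaustive feature-subset search
#'
#' Evaluates every non-empty subset of the eight indices (255 subsets) with
#' leave-one-subject-out cross-validation and returns results ranked by
#' accuracy; ties prefer fewer features, then earlier canonical name order.
#' The winning subset is re-evaluated independently to confirm the reported
#' accuracy.
#'
#' @param samples Labelled feature table.
#' @param spec A [classifier_spec()].
#' @param features Canonical feature names to search over.
#' @return List of class `subset_search`: `results` (data.frame ranked, one
#'   row per subset: `features`, `n_features`, `accuracy`), `best` (the top
#'   `cv_result`).
#' @export
subset_search <- function(samples, spec, features = feature_names()) {
  subsets <- all_feature_subsets(features)
  acc <- numeric(length(subsets))
  for (i in seq_along(subsets))
    acc[i] <- loso_cv(samples, spec, subsets[[i]])$accuracy
  nfeat <- lengths(subsets)
  # canonical-order key: position string of member indices
  key <- vapply(subsets, function(s)
    paste(sprintf("%02d", match(s, features)), collapse = ""), "")
  ord <- order(-acc, nfeat, key)
  results <- data.frame(
    rank = seq_along(ord),
    features = vapply(subsets[ord], paste, "", collapse = ", "),
    n_features = nfeat[ord],
    accuracy = acc[ord])
  best <- loso_cv(samples, spec, subsets[[ord[1]]])
  if (abs(best$accuracy - acc[ord[1]]) > 1e-12)
    stop("subset_search: best-subset re-run did not reproduce its accuracy")
  structure(list(results = results, best = best, spec = spec),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> %s over %d subsets; best %.1f%% with {%s}\n",
              x$spec$family, nrow(x$results), 100 * x$best$accuracy,
              paste(x$best$subset, collapse = ", ")))
  invisible(x)
}

#' Temporal generalization: train on trial 1, test on later trials
#'
#' A single model is trained on all trial-1 samples (standardization
#' statistics from trial 1 only) and applied without retraining to each
#' subsequent trial.
#'
#' @param samples Labelled feature table containing trial 1 and at least
#'   one later trial.
#' @param spec A [classifier_spec()].
#' @param subset Feature names to use.
#' @return data.frame with one row per later trial: `trial`, `accuracy`,
#'   `n`.
#' @export
temporal_generalization <- function(samples, spec,
                                    subset = feature_names()) {
  trials <- sort(unique(samples$trial))
  if (!1 %in% trials) stop("temporal_generalization: trial 1 missing")
  if (length(trials) < 2)
    stop("temporal_generalization: need at least one trial after trial 1")
  train <- samples[samples$trial == 1, , drop = FALSE]
  later <- trials[trials > 1]
  out <- lapply(later, function(tr) {
    te <- samples[samples$trial == tr, , drop = FALSE]
    p <- fit_predict(spec, train, te, subset)
    data.frame(trial = tr,
               accuracy = mean(as.character(p) ==
                                 as.character(te$condition)),
               n = nrow(te))
  })
  do.call(rbind, out)
}
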