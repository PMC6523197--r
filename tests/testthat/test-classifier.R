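# Classification stack: feature assembly, the classifier roster, LOSO
# integrity, exhaustive subset search, temporal generalization.

test_that("feature assembly labels every recording and flags failures", {
  ch <- generate_cohort(n_subjects = 2, n_trials = 1, seed = 21)
  ft <- assemble_features(ch)
  expect_identical(nrow(ft), 8L)
  expect_true(all(feature_names() %in% names(ft)))
  expect_true(all(is.finite(as.matrix(ft[, feature_names()]))))
  # quality failure in one recording drops one row with a logged reason
  ch$recordings[[3]]$ecg$samples[] <- 0
  ft2 <- assemble_features(ch)
  expect_identical(nrow(ft2), 7L)
  expect_length(attr(ft2, "dropped"), 1L)
  # duplicate (subject, trial, condition) is rejected
  dup <- ch
  dup$recordings[[2]] <- dup$recordings[[1]]
  expect_error(assemble_features(dup), "duplicate")
  expect_error(assemble_features(list()), "empty")
})

test_that("1-NN prediction matches an exhaustive-distance oracle", {
  samp <- make_feature_table(6, sep = 1.2, seed = 31)  # 24 <= 50 samples
  tr <- samp[samp$subject_id <= 4, ]
  te <- samp[samp$subject_id > 4, ]
  pred <- fit_predict(classifier_spec("KNN"), tr, te)
  # oracle: standardize by train stats, full pairwise distances
  fx <- feature_names()
  mu <- colMeans(tr[, fx]); sdv <- apply(tr[, fx], 2, sd)
  ztr <- scale(as.matrix(tr[, fx]), mu, sdv)
  zte <- scale(as.matrix(te[, fx]), mu, sdv)
  oracle <- apply(zte, 1, function(z) {
    d <- sqrt(colSums((t(ztr) - z)^2))
    as.character(tr$condition[which.min(d)])
  })
  expect_identical(as.character(pred), unname(oracle))
  # identity: a test sample equal to a train sample gets its label
  pred_id <- fit_predict(classifier_spec("KNN"), samp, samp[7, ])
  expect_identical(as.character(pred_id), as.character(samp$condition[7]))
})

test_that("LDA matches the closed-form two-Gaussian discriminant", {
  withr::with_seed(42, {
    n <- 100
    xa <- cbind(rnorm(n, 0), rnorm(n, 0))
    xb <- cbind(rnorm(n, 2), rnorm(n, 1))
    tr <- data.frame(subject_id = 1, trial = 1,
                     condition = rep(c("BL", "PVT"), each = n),
                     SCL = c(xa[, 1], xb[, 1]),
                     NS_SCRs = c(xa[, 2], xb[, 2]))
    xt <- cbind(rnorm(200, 1), rnorm(200, 0.5))
    te <- data.frame(subject_id = 2, trial = 1, condition = "BL",
                     SCL = xt[, 1], NS_SCRs = xt[, 2])
  })
  sub <- c("SCL", "NS_SCRs")
  pred <- fit_predict(classifier_spec("LDA"), tr, te, sub)
  # plug-in Fisher rule with train-estimated means and pooled covariance,
  # uniform priors, on the same standardized scale
  mu <- colMeans(tr[, sub]); sdv <- apply(tr[, sub], 2, sd)
  z <- scale(as.matrix(tr[, sub]), mu, sdv)
  zt <- scale(as.matrix(te[, sub]), mu, sdv)
  g <- tr$condition
  m1 <- colMeans(z[g == "BL", ]); m2 <- colMeans(z[g == "PVT", ])
  S <- ((n - 1) * cov(z[g == "BL", ]) + (n - 1) * cov(z[g == "PVT", ])) /
    (2 * n - 2)
  w <- solve(S, m2 - m1)
  thresh <- sum(w * (m1 + m2)) / 2
  oracle <- ifelse(zt %*% w > thresh, "PVT", "BL")
  expect_identical(as.character(pred), unname(oracle[, 1]))
})

test_that("Mahalanobis-QDA picks the nearest class in Mahalanobis metric", {
  samp <- make_feature_table(10, sep = 2, seed = 17)
  tr <- samp[samp$subject_id <= 8, ]
  te <- samp[samp$subject_id > 8, ]
  sub <- feature_names()[1:4]
  pred <- fit_predict(classifier_spec("MQDA"), tr, te, sub)
  mu <- colMeans(tr[, sub]); sdv <- apply(tr[, sub], 2, sd)
  ztr <- scale(as.matrix(tr[, sub]), mu, sdv)
  zte <- scale(as.matrix(te[, sub]), mu, sdv)
  oracle <- apply(zte, 1, function(z) {
    d2 <- vapply(condition_levels(), function(cl) {
      xi <- ztr[tr$condition == cl, ]
      stats::mahalanobis(rbind(z), colMeans(xi), cov(xi))
    }, 0)
    names(which.min(d2))
  })
  expect_identical(as.character(pred), unname(oracle))
})

test_that("hyperparameters are echoed in prediction metadata", {
  samp <- make_feature_table(4, seed = 3)
  pred <- fit_predict(classifier_spec("GSVM"), samp, samp[1:2, ])
  sp <- attr(pred, "spec")
  expect_equal(sp$gamma, 2.6)
  expect_equal(sp$cost, 1)
  pred_k <- fit_predict(classifier_spec("KNN"), samp, samp[1:2, ])
  expect_equal(attr(pred_k, "spec")$k, 1)
})

test_that("LOSO folds are leak-free and bookkeeping is exact", {
  samp <- make_feature_table(16, sep = 8, seed = 7)
  cv <- loso_cv(samp, classifier_spec("KNN"))
  expect_identical(nrow(cv$predictions), 64L)       # each sample once
  expect_identical(length(unique(cv$predictions$subject_id)), 16L)
  expect_equal(sum(cv$confusion), 64)
  expect_equal(unname(rowSums(cv$confusion)), rep(16, 4),
               ignore_attr = TRUE)
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  # well-separated classes classify perfectly
  expect_equal(cv$accuracy, 1)
  # fold predictions depend only on the training set (no leakage):
  # recompute subject 1 predictions directly
  p1 <- fit_predict(classifier_spec("KNN"),
                    samp[samp$subject_id != 1, ],
                    samp[samp$subject_id == 1, ])
  expect_identical(as.character(p1),
                   cv$predictions$predicted[cv$predictions$subject_id == 1])
  # shifting one *test* subject's features leaves other folds unchanged
  shifted <- samp
  cols <- feature_names()
  shifted[shifted$subject_id == 2, cols] <-
    shifted[shifted$subject_id == 2, cols] + 50
  cv_s <- loso_cv(shifted, classifier_spec("LDA"))
  cv_o <- loso_cv(samp, classifier_spec("LDA"))
  keep <- cv_o$predictions$subject_id != 2
  expect_identical(cv_s$predictions$predicted[keep],
                   cv_o$predictions$predicted[keep])
  expect_error(loso_cv(samp[samp$subject_id == 1, ],
                       classifier_spec("KNN")), ">= 2 subjects")
})

test_that("permuted labels drive LOSO accuracy to chance", {
  samp <- make_feature_table(16, sep = 3, seed = 11)
  accs <- vapply(1:20, function(r) withr::with_seed(1000 + r, {
    perm <- samp
    perm$condition <- sample(perm$condition)
    loso_cv(perm, classifier_spec("KNN"))$accuracy
  }), 0)
  n_total <- 20 * nrow(samp)
  se <- sqrt(0.25 * 0.75 / n_total)
  expect_lt(abs(mean(accs) - 0.25), 3 * se)
})

test_that("a training fold missing a class raises an error", {
  samp <- make_feature_table(3, seed = 5)
  # condition SS exists only for subject 1
  samp <- samp[!(samp$condition == "SS" & samp$subject_id != 1), ]
  expect_error(loso_cv(samp, classifier_spec("KNN")), "missing class")
})

test_that("subset search enumerates 255 subsets and finds the signal", {
  expect_length(ansid:::all_feature_subsets(), 255)
  # one informative feature (HRVLF, position 5) among 7 noise features
  samp <- make_feature_table(8, sep = 2, seed = 13, informative = 5)
  sr <- subset_search(samp, classifier_spec("KNN"))
  expect_identical(nrow(sr$results), 255L)
  expect_true("HRVLF" %in% sr$best$subset)
  expect_equal(sr$results$accuracy[1], sr$best$accuracy)
  # ranking is by accuracy, ties by fewer features then canonical order
  expect_true(all(diff(sr$results$accuracy) <= 0))
  same_acc <- sr$results$accuracy == sr$results$accuracy[1]
  expect_true(sr$results$n_features[1] ==
                min(sr$results$n_features[same_acc]))
})

test_that("temporal generalization trains once on trial 1", {
  s1 <- make_feature_table(8, sep = 3, trial = 1, seed = 19)
  later <- lapply(2:12, function(tr)
    make_feature_table(8, sep = 3, trial = tr, seed = 19 + tr))
  samp <- do.call(rbind, c(list(s1), later))
  tg <- temporal_generalization(samp, classifier_spec("KNN"))
  expect_identical(nrow(tg), 11L)                 # trials 2..12
  expect_equal(tg$trial, 2:12, ignore_attr = TRUE)
  # no-drift control: held-out-trial accuracy comparable to LOSO on trial 1
  loso_acc <- loso_cv(s1, classifier_spec("KNN"))$accuracy
  expect_lt(abs(mean(tg$accuracy) - loso_acc), 0.15)
  # attenuated separation at late trials lowers accuracy
  drift <- lapply(10:12, function(tr) {
    d <- make_feature_table(8, sep = 0.3, trial = tr, seed = 50 + tr)
    d
  })
  samp2 <- do.call(rbind, c(list(s1), later[1:7], drift))
  tg2 <- temporal_generalization(samp2, classifier_spec("KNN"))
  expect_lt(mean(tg2$accuracy[tg2$trial >= 10]),
            mean(tg2$accuracy[tg2$trial < 10]) - 0.2)
  expect_error(temporal_generalization(s1, classifier_spec("KNN")),
               "trial")
  no1 <- samp[samp$trial > 1, ]
  expect_error(temporal_generalization(no1, classifier_spec("KNN")),
               "trial 1")
})

test_that("the full classifier roster runs under LOSO on 16 subjects", {
  samp <- make_feature_table(16, sep = 2.5, seed = 23)
  for (fam in names(classifier_roster())) {
    cv <- loso_cv(samp, classifier_spec(fam))
    expect_identical(nrow(cv$predictions), 64L)
    # the very local gamma = 2.6 kernel collapses toward the majority vote
    # on diffuse 8-d data, so only the other six get an accuracy floor
    if (fam != "GSVM") expect_gte(cv$accuracy, 0.4)
  }
})
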