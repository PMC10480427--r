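make_small_tables <- function(seed = 1L, n_pos = 20L, n_neg = 20L) {
  seqs <- small_signal_set(n_pos, n_neg, weight = 2.5, seed = seed)
  n <- n_pos + n_neg
  tr_idx <- c(seq_len(n_pos * 0.75), n_pos + seq_len(n_neg * 0.75))
  list(train = build_feature_table(as_peptide_subset(seqs, tr_idx)),
       test = build_feature_table(as_peptide_subset(seqs, setdiff(1:n, tr_idx))))
}

test_that("the four base classifiers fit, predict their own training data, and beat chance", {
  tabs <- make_small_tables(seed = 41)
  clfs <- fit_base_classifiers(tabs$train, base_classifier_spec(seed = 1))
  # 1-NN predicts its own training points perfectly (distance 0 to self)
  p <- epitopeGA:::predict_knn1(clfs$knn, tabs$train$features)
  expect_equal(p$label, tabs$train$labels)
  # separable planted signal: every member clears chance on held-out data
  for (m in c("knn", "rf", "lr", "svm")) {
    pm <- epitopeGA:::predict_member(clfs, m, tabs$test$features)
    expect_gt(mean(pm$label == tabs$test$labels), 0.5)
    expect_true(all(pm$label %in% c(0L, 1L)))
  }
  # single-class training data is rejected
  bad <- tabs$train
  bad$labels <- rep(1L, length(bad$labels))
  expect_error(fit_base_classifiers(bad), "single-class")
})

test_that("random forest predictions are reproducible under one seed", {
  tabs <- make_small_tables(seed = 43)
  spec <- base_classifier_spec(seed = 99)
  f1 <- epitopeGA:::fit_rf(tabs$train$features, tabs$train$labels, spec)
  f2 <- epitopeGA:::fit_rf(tabs$train$features, tabs$train$labels, spec)
  expect_identical(epitopeGA:::predict_rf(f1, tabs$test$features),
                   epitopeGA:::predict_rf(f2, tabs$test$features))
})

test_that("1-NN agrees with the class::knn reference on generic data", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(30 * 6), 30)
    y <- rep(c(0L, 1L), 15)
    N <- matrix(stats::rnorm(12 * 6), 12)
  })
  ours <- epitopeGA:::predict_knn1(epitopeGA:::fit_knn1(X, y), N)$label
  ref <- as.integer(as.character(class::knn(X, N, factor(y), k = 1)))
  expect_equal(ours, ref)
})

test_that("the correct-instance union dominates every individual classifier", {
  tabs <- make_small_tables(seed = 47)
  model <- ensemble_fit(tabs$train, base_classifier_spec(seed = 2))
  u <- correct_instance_union(model, tabs$test)
  expect_equal(u$C_final,
               sort(unique(Reduce(union, u$correct_sets))))
  expect_true(all(u$union_accuracy >= u$accuracies))
  expect_true(all(u$C_final %in% seq_along(tabs$test$labels)))
  expect_error(correct_instance_union(model, epitopeGA:::ft_rows(tabs$test, integer(0))),
               "empty")
})

test_that("pairwise correlation honours both modes and their degenerate cases", {
  expect_equal(correlation(c(1, 2, 3), c(1, 2, 3), "pearson"), 1.0)
  expect_equal(correlation(c(1, 2, 3), c(1, 2, 3), "as_printed"), 1.0)
  expect_equal(correlation(c(1, 0), c(0, 1), "as_printed"), 0.0)
  # constant but not identical vectors: pearson pinned to 0
  expect_equal(correlation(c(2, 2, 2), c(1, 5, 3), "pearson"), 0.0)
  expect_error(correlation(1:3, 1:4), "length mismatch")
  # as_printed is bounded by +/- sqrt(n) (Cauchy-Schwarz)
  withr::with_seed(9, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      r <- correlation(stats::rnorm(n), stats::rnorm(n), "as_printed")
      expect_lte(abs(r), sqrt(n) + 1e-12)
    }
  })
})

test_that("routing picks the classifier holding the best-matching correct instance", {
  tabs <- make_small_tables(seed = 53)
  model <- ensemble_fit(tabs$train, base_classifier_spec(seed = 3))
  model <- ensemble_calibrate(model, tabs$test)
  # querying a stored 1-NN-correct instance routes to knn with correlation 1
  knn_correct <- model$union$correct_sets$knn
  expect_gt(length(knn_correct), 0L)
  q <- tabs$test$features[knn_correct[1], ]
  r <- route_and_classify(model, q)
  expect_equal(r$max_corr, 1.0)
  expect_equal(r$classifier, "knn") # tie-break order puts knn first
  expect_true(r$label %in% c(0L, 1L))
  # batch routing returns one decision per row
  rb <- route_and_classify(model, tabs$test$features)
  expect_equal(nrow(rb), nrow(tabs$test$features))
  expect_true(all(rb$label %in% c(0L, 1L)))
  # a routed query equal to a stored correct instance goes to a classifier
  # that classified it correctly
  i <- model$union$correct_sets$rf[1]
  ri <- route_and_classify(model, tabs$test$features[i, ])
  expect_true(i %in% model$union$correct_sets[[ri$classifier]])
})

test_that("classifiers without stored correct instances are never chosen", {
  tabs <- make_small_tables(seed = 59)
  model <- ensemble_fit(tabs$train, base_classifier_spec(seed = 4))
  model <- ensemble_calibrate(model, tabs$test)
  # forcibly empty all but the svm store
  for (m in c("knn", "rf", "lr")) {
    model$stored[[m]] <- list(X = tabs$test$features[0, , drop = FALSE],
                              y = integer(0))
  }
  r <- route_and_classify(model, tabs$test$features[1:3, ])
  expect_true(all(r$classifier == "svm"))
  for (m in c("svm")) {
    model$stored[[m]] <- list(X = tabs$test$features[0, , drop = FALSE],
                              y = integer(0))
  }
  expect_error(route_and_classify(model, tabs$test$features[1, ]),
               "no classifier")
})

test_that("self-augmentation obeys the strict 0.999 gate and never shrinks the pool", {
  tabs <- make_small_tables(seed = 61)
  model <- ensemble_fit(tabs$train, base_classifier_spec(seed = 5))
  n0 <- length(model$pool$y)
  v <- tabs$test$features[1, ]
  m1 <- maybe_augment(model, v, 1L, max_corr = 1.0)
  expect_equal(length(m1$pool$y), n0 + 1L)
  expect_true(m1$stale)
  m2 <- maybe_augment(model, v, 1L, max_corr = 0.5)
  expect_equal(length(m2$pool$y), n0)
  # boundary: exactly 0.999 is not "above" the threshold
  m3 <- maybe_augment(model, v, 1L, max_corr = 0.999)
  expect_equal(length(m3$pool$y), n0)
  expect_false(m3$stale)
  # refit clears the stale flag and keeps the grown pool
  m4 <- ensemble_refit(m1)
  expect_false(m4$stale)
  expect_equal(length(m4$pool$y), n0 + 1L)
})

test_that("ensemble bundles persist and reload", {
  tabs <- make_small_tables(seed = 67)
  model <- ensemble_fit(tabs$train, base_classifier_spec(seed = 6))
  model <- ensemble_calibrate(model, tabs$test)
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$correlation_mode, "pearson")
  expect_true(manifest$calibrated)
  back <- load_ensemble(dir)
  expect_identical(route_and_classify(back, tabs$test$features[1:2, ]),
                   route_and_classify(model, tabs$test$features[1:2, ]))
})
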