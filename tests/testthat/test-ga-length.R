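test_that("fitness threshold is mean accuracy scaled by Mu", {
  expect_equal(fitness_threshold(c(0.6, 0.8), 0.5), 0.35)
  expect_equal(fitness_threshold(c(0.6, 0.8), 1), 0.7)
  # all-equal accuracies pass any Mu <= 1 threshold
  expect_true(all(0.7 > fitness_threshold(rep(0.7, 4), 0.99)))
  expect_error(fitness_threshold(numeric(0), 0.5), "empty")
})

test_that("length scoring returns accuracy in [0, 1], ~1 on separable self-test", {
  seqs <- small_signal_set(20, 20, weight = 2.5, seed = 17)
  acc <- evaluate_length_solution(12, seqs, seqs)
  expect_gte(acc, 0.95) # train == test with planted signal
  expect_lte(acc, 1)
  expect_error(evaluate_length_solution(10, as_peptide_subset(seqs, 1:20), seqs),
               "single-class")
  expect_error(evaluate_length_solution(10, seqs, seqs[0, ]), "empty")
})

test_that("random labels give chance-level accuracy on average", {
  accs <- vapply(1:20, function(s) {
    # positives occupy rows 1:15; keep train and test class-balanced
    all_seqs <- small_signal_set(15, 15, kmer = NULL, lengths = c(8L, 12L),
                                 seed = 300 + s)
    evaluate_length_solution(10, as_peptide_subset(all_seqs, c(1:10, 16:25)),
                             as_peptide_subset(all_seqs, c(11:15, 26:30)))
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("length search stays in bounds, is elitist and reproducible", {
  seqs <- small_signal_set(25, 25, weight = 2, seed = 23)
  train <- as_peptide_subset(seqs, c(1:20, 26:45))
  test <- as_peptide_subset(seqs, c(21:25, 46:50))
  cfg <- ga_config(Ns = 3, Ni = 3, seed = 6)
  res <- run_feature_ga(train, test, cfg)
  lens <- nchar(c(train$residues, test$residues))
  expect_gte(res$best_length, min(lens))
  expect_lte(res$best_length, max(lens))
  expect_true(all(diff(res$trace) >= 0))
  # refitting the returned truncated tables reproduces the fitness exactly
  model <- epitopeGA:::lsvc_fit(res$train_table$features, res$train_table$labels)
  refit_acc <- mean(epitopeGA:::lsvc_predict(model, res$test_table$features) ==
                      res$test_table$labels)
  expect_equal(refit_acc, res$best_fitness)
  # identical seed, identical outcome
  res2 <- run_feature_ga(train, test, cfg)
  expect_equal(res2$best_length, res$best_length)
  expect_equal(res2$trace, res$trace)
})

test_that("a single-candidate search equals scoring one random length", {
  seqs <- small_signal_set(12, 12, seed = 29)
  train <- as_peptide_subset(seqs, c(1:8, 13:20))
  test <- as_peptide_subset(seqs, c(9:12, 21:24))
  cfg <- ga_config(Ns = 1, Ni = 1, seed = 77)
  res <- run_feature_ga(train, test, cfg)
  lens <- nchar(c(train$residues, test$residues))
  drawn <- withr::with_seed(77, sample(min(lens):max(lens), 1L))
  expect_equal(res$best_length, drawn)
  expect_equal(res$best_fitness, evaluate_length_solution(drawn, train, test))
})

test_that("signal confined to a prefix favours short truncation lengths", {
  # positives carry the dipeptide only inside the first 10 residues;
  # the tail is pure background for both classes
  make_prefix_set <- function(seed) {
    withr::with_seed(seed, {
      n <- 60L
      label <- rep(c(1L, 0L), each = n / 2)
      res <- vapply(seq_len(n), function(i) {
        head <- random_peptide(10L)
        if (label[i] == 1L) {
          st <- sample.int(9L, 1L)
          substr(head, st, st + 1L) <- "WH"
        }
        paste0(head, random_peptide(15L))
      }, "")
      peptide_set(res, label)
    })
  }
  better <- 0L
  for (s in 1:10) {
    seqs <- make_prefix_set(500 + s)
    train <- as_peptide_subset(seqs, c(1:20, 31:50))
    test <- as_peptide_subset(seqs, c(21:30, 51:60))
    res <- run_feature_ga(train, test, ga_config(Ns = 4, Ni = 4, seed = s))
    acc_full <- evaluate_length_solution(res$SLMax, train, test)
    if (res$best_fitness >= acc_full) better <- better + 1L
  }
  expect_gte(better, 8L)
})

test_that("inner validation mode scores candidates without touching the test set", {
  seqs <- small_signal_set(20, 20, seed = 31)
  train <- as_peptide_subset(seqs, 1:30)
  test <- as_peptide_subset(seqs, 31:40)
  cfg <- ga_config(Ns = 2, Ni = 2, seed = 4, inner_split = 0.3)
  res <- run_feature_ga(train, test, cfg)
  expect_true(res$best_length >= res$SLMin && res$best_length <= res$SLMax)
  # the returned tables still cover the full stage-one partition
  expect_equal(nrow(res$train_table$features), 30L)
  expect_equal(nrow(res$test_table$features), 10L)
})
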