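test_that("directed average variance matches the scalar transliteration oracle", {
  # hand case: sd of class b is 0, so class a deviates around 0
  expect_equal(average_variance(c(0, 2), c(1, 1)), 2)
  expect_equal(average_variance(c(0, 2), c(1, 1)),
               oracle_avg_var_scalar(c(0, 2), c(1, 1)))
  # identical class-a values equal to the inner center give 0
  expect_equal(average_variance(c(0, 0), c(1, 1)), 0)

  withr::with_seed(11, {
    for (rep in 1:20) {
      xa <- stats::rnorm(sample(2:8, 1), sd = 2)
      xb <- stats::rnorm(sample(2:8, 1), sd = 2)
      expect_equal(average_variance(xa, xb), oracle_avg_var_scalar(xa, xb))
    }
    A <- matrix(stats::rnorm(4 * 6), 4)
    B <- matrix(stats::rnorm(6 * 6), 6)
    expect_equal(average_variance(A, B), oracle_avg_var_matrix(A, B))
  })
})

test_that("average variance is positively homogeneous of degree 1", {
  withr::with_seed(5, {
    A <- matrix(stats::rexp(12), 4)
    B <- matrix(stats::rexp(9), 3)
  })
  expect_equal(average_variance(2 * A, 2 * B), 2 * average_variance(A, B))
  expect_equal(average_variance(7 * A, 7 * B), 7 * average_variance(A, B))
})

test_that("degenerate class sizes error", {
  expect_error(average_variance(1, c(1, 2)), ">= 2 samples")
  expect_error(average_variance(c(1, 2), 3), ">= 2 samples")
})

test_that("partition fitness is the mean of the directed class variances", {
  withr::with_seed(21, X <- matrix(stats::rnorm(8 * 5), 8))
  labels <- rep(c(0L, 1L), each = 4L)
  ft <- toy_feature_table(X, labels)
  idx <- c(1:3, 5:7)
  v1 <- average_variance(X[1:3, ], X[5:7, ])
  v2 <- average_variance(X[5:7, ], X[1:3, ])
  expect_equal(solution_fitness(ft, idx), (v1 + v2) / 2)
  expect_error(solution_fitness(ft, c(1, 5, 6)), "fewer than 2")
})

test_that("fast GA fitness equals the reference implementation", {
  withr::with_seed(31, X <- matrix(stats::rpois(20 * 30, 1) + 0.0, 20))
  labels <- rep(c(0L, 1L), each = 10L)
  ft <- toy_feature_table(X, labels)
  fast <- epitopeGA:::split_fitness_fast(X, X * X, labels, 1:16, c(0L, 1L))
  expect_equal(fast, solution_fitness(ft, 1:16))
})

test_that("mutation threshold is mean fitness scaled by Mu", {
  expect_equal(mutation_threshold(c(2, 4), 0.5), 1.5)
  expect_equal(mutation_threshold(c(2, 4), 1), 3)   # Mu = 1: the mean itself
  expect_equal(mutation_threshold(c(2, 4), 1e-12), 3e-12)
  expect_error(mutation_threshold(numeric(0), 0.5), "empty")
})

test_that("split search returns stratified, deterministic partitions", {
  seqs <- small_signal_set(15, 15, seed = 9)
  ft <- build_feature_table(seqs)
  cfg <- ga_config(Ns = 3, Ni = 3, Tr = 0.7, seed = 42)
  sol <- run_split_ga(ft, cfg)
  labs <- ft$labels[sol$train_indices]
  expect_equal(sum(labs == 0), sum(labs == 1))
  expect_setequal(c(sol$train_indices, sol$test_indices), 1:30)
  expect_length(intersect(sol$train_indices, sol$test_indices), 0)
  expect_gte(sol$fitness, 0)
  # determinism under the same seed
  sol2 <- run_split_ga(ft, cfg)
  expect_identical(sol$train_indices, sol2$train_indices)
  # degenerate single-candidate single-iteration search
  d <- run_split_ga(ft, ga_config(Ns = 1, Ni = 1, Tr = 0.7, seed = 5))
  expect_equal(d$fitness, solution_fitness(ft, d$train_indices))
  # best fitness never decreases across iterations
  expect_true(all(diff(sol$trace) >= 0))
  expect_error(run_split_ga(ft, ga_config(Tr = 0.99)), "infeasible")
})

test_that("small-instance search recovers the exhaustively best split", {
  withr::with_seed(8, X <- matrix(stats::rnorm(6 * 3), 6))
  ft <- toy_feature_table(X, rep(c(0L, 1L), each = 3L))
  # all equal-per-class splits with 2 training rows per class
  combos <- expand.grid(a = 1:3, b = 1:3)
  all_fit <- apply(combos, 1, function(co) {
    solution_fitness(ft, setdiff(1:6, c(co[1], co[2] + 3L)))
  })
  sol <- run_split_ga(ft, ga_config(Ns = 4, Ni = 15, Mu = 1, Tr = 0.67,
                                    seed = 2))
  expect_equal(sol$fitness, max(all_fit))
})

test_that("separated classes score higher partition fitness than shuffled labels", {
  # count-distributed features (low-rate vs enriched class), the geometry
  # of k-mer data; for symmetric location shifts the statistic is nearly
  # shuffle-invariant (see the methods vignette)
  wins <- 0L
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      X <- rbind(matrix(stats::rpois(10 * 10, 0.2) + 0.0, 10),
                 matrix(stats::rpois(10 * 10, 3) + 0.0, 10))
      labels <- rep(c(0L, 1L), each = 10L)
      shuffled <- sample(labels)
    })
    cfg <- ga_config(Ns = 3, Ni = 3, Tr = 0.8, seed = s)
    f_sep <- run_split_ga(toy_feature_table(X, labels), cfg)$fitness
    f_shuf <- run_split_ga(toy_feature_table(X, shuffled), cfg)$fitness
    if (f_sep > f_shuf) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("split reports write index files and a JSON trace", {
  seqs <- small_signal_set(6, 6, seed = 13)
  ft <- build_feature_table(seqs)
  sol <- run_split_ga(ft, ga_config(Ns = 2, Ni = 2, Tr = 0.7, seed = 3))
  dir <- withr::local_tempdir()
  write_split_report(sol, ft, dir)
  expect_equal(readLines(file.path(dir, "train_ids.txt")),
               ft$ids[sol$train_indices])
  rep <- jsonlite::fromJSON(file.path(dir, "split_report.json"))
  expect_equal(rep$fitness, sol$fitness)
  expect_length(rep$trace, 2L)
})
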