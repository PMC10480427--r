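# Stage 1 of the genetic search: choose a stratified train/test partition
# whose training classes show maximal inter-class feature variance.
#
# The variance statistic is defined for scalar samples; feature rows are
# 8420-vectors, so it is applied independently per feature dimension and
# the per-dimension values are averaged (see the methods vignette).

#' Directed average variance between two sample classes
#'
#' For each feature dimension, the inner term is the sample standard
#' deviation of the second class (its mean over that class's samples is
#' the centering constant), and the outer term is the sample standard
#' deviation of the first class's values around that constant, using
#' `m - 1` / `n - 1` denominators. The per-dimension values are averaged
#' into one non-negative scalar. The statistic is directed:
#' `average_variance(a, b)` generally differs from `average_variance(b, a)`.
#'
#' @param class_a Numeric matrix (rows = samples) or vector; `m >= 2` rows.
#' @param class_b Numeric matrix or vector of the other class; `n >= 2` rows.
#' @return Non-negative scalar.
#' @examples
#' average_variance(c(0, 2), c(1, 1)) # sd of {0,2} around sd(b) = 0 -> 2
#' @export
average_variance <- function(class_a, class_b) {
  A <- if (is.matrix(class_a)) class_a else matrix(class_a, ncol = 1L)
  B <- if (is.matrix(class_b)) class_b else matrix(class_b, ncol = 1L)
  m <- nrow(A); n <- nrow(B)
  if (m < 2L || n < 2L) {
    stop("both classes need >= 2 samples (m - 1 and n - 1 denominators)")
  }
  if (ncol(A) != ncol(B)) stop("classes must share feature dimensions")
  sd_b <- sqrt(pmax(colSums(sweep(B, 2L, colMeans(B))^2) / (n - 1), 0))
  v <- sqrt(pmax(colSums(sweep(A, 2L, sd_b)^2) / (m - 1), 0))
  mean(v)
}

#' Partition fitness: mean directed variance over classes
#'
#' The fitness of a candidate training subset is the mean, over the k
#' classes, of the directed average variance of that class's training rows
#' against the training rows of all other classes.
#'
#' @param table A [build_feature_table()] result.
#' @param train_indices Integer row indices of the candidate training set.
#' @return Non-negative scalar fitness.
#' @export
solution_fitness <- function(table, train_indices) {
  stopifnot(inherits(table, "feature_table"))
  labs <- table$labels[train_indices]
  classes <- sort(unique(table$labels))
  vals <- vapply(classes, function(cl) {
    a <- train_indices[labs == cl]
    b <- train_indices[labs != cl]
    if (length(a) < 2L || length(b) < 2L) {
      stop("class ", cl, " has fewer than 2 training samples")
    }
    average_variance(table$features[a, , drop = FALSE],
                     table$features[b, , drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Survival threshold from mean fitness
#'
#' `M_threshold = mean(fitnesses) * Mu`. Solutions whose fitness exceeds
#' the threshold survive an iteration unchanged; the rest are regenerated.
#'
#' @param fitnesses Non-empty numeric vector.
#' @param Mu Mutation factor.
#' @return Scalar threshold.
#' @examples
#' mutation_threshold(c(2, 4), 0.5) # 1.5
#' @export
mutation_threshold <- function(fitnesses, Mu) {
  if (length(fitnesses) == 0L) stop("empty fitness collection")
  mean(fitnesses) * Mu
}

# fast equivalent of solution_fitness built from per-subset column sums of
# the feature matrix and its elementwise square (precomputed once per run);
# tested for equality against the reference implementation
split_fitness_fast <- function(X, X2, labels, train_idx, classes) {
  labs <- labels[train_idx]
  per_class <- lapply(classes, function(cl) {
    idx <- train_idx[labs == cl]
    list(n = length(idx),
         s1 = colSums(X[idx, , drop = FALSE]),
         s2 = colSums(X2[idx, , drop = FALSE]))
  })
  directed <- function(a, b) {
    m <- a$n; n <- b$n
    mean_b <- b$s1 / n
    sd_b <- sqrt(pmax((b$s2 - n * mean_b^2) / (n - 1), 0))
    ss <- a$s2 - 2 * sd_b * a$s1 + m * sd_b^2
    mean(sqrt(pmax(ss, 0) / (m - 1)))
  }
  k <- length(classes)
  vals <- vapply(seq_len(k), function(i) {
    other <- Reduce(function(u, v) list(n = u$n + v$n, s1 = u$s1 + v$s1,
                                        s2 = u$s2 + v$s2),
                    per_class[-i])
    directed(per_class[[i]], other)
  }, numeric(1))
  mean(vals)
}

#' Genetic search for a maximal-variance train/test partition
#'
#' Runs `Ni` iterations over `Ns` candidate partitions. Each candidate is a
#' stratified random training subset with equal per-class counts (total
#' approximately `Tr` times the number of rows). A freshly generated
#' candidate is accepted when its fitness exceeds the running best (`CVV`,
#' initialized at 0); after at most `regen_attempts` rejected draws the
#' best rejected candidate is kept. At the end of an iteration, solutions
#' with fitness above [mutation_threshold()] are frozen for the next
#' iteration; the rest are regenerated. The best candidate always exceeds
#' the threshold (for `Mu` <= 1), so the best fitness trace is monotone
#' non-decreasing. The run is fully reproducible from `cfg$seed`.
#'
#' @param table A [build_feature_table()] result with >= 2 rows per class.
#' @param cfg A [ga_config()].
#' @return A list of class `split_solution`: `train_indices`,
#'   `test_indices`, `fitness`, `trace` (best fitness per iteration),
#'   `n_train_per_class`, and the config.
#' @export
run_split_ga <- function(table, cfg = ga_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "ga_config"))
  labels <- table$labels
  n <- length(labels)
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2L) stop("need at least two classes")
  n_pc <- round(cfg$Tr * n / k)
  class_sizes <- as.integer(table(factor(labels, levels = classes)))
  if (n_pc < 2L) stop("infeasible Tr: fewer than 2 training samples per class")
  if (any(class_sizes < n_pc + 1L)) {
    stop("infeasible Tr/class balance: a class has only ",
         min(class_sizes), " samples but ", n_pc,
         " training + >= 1 test are required")
  }
  X <- table$features
  X2 <- X * X
  class_rows <- lapply(classes, function(cl) which(labels == cl))

  withr::with_seed(cfg$seed, {
    gen <- function() {
      sort(unlist(lapply(class_rows, function(r) sample(r, n_pc)),
                  use.names = FALSE))
    }
    fit <- function(idx) split_fitness_fast(X, X2, labels, idx, classes)

    train <- vector("list", cfg$Ns)
    fitness <- rep(NA_real_, cfg$Ns)
    frozen <- rep(FALSE, cfg$Ns)
    CVV <- 0
    trace <- numeric(cfg$Ni)
    for (it in seq_len(cfg$Ni)) {
      for (s in seq_len(cfg$Ns)) {
        if (frozen[s]) next
        best_rej <- NULL
        accepted <- FALSE
        for (a in seq_len(cfg$regen_attempts)) {
          cand <- gen()
          f <- fit(cand)
          if (f > CVV) {
            train[[s]] <- cand; fitness[s] <- f; CVV <- f
            accepted <- TRUE
            break
          }
          if (is.null(best_rej) || f > best_rej$f) {
            best_rej <- list(idx = cand, f = f)
          }
        }
        if (!accepted) {
          train[[s]] <- best_rej$idx
          fitness[s] <- best_rej$f
        }
      }
      thr <- mutation_threshold(fitness, cfg$Mu)
      frozen <- fitness > thr
      trace[it] <- max(fitness)
    }
    best <- which.max(fitness)
    structure(
      list(train_indices = train[[best]],
           test_indices = setdiff(seq_len(n), train[[best]]),
           fitness = fitness[best], trace = trace,
           n_train_per_class = n_pc, config = cfg),
      class = "split_solution"
    )
  })
}

#' @export
print.split_solution <- function(x, ...) {
  cat("split_solution:", length(x$train_indices), "train /",
      length(x$test_indices), "test; fitness =", format(x$fitness), "\n")
  invisible(x)
}

#' Write the chosen partition and a JSON run report
#'
#' Emits `train_ids.txt` and `test_ids.txt` (one id per line) plus
#' `split_report.json` with the fitness trace, a config echo and the seed.
#'
#' @param sol A [run_split_ga()] result.
#' @param table The feature table the search ran on (for ids).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_split_report <- function(sol, table, dir) {
  stopifnot(inherits(sol, "split_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(table$ids[sol$train_indices], file.path(dir, "train_ids.txt"))
  writeLines(table$ids[sol$test_indices], file.path(dir, "test_ids.txt"))
  jsonlite::write_json(
    list(fitness = sol$fitness, trace = sol$trace,
         n_train_per_class = sol$n_train_per_class,
         config = unclass(sol$config)),
    file.path(dir, "split_report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
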