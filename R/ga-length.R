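# Stage 2 of the genetic search: choose a sequence truncation length.
# Candidate lengths in [SLMin, SLMax] are scored by the test accuracy of a
# linear-kernel support vector classifier trained on features re-extracted
# from length-truncated sequences. The search loop mirrors stage 1, with
# the running best accuracy (CA) in place of the variance accumulator.

# linear SVC via libsvm on a compressed sparse row matrix; count features
# are left unscaled
lsvc_fit <- function(X, y, cost = 1) {
  y <- factor(y, levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) stop("single-class training set")
  e1071::svm(SparseM::as.matrix.csr(X), y, kernel = "linear",
             cost = cost, scale = FALSE)
}

lsvc_predict <- function(model, X) {
  as.integer(as.character(predict(model, SparseM::as.matrix.csr(X))))
}

#' Score one candidate truncation length
#'
#' Truncates the training and test sequences to their first `SLsel`
#' residues, re-extracts the k-mer features, fits a linear-kernel support
#' vector classifier on the training rows, and returns the fraction of
#' test rows classified correctly.
#'
#' @param SLsel Candidate truncation length (>= 1).
#' @param train,test [peptide_set()]s; the training set must contain both
#'   classes.
#' @param residue_policy Passed to [build_feature_table()].
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_length_solution <- function(SLsel, train, test,
                                     residue_policy = "skip") {
  if (nrow(test) == 0L) stop("empty test set")
  tr <- build_feature_table(truncate_sequences(train, SLsel), residue_policy)
  te <- build_feature_table(truncate_sequences(test, SLsel), residue_policy)
  model <- lsvc_fit(tr$features, tr$labels)
  mean(lsvc_predict(model, te$features) == te$labels)
}

#' Survival threshold for the length search
#'
#' `f_th = mean(accuracies) * Mu`; identical in form to
#' [mutation_threshold()], named for the accuracy-driven stage.
#'
#' @param accuracies Non-empty numeric vector of candidate accuracies.
#' @param Mu Mutation factor.
#' @return Scalar threshold.
#' @export
fitness_threshold <- function(accuracies, Mu) {
  mutation_threshold(accuracies, Mu)
}

#' Genetic search for the optimal sequence truncation length
#'
#' `SLMin` and `SLMax` are the shortest and longest sequence lengths over
#' the training and test sets combined. Candidate lengths are drawn
#' uniformly from `[SLMin, SLMax]`; each is scored by
#' [evaluate_length_solution()] (results are memoized within the run —
#' the score of a length is deterministic). Acceptance, regeneration and
#' the survival threshold mirror [run_split_ga()], with the running best
#' accuracy `CA` (initialized at 0) in place of the variance accumulator.
#'
#' When `cfg$inner_split` is set, candidate accuracies are measured on an
#' inner validation fraction carved from the training set (seeded), which
#' avoids selecting the length on the final test partition; the default
#' scores on `test`, matching the procedure's use of the stage-one
#' partition.
#'
#' @param train,test [peptide_set()]s from the stage-one partition.
#' @param cfg A [ga_config()].
#' @param residue_policy Passed to [build_feature_table()].
#' @return A list of class `length_solution`: `best_length`,
#'   `best_fitness`, `SLMin`, `SLMax`, `trace`, `train_table` and
#'   `test_table` (feature tables of the truncated sets), and the config.
#' @export
run_feature_ga <- function(train, test, cfg = ga_config(),
                           residue_policy = "skip") {
  stopifnot(inherits(train, "peptide_set"), inherits(test, "peptide_set"),
            inherits(cfg, "ga_config"))
  lens <- nchar(c(train$residues, test$residues))
  SLMin <- min(lens)
  SLMax <- max(lens)
  if (SLMin > SLMax || SLMin < 1L) stop("invalid sequence length bounds")

  fit_train <- train
  fit_test <- test
  if (!is.null(cfg$inner_split)) {
    withr::with_seed(derive_seed(cfg$seed, 77L), {
      hold <- unlist(lapply(split(seq_len(nrow(train)), train$label),
                            function(ix) sample(ix, max(1L, round(cfg$inner_split * length(ix))))),
                     use.names = FALSE)
    })
    fit_test <- train[hold, , drop = FALSE]
    fit_train <- train[-hold, , drop = FALSE]
    class(fit_test) <- class(fit_train) <- c("peptide_set", "data.frame")
  }

  cache <- new.env(parent = emptyenv())
  score <- function(L) {
    key <- as.character(L)
    if (is.null(cache[[key]])) {
      cache[[key]] <- evaluate_length_solution(L, fit_train, fit_test,
                                               residue_policy)
    }
    cache[[key]]
  }

  withr::with_seed(cfg$seed, {
    lengths_ <- rep(NA_integer_, cfg$Ns)
    fitness <- rep(NA_real_, cfg$Ns)
    frozen <- rep(FALSE, cfg$Ns)
    CA <- 0
    trace <- numeric(cfg$Ni)
    for (it in seq_len(cfg$Ni)) {
      for (s in seq_len(cfg$Ns)) {
        if (frozen[s]) next
        best_rej <- NULL
        accepted <- FALSE
        for (a in seq_len(cfg$regen_attempts)) {
          L <- sample(SLMin:SLMax, 1L)
          f <- score(L)
          if (f > CA) {
            lengths_[s] <- L; fitness[s] <- f; CA <- f
            accepted <- TRUE
            break
          }
          if (is.null(best_rej) || f > best_rej$f) best_rej <- list(L = L, f = f)
        }
        if (!accepted) {
          lengths_[s] <- best_rej$L
          fitness[s] <- best_rej$f
        }
      }
      thr <- fitness_threshold(fitness, cfg$Mu)
      frozen <- fitness > thr
      trace[it] <- max(fitness)
    }
    best <- which.max(fitness)
    best_length <- lengths_[best]
    structure(
      list(best_length = best_length, best_fitness = fitness[best],
           SLMin = SLMin, SLMax = SLMax, trace = trace,
           train_table = build_feature_table(
             truncate_sequences(train, best_length), residue_policy),
           test_table = build_feature_table(
             truncate_sequences(test, best_length), residue_policy),
           config = cfg),
      class = "length_solution"
    )
  })
}

#' @export
print.length_solution <- function(x, ...) {
  cat("length_solution: SLsel =", x$best_length, "in [", x$SLMin, ",",
      x$SLMax, "]; accuracy =", format(x$best_fitness), "\n")
  invisible(x)
}

#' Write a JSON run report for the length search
#'
#' @param sol A [run_feature_ga()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_length_report <- function(sol, dir) {
  stopifnot(inherits(sol, "length_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(SLMin = sol$SLMin, SLMax = sol$SLMax, best_length = sol$best_length,
         best_fitness = sol$best_fitness, trace = sol$trace,
         config = unclass(sol$config)),
    file.path(dir, "length_report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
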