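# Instance-based ensemble: track which test instances each base
# classifier gets right, report the union ("oracle") accuracy, and route
# new sequences to the classifier whose stored correct instances
# correlate best with the query.

#' Pairwise correlation between two feature vectors
#'
#' Two modes. `"pearson"` is the standard Pearson coefficient, with the
#' degenerate cases pinned: identical vectors give 1.0 and otherwise a
#' constant vector gives 0.0. `"as_printed"` is the raw routing statistic
#' `sum(F_test - F_new) / sqrt(sum((F_test - F_new)^2))` with the 0/0
#' case (identical vectors) defined as 1.0; by Cauchy-Schwarz its value
#' is bounded by +/- sqrt(n), so it is not confined to \[-1, 1\].
#'
#' @param test_vec,new_vec Numeric vectors of equal length.
#' @param mode `"pearson"` (default, used for routing and the
#'   augmentation gate) or `"as_printed"`.
#' @return Scalar correlation.
#' @examples
#' correlation(c(1, 0), c(0, 1), mode = "as_printed") # 0
#' correlation(1:5, 1:5) # 1
#' @export
correlation <- function(test_vec, new_vec, mode = c("pearson", "as_printed")) {
  mode <- match.arg(mode)
  if (length(test_vec) != length(new_vec)) stop("length mismatch")
  if (length(test_vec) < 1L) stop("empty vectors")
  d <- test_vec - new_vec
  if (all(d == 0)) return(1.0)
  if (mode == "as_printed") {
    sum(d) / sqrt(sum(d^2))
  } else {
    if (stats::sd(test_vec) == 0 || stats::sd(new_vec) == 0) return(0.0)
    stats::cor(test_vec, new_vec)
  }
}

# max correlation of each row of `newX` against any row of `S`,
# vectorized for both modes; returns -Inf rows when S is empty
max_row_correlation <- function(S, newX, mode) {
  if (is.null(S) || nrow(S) == 0L) return(rep(-Inf, nrow(newX)))
  d2 <- pmax(outer(rowSums(newX^2), rowSums(S^2), "+") -
               2 * tcrossprod(newX, S), 0)
  identical_pair <- d2 < 1e-9
  if (mode == "as_printed") {
    sdiff <- outer(rowSums(newX), rowSums(S), function(a, b) b - a)
    r <- sdiff / sqrt(d2)
    r[identical_pair] <- 1.0
  } else {
    nc <- ncol(S)
    Sc <- S - rowMeans(S)
    Nc <- newX - rowMeans(newX)
    sS <- sqrt(rowSums(Sc^2))
    sN <- sqrt(rowSums(Nc^2))
    denom <- outer(sN, sS)
    r <- tcrossprod(Nc, Sc) / denom
    r[denom == 0] <- 0.0
    r[identical_pair] <- 1.0
  }
  apply(r, 1L, max)
}

#' Fit the instance-based ensemble
#'
#' @param train A [build_feature_table()] result with both classes.
#' @param spec A [base_classifier_spec()].
#' @param correlation_mode Routing correlation mode; see [correlation()].
#' @param augment_threshold Self-augmentation gate: queries whose maximum
#'   routing correlation strictly exceeds it join the training pool.
#' @return A list of class `ensemble_model`.
#' @export
ensemble_fit <- function(train, spec = base_classifier_spec(),
                         correlation_mode = c("pearson", "as_printed"),
                         augment_threshold = 0.999) {
  correlation_mode <- match.arg(correlation_mode)
  clfs <- fit_base_classifiers(train, spec)
  structure(
    list(classifiers = clfs, spec = spec,
         correlation_mode = correlation_mode,
         augment_threshold = augment_threshold,
         pool = list(X = train$features, y = train$labels),
         stored = NULL, stale = FALSE),
    class = "ensemble_model"
  )
}

#' Correct-instance union and its accuracy
#'
#' Each base classifier predicts the test table; its correct set holds
#' the indices it classifies correctly. `C_final` is the deduplicated
#' union of the four correct sets, and the union accuracy is
#' `|C_final| / n_test`. This is an oracle-style metric: it assumes the
#' right classifier is known per instance. The routed accuracy from
#' [route_and_classify()] is the matching end-to-end metric.
#'
#' @param model An [ensemble_fit()] result.
#' @param test A `feature_table` (non-empty).
#' @return List with `correct_sets` (per classifier), `C_final`,
#'   `union_accuracy`, per-classifier `accuracies` and `predictions`.
#' @export
correct_instance_union <- function(model, test) {
  stopifnot(inherits(model, "ensemble_model"), inherits(test, "feature_table"))
  n <- nrow(test$features)
  if (n == 0L) stop("empty test set")
  preds <- lapply(CLASSIFIER_ORDER, function(m)
    predict_member(model$classifiers, m, test$features))
  names(preds) <- CLASSIFIER_ORDER
  correct <- lapply(preds, function(p) which(p$label == test$labels))
  C_final <- sort(unique(unlist(correct, use.names = FALSE)))
  list(correct_sets = correct,
       C_final = C_final,
       union_accuracy = length(C_final) / n,
       accuracies = vapply(correct, function(s) length(s) / n, numeric(1)),
       predictions = preds)
}

#' Store routing instances from a calibration table
#'
#' Runs [correct_instance_union()] on `calib` and stores, per classifier,
#' the feature vectors (and labels) of the instances it classified
#' correctly. These stored instances drive [route_and_classify()].
#'
#' @param model An [ensemble_fit()] result.
#' @param calib A `feature_table` used to build the correct sets.
#' @return The model, with `$stored` populated and `$union` attached.
#' @export
ensemble_calibrate <- function(model, calib) {
  u <- correct_instance_union(model, calib)
  model$stored <- lapply(u$correct_sets, function(idx)
    list(X = calib$features[idx, , drop = FALSE],
         y = calib$labels[idx]))
  model$union <- u[c("correct_sets", "C_final", "union_accuracy", "accuracies")]
  model
}

#' Route new feature vectors to the best-matching classifier
#'
#' For each query row, `Corr_j` is the maximum correlation between the
#' query and any stored correct instance of classifier `j`; the
#' classifier with the largest `Corr_j` (ties broken in the fixed order
#' knn > rf > lr > svm) produces the final prediction. A classifier with
#' no stored correct instances gets `Corr_j = -Inf` and is never chosen.
#'
#' @param model A calibrated [ensemble_calibrate()] model.
#' @param newX Numeric matrix of query feature rows (or one vector).
#' @return Data frame with one row per query: `label`, `classifier`,
#'   `max_corr`, `score` (the chosen classifier's decision score).
#' @export
route_and_classify <- function(model, newX) {
  stopifnot(inherits(model, "ensemble_model"))
  if (is.null(model$stored)) stop("model is not calibrated; run ensemble_calibrate()")
  if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1L)
  corr <- vapply(CLASSIFIER_ORDER, function(m)
    max_row_correlation(model$stored[[m]]$X, newX, model$correlation_mode),
    numeric(nrow(newX)))
  corr <- matrix(corr, nrow = nrow(newX),
                 dimnames = list(NULL, CLASSIFIER_ORDER))
  if (all(!is.finite(corr))) stop("no classifier has stored correct instances")
  choice <- CLASSIFIER_ORDER[max.col(corr, ties.method = "first")]
  out <- data.frame(label = NA_integer_, classifier = choice,
                    max_corr = corr[cbind(seq_len(nrow(newX)),
                                          match(choice, CLASSIFIER_ORDER))],
                    score = NA_real_, stringsAsFactors = FALSE)
  for (m in unique(choice)) {
    rows <- which(choice == m)
    p <- predict_member(model$classifiers, m, newX[rows, , drop = FALSE])
    out$label[rows] <- p$label
    out$score[rows] <- p$score
  }
  out
}

#' Self-augmentation of the training pool
#'
#' If the query's maximum routing correlation strictly exceeds the
#' augmentation threshold (default 0.999), the query's features and its
#' *predicted* label are appended to the training pool and the model is
#' flagged stale (base classifiers must be refitted before further
#' accuracy claims). Otherwise the model is returned unchanged. The pool
#' never shrinks.
#'
#' @param model An `ensemble_model`.
#' @param new_vec Query feature vector.
#' @param predicted_label Its routed prediction.
#' @param max_corr The routing correlation from [route_and_classify()].
#' @return The (possibly augmented) model; `$stale` indicates a pending
#'   refit.
#' @export
maybe_augment <- function(model, new_vec, predicted_label, max_corr) {
  stopifnot(inherits(model, "ensemble_model"))
  if (is.finite(max_corr) && max_corr > model$augment_threshold) {
    model$pool$X <- rbind(model$pool$X, matrix(new_vec, nrow = 1L))
    model$pool$y <- c(model$pool$y, as.integer(predicted_label))
    model$stale <- TRUE
  }
  model
}

#' Refit a stale ensemble on its augmented pool
#'
#' @param model An `ensemble_model` whose pool may have grown.
#' @return A refitted, non-stale model (stored routing instances are
#'   kept; recalibrate to refresh them).
#' @export
ensemble_refit <- function(model) {
  stopifnot(inherits(model, "ensemble_model"))
  pool <- structure(list(features = model$pool$X, labels = model$pool$y,
                         ids = rownames(model$pool$X) %||%
                           paste0("pool_", seq_along(model$pool$y))),
                    class = "feature_table")
  model$classifiers <- fit_base_classifiers(pool, model$spec)
  model$stale <- FALSE
  model
}

#' Save / load an ensemble model bundle
#'
#' The bundle directory holds the serialized model plus a JSON manifest
#' (correlation mode, augmentation threshold, classifier order, pool
#' size, seed).
#'
#' @param model An `ensemble_model`.
#' @param dir Bundle directory.
#' @return `dir` invisibly (save); the model (load).
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "ensemble_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "ensemble.rds"))
  jsonlite::write_json(
    list(correlation_mode = model$correlation_mode,
         augment_threshold = model$augment_threshold,
         classifier_order = CLASSIFIER_ORDER,
         pool_size = length(model$pool$y),
         calibrated = !is.null(model$stored),
         seed = model$spec$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  model <- readRDS(file.path(dir, "ensemble.rds"))
  stopifnot(inherits(model, "ensemble_model"))
  model
}
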