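# The four base classifiers, behind one tiny fit/predict interface.
#
# ranger and e1071 are imported (not just ::-qualified) so their S3
# predict methods are registered even when a fitted model is deserialized
# in a fresh session.

#' @importFrom ranger ranger
#' @importFrom e1071 svm
#' @importFrom SparseM as.matrix.csr
NULL

# Hyperparameters are fixed by the method: 1-nearest neighbour; random
# forest with 100 trees; L2-regularized logistic regression fitted with
# an L-BFGS solver; and an (RBF) support vector machine with stopping
# tolerance 1e-4 (0.01%). Count features are used unscaled throughout.

#' Base-classifier specification
#'
#' @param knn_k Neighbours for the k-NN member (fixed at 1).
#' @param rf_estimators Trees in the random forest (fixed at 100).
#' @param svm_tolerance SVM stopping tolerance (0.01% = 1e-4).
#' @param lr_C Inverse regularization strength of the logistic member.
#' @param seed Integer seed for the stochastic members (random forest).
#' @return A list of class `base_classifier_spec`.
#' @export
base_classifier_spec <- function(knn_k = 1L, rf_estimators = 100L,
                                 svm_tolerance = 1e-4, lr_C = 1, seed = 1L) {
  structure(list(knn_k = as.integer(knn_k),
                 rf_estimators = as.integer(rf_estimators),
                 svm_tolerance = svm_tolerance, lr_C = lr_C,
                 seed = as.integer(seed)),
            class = "base_classifier_spec")
}

# ---- 1-nearest neighbour ----------------------------------------------
# distances computed by cross products (||a-b||^2 = |a|^2 + |b|^2 - 2ab);
# ties broken by the first training row, deterministically

fit_knn1 <- function(X, y) {
  list(kind = "knn", X = X, y = y, sq = rowSums(X^2))
}

predict_knn1 <- function(clf, newX) {
  d2 <- outer(rowSums(newX^2), clf$sq, "+") - 2 * tcrossprod(newX, clf$X)
  idx <- max.col(-d2, ties.method = "first")
  lab <- clf$y[idx]
  list(label = lab, score = as.numeric(lab))
}

# ---- random forest -----------------------------------------------------

fit_rf <- function(X, y, spec) {
  ranger::ranger(y = factor(y, levels = c(0L, 1L)), x = X,
                 num.trees = spec$rf_estimators, probability = TRUE,
                 seed = spec$seed, num.threads = 1L)
}

predict_rf <- function(clf, newX) {
  p1 <- predict(clf, data = newX, num.threads = 1L)$predictions[, "1"]
  list(label = as.integer(p1 > 0.5), score = p1)
}

# ---- logistic regression (L-BFGS, ridge penalty) ----------------------
# minimizes 0.5 ||w||^2 + C * sum log(1 + exp(-y f)), y in {-1, +1}

fit_lr <- function(X, y, C = 1, maxit = 100L) {
  ys <- ifelse(y == 1L, 1, -1)
  p <- ncol(X)
  obj <- function(th) {
    f <- drop(X %*% th[1:p]) + th[p + 1L]
    m <- -ys * f
    0.5 * sum(th[1:p]^2) + C * sum(pmax(m, 0) + log1p(exp(-abs(m))))
  }
  gr <- function(th) {
    f <- drop(X %*% th[1:p]) + th[p + 1L]
    pr <- 1 / (1 + exp(ys * f)) # P(misclassified side)
    a <- -ys * pr
    c(th[1:p] + C * drop(crossprod(X, a)), C * sum(a))
  }
  o <- stats::optim(rep(0, p + 1L), obj, gr, method = "L-BFGS-B",
                    control = list(maxit = maxit))
  list(kind = "lr", w = o$par[1:p], b = o$par[p + 1L],
       convergence = o$convergence)
}

predict_lr <- function(clf, newX) {
  pr <- stats::plogis(drop(newX %*% clf$w) + clf$b)
  list(label = as.integer(pr > 0.5), score = pr)
}

# ---- support vector machine -------------------------------------------

fit_svm <- function(X, y, spec) {
  e1071::svm(SparseM::as.matrix.csr(X), factor(y, levels = c(0L, 1L)),
             tolerance = spec$svm_tolerance, scale = FALSE)
}

predict_svm <- function(clf, newX) {
  pr <- predict(clf, SparseM::as.matrix.csr(newX), decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient the decision value so larger means class "1"
  if (colnames(attr(pr, "decision.values"))[1] == "0/1") dv <- -dv
  list(label = as.integer(as.character(pr)), score = dv)
}

#' Fit the four base classifiers
#'
#' Fits 1-NN, random forest, logistic regression and SVM independently on
#' the same training table. The fixed classifier order `knn`, `rf`, `lr`,
#' `svm` is also the routing tie-break order.
#'
#' @param train A [build_feature_table()] result containing both classes.
#' @param spec A [base_classifier_spec()].
#' @return A named list of fitted classifiers (class `base_classifiers`).
#' @export
fit_base_classifiers <- function(train, spec = base_classifier_spec()) {
  stopifnot(inherits(train, "feature_table"))
  X <- train$features
  y <- train$labels
  if (length(unique(y)) < 2L) stop("single-class training set")
  structure(
    list(knn = fit_knn1(X, y),
         rf = fit_rf(X, y, spec),
         lr = fit_lr(X, y, C = spec$lr_C),
         svm = fit_svm(X, y, spec)),
    class = "base_classifiers"
  )
}

# predictions of one member on a feature matrix
predict_member <- function(clfs, member, newX) {
  switch(member,
    knn = predict_knn1(clfs$knn, newX),
    rf  = predict_rf(clfs$rf, newX),
    lr  = predict_lr(clfs$lr, newX),
    svm = predict_svm(clfs$svm, newX),
    stop("unknown classifier: ", member))
}

CLASSIFIER_ORDER <- c("knn", "rf", "lr", "svm")
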