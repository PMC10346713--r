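# Classifier contracts: pooled-covariance LDA (with optional shrinkage),
# linear SVM (e1071), and KNN with deterministic tie rules.

#' Describe a classifier
#'
#' @param kind \code{"lda"}, \code{"linear_svm"} or \code{"knn"}.
#' @param cost SVM misclassification cost C (> 0; default 1).
#' @param k_n KNN neighbour count (default 5; odd avoids voting ties).
#' @param shrinkage LDA shrinkage in [0, 1] of the pooled covariance toward
#'   the average-variance diagonal (default 0 = plain LDA).
#' @param inner_tuning \code{"off"} (fixed hyperparameters, default) or
#'   \code{"small_grid"} (small inner 3-fold grid search on the training
#'   set: C in \{0.1, 1, 10\}, k_n in \{3, 5, 7\}, shrinkage in
#'   \{0, 0.2, 0.5\}).
#' @return Object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(kind = c("lda", "linear_svm", "knn"), cost = 1,
                            k_n = 5L, shrinkage = 0,
                            inner_tuning = c("off", "small_grid")) {
  kind <- match.arg(kind)
  inner_tuning <- match.arg(inner_tuning)
  if (!is.numeric(cost) || cost <= 0) stopf("cost must be > 0")
  if (!is_count(k_n) || k_n < 1) stopf("k_n must be a positive integer")
  if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
    stopf("shrinkage must be in [0, 1]")
  structure(list(kind = kind, cost = cost, k_n = as.integer(k_n),
                 shrinkage = shrinkage, inner_tuning = inner_tuning),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- switch(x$kind, lda = sprintf("shrinkage = %g", x$shrinkage),
               linear_svm = sprintf("C = %g", x$cost),
               knn = sprintf("k_n = %d", x$k_n))
  cat(sprintf("classifier_spec: %s (%s, tuning: %s)\n", x$kind, hp,
              x$inner_tuning))
  invisible(x)
}

# Binary pooled-covariance linear discriminant.  shrinkage lambda blends the
# pooled covariance with mean(diag(S)) * I.  Matches MASS::lda predictions
# at lambda = 0 (class priors taken from training frequencies).
lda_fit <- function(x, y) {
  i1 <- y == 1L
  n1 <- sum(i1); n2 <- sum(!i1)
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[!i1, , drop = FALSE])
  S <- (crossprod(sweep(x[i1, , drop = FALSE], 2L, mu1)) +
        crossprod(sweep(x[!i1, , drop = FALSE], 2L, mu2))) / (n1 + n2 - 2)
  list(mu1 = mu1, mu2 = mu2, S = S, n1 = n1, n2 = n2)
}

lda_weights <- function(fit, lambda) {
  S <- (1 - lambda) * fit$S +
    lambda * mean(diag(fit$S)) * diag(nrow(fit$S))
  w <- tryCatch(solve(S, fit$mu2 - fit$mu1),
                error = function(e)
                  solve(S + 1e-8 * mean(diag(S)) * diag(nrow(S)),
                        fit$mu2 - fit$mu1))
  thr <- sum(w * (fit$mu1 + fit$mu2)) / 2 - log(fit$n2 / fit$n1)
  list(w = w, thr = thr)
}

# KNN with deterministic tie rules: stable neighbour ordering by (distance,
# training index); a voting tie falls back to the nearest single neighbour;
# an exact distance tie there falls back to the lowest class id.
knn_predict <- function(train_x, y, test_x, k) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), `+`) -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1L, function(d) {
    ord <- order(d)                          # stable: index breaks ties
    votes <- tabulate(y[ord[seq_len(k)]], 2L)
    if (votes[1L] != votes[2L]) return(which.max(votes))
    nearest <- which(d <= d[ord[1L]] + 1e-12)
    min(y[nearest])
  })
}

#' Train a classifier on one split and score the test set
#'
#' Fits the classifier described by \code{spec} on the training table and
#' returns the fraction of test samples whose predicted class matches their
#' label.  The fit never reads the test rows.  With
#' \code{inner_tuning = "small_grid"} the hyperparameter is chosen by a
#' deterministic inner 3-fold cross-validation on the training set first.
#'
#' @param spec A [classifier_spec()].
#' @param train,test \code{feature_table}s with identical features; the
#'   training set must contain both classes.
#' @return Accuracy in [0, 1], with the predicted test labels as attribute
#'   \code{"predictions"}.
#' @export
train_eval <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_table"),
            inherits(test, "feature_table"))
  if (!identical(colnames(train$x), colnames(test$x)))
    stopf("train and test feature names differ")
  lev <- sort(unique(train$meta$class_label))
  if (length(lev) < 2L)
    stopf("degenerate fold: training set contains a single class")
  if (length(lev) > 2L) stopf("only binary classification is supported")
  y <- match(train$meta$class_label, lev)
  spec <- tune_spec(spec, train$x, y)
  pred <- fit_predict(spec, train$x, y, test$x)
  predictions <- lev[pred]
  acc <- mean(predictions == test$meta$class_label)
  attr(acc, "predictions") <- predictions
  acc
}

fit_predict <- function(spec, train_x, y, test_x) {
  switch(spec$kind,
    lda = {
      lw <- lda_weights(lda_fit(train_x, y), spec$shrinkage)
      ifelse(test_x %*% lw$w > lw$thr, 2L, 1L)
    },
    linear_svm = {
      fit <- e1071::svm(train_x, factor(y, levels = 1:2), kernel = "linear",
                        cost = spec$cost, scale = FALSE)
      as.integer(as.character(predict(fit, test_x)))
    },
    knn = knn_predict(train_x, y, test_x, spec$k_n))
}

# Deterministic inner 3-fold grid search (fold assignment is a fixed
# function of the training set size).
tune_spec <- function(spec, train_x, y) {
  if (spec$inner_tuning == "off") return(spec)
  grid <- switch(spec$kind,
    lda = lapply(c(0, 0.2, 0.5), function(v) list(shrinkage = v)),
    linear_svm = lapply(c(0.1, 1, 10), function(v) list(cost = v)),
    knn = lapply(c(3L, 5L, 7L), function(v) list(k_n = v)))
  n <- nrow(train_x)
  folds <- with_seed(n, split(sample.int(n), rep(1:3, length.out = n)))
  score <- vapply(grid, function(hp) {
    s2 <- spec
    s2[names(hp)] <- hp
    s2$inner_tuning <- "off"
    mean(vapply(folds, function(te) {
      if (length(unique(y[-te])) < 2L || length(te) == 0) return(NA_real_)
      mean(fit_predict(s2, train_x[-te, , drop = FALSE], y[-te],
                       train_x[te, , drop = FALSE]) == y[te])
    }, 0), na.rm = TRUE)
  }, 0)
  best <- grid[[which.max(score)]]
  spec[names(best)] <- best
  spec$inner_tuning <- "off"
  spec
}
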