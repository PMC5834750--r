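#' Multiclass adaptive boosting over decision trees (SAMME)
#'
#' Boosts shallow classification trees with the SAMME re-weighting scheme,
#' which reduces to classical two-class AdaBoost when there are two
#' labels. The default weak learner is a decision stump (depth 1), a
#' conservative choice for small-sample feature tables.
#'
#' @param features Data frame of numeric predictors.
#' @param labels Factor of class labels (>= 2 classes, >= 4 subjects).
#' @param n_rounds Number of boosting rounds (learning cycles).
#' @param tree_depth Maximum depth of each weak learner.
#' @return Object of class `adaboost`: list of weak learners, their
#'   weights, and the class levels.
#' @export
adaboost_fit <- function(features, labels, n_rounds = 100, tree_depth = 1) {
  features <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(features)
  k <- nlevels(labels)
  if (k < 2) stop_sivd("need at least two classes")
  if (n < 4) stop_sivd("need at least four subjects")
  dat <- cbind(features, .y = labels)
  fml <- stats::as.formula(paste(".y ~", paste(names(features), collapse = " + ")))
  ctrl <- rpart::rpart.control(maxdepth = tree_depth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  eps <- 1e-10
  for (m in seq_len(n_rounds)) {
    dat$.w <- w * n
    fit <- rpart::rpart(fml, data = dat, weights = .w, method = "class",
                        control = ctrl)
    pred <- predict(fit, dat, type = "class")
    err <- sum(w[pred != labels])
    if (err >= 1 - 1 / k) break  # weak-learner condition violated
    err <- max(err, eps)
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= eps) break  # perfect fit: further rounds cannot reweight
    w <- w * exp(alpha * (pred != labels))
    w <- w / sum(w)
  }
  if (length(trees) == 0) stop_sivd("no usable weak learner found")
  structure(list(trees = trees, alphas = alphas, classes = levels(labels),
                 n_rounds = n_rounds, tree_depth = tree_depth),
            class = "adaboost")
}

#' Predict classes from a boosted model
#'
#' @param object An `adaboost` model.
#' @param newdata Data frame of predictors.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.adaboost <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in seq_along(object$trees)) {
    pred <- as.character(predict(object$trees[[m]], newdata, type = "class"))
    votes[cbind(seq_len(nrow(newdata)), match(pred, object$classes))] <-
      votes[cbind(seq_len(nrow(newdata)), match(pred, object$classes))] +
      object$alphas[m]
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Leave-one-out cross-validation of the boosted classifier
#'
#' Fits the model n times, each time holding out one subject, and
#' aggregates the held-out predictions into a confusion matrix.
#'
#' @param features Data frame of predictors.
#' @param labels Class labels.
#' @param n_rounds,tree_depth Passed to [adaboost_fit()].
#' @return List with `predictions` (factor), `confusion` (true x
#'   predicted), `accuracy`.
#' @export
loocv_adaboost <- function(features, labels, n_rounds = 100, tree_depth = 1) {
  features <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(features)
  if (n < 4) stop_sivd("need at least four subjects")
  preds <- character(n)
  for (s in seq_len(n)) {
    train_lab <- droplevels(labels[-s])
    if (nlevels(train_lab) < nlevels(labels)) {
      warning("training fold ", s, " lost a class; predicting from the rest")
    }
    fit <- adaboost_fit(features[-s, , drop = FALSE], train_lab,
                        n_rounds, tree_depth)
    preds[s] <- as.character(predict(fit, features[s, , drop = FALSE]))
  }
  preds <- factor(preds, levels = levels(labels))
  confusion <- table(true = labels, predicted = preds)
  list(predictions = preds, confusion = confusion,
       accuracy = sum(diag(confusion)) / n)
}

#' One-vs-rest sensitivity and specificity from a confusion matrix
#'
#' @param confusion Square table/matrix, rows = true classes, columns =
#'   predicted classes.
#' @param positive_class Name of the positive class.
#' @return List with `sensitivity` and `specificity` (`NaN` with a warning
#'   when a denominator is zero).
#' @export
sensitivity_specificity <- function(confusion, positive_class) {
  confusion <- as.matrix(confusion)
  if (!positive_class %in% rownames(confusion)) {
    stop_sivd("positive class not present in the confusion matrix")
  }
  pos <- positive_class
  tp <- confusion[pos, pos]
  fn <- sum(confusion[pos, ]) - tp
  fp <- sum(confusion[, pos]) - tp
  tn <- sum(confusion) - tp - fn - fp
  sens <- if (tp + fn == 0) { warning("no true positives or false negatives"); NaN } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no true negatives or false positives"); NaN } else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec)
}
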