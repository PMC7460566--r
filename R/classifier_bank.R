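# Binary classifier bank and evaluation metrics.
#
# Four classifiers judge the resolving ability of a gene subset: logistic
# regression (GLM), linear-kernel SVM with cross-validated cost, a single
# CART decision tree and a 10-tree random forest. Every trained model obeys
# one contract: `px_score()` returns the tumor-class probability in [0, 1]
# and `predict()` returns 1 iff that score >= 0.5. Evaluation uses the
# standard confusion-matrix criteria (accuracy, precision, recall, F-measure,
# Matthews correlation coefficient) and the Mann-Whitney formulation of the
# area under the ROC curve.

#' Stratified train/test split
#'
#' Samples each class without replacement; the per-class training count is
#' `round(train_frac * class size)` with half-up rounding. Deterministic for
#' a given seed.
#'
#' @param labels A [sample_labels()] vector (both classes >= 2 samples).
#' @param train_frac Training fraction in (0, 1); default 0.6.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` of sample ids.
#' @examples
#' lab <- sample_labels(stats::setNames(rep(0:1, each = 10), paste0("s", 1:20)))
#' sp <- stratified_split(lab, 0.6, seed = 1)
#' lengths(sp) # 12 train, 8 test
#' @export
stratified_split <- function(labels, train_frac = 0.6, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) .stopf("train_frac must be in (0, 1)")
  ids <- names(labels)
  if (is.null(ids)) .stopf("labels must be named by sample id")
  train <- character(0)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      cls_ids <- ids[labels == cls]
      if (length(cls_ids) < 2) {
        .stopf("class %d has fewer than 2 samples", cls)
      }
      n_tr <- .round_half_up(train_frac * length(cls_ids))
      n_tr <- min(max(n_tr, 1L), length(cls_ids) - 1L)
      train <- c(train, sample(cls_ids, n_tr))
    }
  })
  list(train = train, test = setdiff(ids, train))
}

#' Train a binary classifier
#'
#' @param kind One of `"glm"` (binomial logit), `"svm"` (linear kernel,
#'   cost chosen by seeded k-fold cross-validation over `cost_grid`),
#'   `"cart"` (single decision tree) or `"rf"` (random forest of `n_trees`
#'   trees).
#' @param x Numeric training matrix, rows = samples.
#' @param y Integer 0/1 labels (both classes present).
#' @param seed Integer seed for stochastic fitting steps.
#' @param cost_grid SVM cost candidates (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param n_folds CV folds for the SVM cost search (default 10, reduced to
#'   the sample count when needed).
#' @param n_trees Random-forest size (default 10).
#' @return A `px_model` object with a [predict()] method; see [px_score()].
#' @export
train_classifier <- function(kind = c("glm", "svm", "cart", "rf"), x, y,
                             seed = 1,
                             cost_grid = c(0.01, 0.1, 1, 10, 100),
                             n_folds = 10, n_trees = 10) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) .stopf("x and y sizes differ")
  if (length(unique(y)) < 2) .stopf("training data must contain both classes")
  colnames(x) <- .feature_names(x)

  # degenerate design: no feature varies -> majority-class model
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    fit <- list(p = mean(y))
    return(structure(list(kind = kind, fit = fit, features = colnames(x),
                          degenerate = TRUE),
                     class = "px_model"))
  }

  yf <- factor(y, levels = c(0, 1))
  df <- data.frame(x, check.names = FALSE)
  df$.y <- yf
  fit <- switch(kind,
    glm = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial("logit"))
    ),
    svm = {
      cost <- .tune_svm_cost(x, yf, cost_grid, n_folds, seed)
      with_seed(seed,
        e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE,
                   probability = TRUE))
    },
    cart = rpart::rpart(.y ~ ., data = df, method = "class"),
    rf = with_seed(seed, randomForest::randomForest(x, yf, ntree = n_trees))
  )
  structure(list(kind = kind, fit = fit, features = colnames(x),
                 degenerate = FALSE),
            class = "px_model")
}

.feature_names <- function(x) {
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  make.names(nm, unique = TRUE)
}

# seeded k-fold CV accuracy over the cost grid; first maximum wins
.tune_svm_cost <- function(x, yf, cost_grid, n_folds, seed) {
  n <- nrow(x)
  k <- min(n_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  acc <- vapply(cost_grid, function(cost) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(yf[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    correct / n
  }, numeric(1))
  cost_grid[which.max(acc)]
}

#' Tumor-class probability score of a trained model
#'
#' @param model A `px_model` from [train_classifier()].
#' @param newx Numeric matrix of samples to score.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
px_score <- function(model, newx) {
  stopifnot(inherits(model, "px_model"))
  newx <- as.matrix(newx)
  colnames(newx) <- model$features
  if (isTRUE(model$degenerate)) {
    return(rep(model$fit$p, nrow(newx)))
  }
  df <- data.frame(newx, check.names = FALSE)
  p <- switch(model$kind,
    glm = as.numeric(stats::predict(model$fit, newdata = df,
                                    type = "response")),
    svm = {
      pr <- predict(model$fit, newx, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    cart = as.numeric(stats::predict(model$fit, newdata = df,
                                     type = "prob")[, "1"]),
    rf = as.numeric(stats::predict(model$fit, newdata = newx,
                                   type = "prob")[, "1"])
  )
  pmin(pmax(p, 0), 1)
}

#' Predict hard 0/1 classes
#'
#' @param object A `px_model`.
#' @param newx Matrix of samples.
#' @param ... Unused.
#' @return Integer vector: 1 iff the tumor score is >= 0.5.
#' @export
predict.px_model <- function(object, newx, ...) {
  as.integer(px_score(object, newx) >= 0.5)
}

#' @export
print.px_model <- function(x, ...) {
  cat(sprintf("px_model: %s%s (%d features)\n", x$kind,
              if (isTRUE(x$degenerate)) " [majority-class fallback]" else "",
              length(x$features)))
  invisible(x)
}

#' Confusion matrix with tumor (1) as the positive class
#'
#' @param y_true,y_pred Equal-length integer vectors with values in `{0, 1}`.
#' @return A `confusion` list with counts `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) .stopf("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    .stopf("labels must be 0 or 1")
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FN=%d FP=%d TN=%d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' F-measure from precision and recall
#'
#' Harmonic mean `F = 2 PR RC / (PR + RC)`; 0 when both are 0.
#'
#' @param pr Precision.
#' @param rc Recall.
#' @return F-measure in `[0, 1]`.
#' @examples
#' f_measure(0.895, 0.708) # ~0.791
#' @export
f_measure <- function(pr, rc) {
  ifelse(pr + rc == 0, 0, 2 * pr * rc / (pr + rc))
}

#' Classifier quality criteria from a confusion matrix
#'
#' Accuracy `AC = (TP + TN) / total`, precision `PR = TP / (TP + FP)`,
#' recall `RC = TP / (TP + FN)`, F-measure (harmonic mean of PR and RC) and
#' the Matthews correlation coefficient
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any 0/0 is reported as 0 with a warning.
#'
#' @param cm A [confusion()] object.
#' @return Named numeric vector `AC`, `PR`, `RC`, `F`, `MCC`.
#' @export
classifier_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0) .stopf("empty confusion matrix")
  zdiv <- function(num, den, what) {
    if (den == 0) {
      .warnf("%s undefined (0/0): reporting 0", what)
      0
    } else {
      num / den
    }
  }
  ac <- (cm$TP + cm$TN) / total
  pr <- zdiv(cm$TP, cm$TP + cm$FP, "precision")
  rc <- zdiv(cm$TP, cm$TP + cm$FN, "recall")
  f <- f_measure(pr, rc)
  mcc_den <- sqrt(prod(c(cm$TP + cm$FP, cm$TP + cm$FN,
                         cm$TN + cm$FP, cm$TN + cm$FN)))
  mcc <- if (mcc_den == 0) {
    .warnf("MCC undefined (zero factor): reporting 0")
    0
  } else {
    (cm$TP * cm$TN - cm$FP * cm$FN) / mcc_den
  }
  c(AC = ac, PR = pr, RC = rc, F = f, MCC = mcc)
}

#' ROC curve and AUC
#'
#' AUC uses the Mann-Whitney formulation: the probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties counted as
#' one half. ROC points are computed at every score threshold.
#'
#' @param y_true Integer 0/1 truth vector (both classes present).
#' @param scores Numeric scores, higher = more tumor-like.
#' @return List with `auc` and `roc` (data.frame `threshold, fpr, tpr`).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) .stopf("lengths differ")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) .stopf("both classes required for ROC analysis")
  r <- rank(scores) # average ranks handle ties as 1/2
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & y_true == 0) / n0,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & y_true == 1) / n1,
                 numeric(1))
  )
  list(auc = auc, roc = roc)
}
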