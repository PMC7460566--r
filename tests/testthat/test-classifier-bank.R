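test_that("stratified split sizes follow half-up per-class rounding", {
  lab <- balanced_labels(paste0("s", 1:20))
  sp <- stratified_split(lab, 0.6, seed = 1)
  expect_equal(length(sp$train), 12L)
  expect_equal(length(sp$test), 8L)
  expect_equal(sum(lab[sp$train] == 0), 6L)
  expect_equal(sum(lab[sp$train] == 1), 6L)

  # 65 healthy + 91 tumor at 0.6 -> 39 + 55 = 94 train, 62 test
  big <- sample_labels(stats::setNames(rep(c(0L, 1L), c(65, 91)),
                                       paste0("p", 1:156)))
  spb <- stratified_split(big, 0.6, seed = 2)
  expect_equal(sum(big[spb$train] == 0), 39L)
  expect_equal(sum(big[spb$train] == 1), 55L)
  expect_equal(length(spb$test), 62L)

  expect_identical(stratified_split(lab, 0.6, seed = 7),
                   stratified_split(lab, 0.6, seed = 7))
  expect_false(identical(stratified_split(lab, 0.6, seed = 7),
                         stratified_split(lab, 0.6, seed = 8)))
})

test_that("every classifier kind learns a separable toy problem", {
  set.seed(30)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y * 4 + rnorm(n, sd = 0.2), f2 = rnorm(n))
  for (kind in c("glm", "svm", "cart", "rf")) {
    m <- train_classifier(kind, x, y, seed = 1)
    expect_equal(mean(predict(m, x) == y), 1, info = kind)
    s <- px_score(m, x)
    expect_true(all(s >= 0 & s <= 1), info = kind)
    expect_equal(predict(m, x), as.integer(s >= 0.5), info = kind)
  }
})

test_that("constant features degrade to majority-class prediction", {
  y <- rep(c(0L, 1L), c(7, 13))
  x <- matrix(5, 20, 3)
  for (kind in c("glm", "svm", "cart", "rf")) {
    m <- train_classifier(kind, x, y, seed = 1)
    expect_equal(predict(m, x), rep(1L, 20), info = kind) # majority = tumor
  }
})

test_that("confusion counts follow the tumor-positive convention", {
  y <- rep(c(1L, 0L), each = 5)
  cm <- confusion(y, y)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]), c(TP = 5, FN = 0, FP = 0, TN = 5))
  cm2 <- confusion(y, 1L - y)
  expect_equal(unlist(cm2[c("TP", "FN", "FP", "TN")]), c(TP = 0, FN = 5, FP = 5, TN = 0))
  # hand tally on a mixed vector of 8 samples
  yt <- c(1, 1, 1, 0, 0, 0, 1, 0)
  yp <- c(1, 0, 1, 1, 0, 0, 0, 1)
  cm3 <- confusion(yt, yp)
  expect_equal(unlist(cm3[c("TP", "FN", "FP", "TN")]), c(TP = 2, FN = 2, FP = 2, TN = 2))
  expect_error(confusion(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("metrics match the printed-table identities and hand arithmetic", {
  expect_equal(round(f_measure(0.895, 0.708), 3), 0.791)
  cm <- structure(list(TP = 1, FN = 1, FP = 1, TN = 1), class = "confusion")
  expect_equal(classifier_metrics(cm)[["MCC"]], 0)
  cm2 <- structure(list(TP = 17, FN = 7, FP = 2, TN = 20), class = "confusion")
  met <- classifier_metrics(cm2)
  expect_equal(met[["AC"]], 37 / 46, tolerance = 1e-12)
  expect_equal(met[["PR"]], 17 / 19, tolerance = 1e-12)
  expect_equal(met[["RC"]], 17 / 24, tolerance = 1e-12)
})

test_that("metrics agree with the naive oracle and F stays between PR and RC", {
  for (tp in 0:4) for (fn in 0:4) for (fp in 0:4) for (tn in 0:4) {
    if (tp + fn + fp + tn == 0) next
    cm <- structure(list(TP = tp, FN = fn, FP = fp, TN = tn),
                    class = "confusion")
    got <- suppressWarnings(classifier_metrics(cm))
    expect_equal(got, naive_metrics(tp, fn, fp, tn), tolerance = 1e-12)
    if (got[["PR"]] > 0 && got[["RC"]] > 0) {
      expect_gte(got[["F"]], min(got[["PR"]], got[["RC"]]) - 1e-12)
      expect_lte(got[["F"]], max(got[["PR"]], got[["RC"]]) + 1e-12)
    }
  }
})

test_that("AUC uses the Mann-Whitney formulation with half-ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)

  set.seed(41)
  y <- rep(c(0L, 1L), each = 15)
  s <- rnorm(30) + y
  s[3] <- s[20] # inject a cross-class tie
  expect_equal(roc_auc(y, s)$auc, naive_auc(y, s), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(y, exp(2 * s))$auc, roc_auc(y, s)$auc, tolerance = 1e-12)
  expect_error(roc_auc(rep(1, 4), 1:4), "both classes")
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rep(c(0L, 1L), each = 20)
  s <- rnorm(40) + 0.8 * y
  want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                         direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(y, s)$auc, want, tolerance = 1e-10)
})

test_that("a linear SVM separates the planted expression classes", {
  accs <- vapply(1:5, function(seed) {
    sim <- generate_synthetic(synth_config(seed = seed))
    blk <- which(sim$truth$role == "block")
    sp <- stratified_split(sim$labels, 0.6, seed = seed)
    xtr <- sim$dataset$values[match(sp$train, sim$dataset$sample_ids), blk]
    xte <- sim$dataset$values[match(sp$test, sim$dataset$sample_ids), blk]
    m <- train_classifier("svm", xtr, as.integer(sim$labels[sp$train]),
                          seed = seed)
    mean(predict(m, xte) == as.integer(sim$labels[sp$test]))
  }, numeric(1))
  expect_gte(median(accs), 0.95)
})
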