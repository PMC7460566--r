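# Mamdani fuzzy inference system fusing the SVM, CART and RF outputs.
#
# Each classifier output (a tumor probability in [0, 1]) is fuzzified into
# the input terms "Healthy" (HL) and "Tumor" (TM); the 8-rule base covers
# every combination of the three inputs, with a majority-structured
# consequent over the output terms HL < PHL ("probably healthy") < PTM
# ("probably tumor") < TM. Inference is classic Mamdani: min for rule
# activation, clipping of the consequent terms, max accumulation, and
# centroid defuzzification of the accumulated membership function on a
# uniform grid. The crisp output FS in [0, 1] is the final health-state
# score; FS >= threshold (default 0.5) is called tumor.

#' Trapezoidal membership function
#'
#' @param a,b,c,d Non-decreasing breakpoints in `[0, 1]`; membership rises
#'   linearly on `[a, b]`, is 1 on `[b, c]` and falls on `[c, d]`.
#' @return A `membership_function` object.
#' @export
mf_trapezoid <- function(a, b, c, d) {
  pts <- c(a, b, c, d)
  if (is.unsorted(pts)) .stopf("trapezoid breakpoints must be non-decreasing")
  if (any(pts < 0) || any(pts > 1)) .stopf("breakpoints must lie in [0, 1]")
  structure(list(shape = "trapezoid", pts = pts), class = "membership_function")
}

#' Triangular membership function
#'
#' @param a,b,c Non-decreasing breakpoints in `[0, 1]`; membership peaks at
#'   `b`.
#' @return A `membership_function` object.
#' @export
mf_triangle <- function(a, b, c) {
  pts <- c(a, b, c)
  if (is.unsorted(pts)) .stopf("triangle breakpoints must be non-decreasing")
  if (any(pts < 0) || any(pts > 1)) .stopf("breakpoints must lie in [0, 1]")
  structure(list(shape = "triangle", pts = pts), class = "membership_function")
}

#' Evaluate a membership function
#'
#' Piecewise-linear evaluation; values outside `[0, 1]` are clamped to the
#' universe with a warning.
#'
#' @param mf A [mf_trapezoid()] or [mf_triangle()].
#' @param x Numeric vector of crisp values.
#' @return Membership degrees in `[0, 1]`.
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  if (any(x < 0 | x > 1)) {
    .warnf("crisp value outside [0, 1]: clamping to the universe")
    x <- pmin(pmax(x, 0), 1)
  }
  p <- mf$pts
  if (mf$shape == "triangle") p <- c(p[1], p[2], p[2], p[3])
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  left <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  right <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  pmax(0, pmin(1, left, right))
}

#' The 8-rule majority rule base
#'
#' One rule per combination of the three input terms (`"TM"`/`"HL"` for each
#' of x_SVM, x_CART, x_RF). The consequent is `TM` when all three vote
#' tumor, `PTM` for exactly two tumor votes, `PHL` for exactly one, and `HL`
#' when none do.
#'
#' @return Data frame with columns `x_svm`, `x_cart`, `x_rf`, `fs`.
#' @export
default_rule_base <- function() {
  rules <- expand.grid(x_svm = c("TM", "HL"), x_cart = c("TM", "HL"),
                       x_rf = c("TM", "HL"), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_tm <- rowSums(rules == "TM")
  rules$fs <- c("HL", "PHL", "PTM", "TM")[n_tm + 1]
  rules
}

.validate_rule_base <- function(rules) {
  need <- c("x_svm", "x_cart", "x_rf", "fs")
  if (!all(need %in% names(rules))) {
    .stopf("rule base needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(rules) != 8) .stopf("rule base must contain exactly 8 rules")
  key <- do.call(paste, rules[c("x_svm", "x_cart", "x_rf")])
  if (anyDuplicated(key)) .stopf("duplicate antecedent combination in rule base")
  if (!all(unlist(rules[c("x_svm", "x_cart", "x_rf")]) %in% c("TM", "HL"))) {
    .stopf("input terms must be TM or HL")
  }
  if (!all(rules$fs %in% c("HL", "PHL", "PTM", "TM"))) {
    .stopf("output terms must be HL, PHL, PTM or TM")
  }
  invisible(rules)
}

#' Construct a Mamdani fuzzy fusion system
#'
#' The default membership layout covers the whole `[0, 1]` universe with
#' ordered, slightly overlapping terms (so every crisp value has positive
#' membership in at least one term): inputs `HL = trapezoid(0, 0, 0.2,
#' 0.55)`, `TM = trapezoid(0.45, 0.8, 1, 1)`; output `HL = trapezoid(0, 0,
#' 0.15, 0.35)`, `PHL = triangle(0.25, 0.4, 0.55)`, `PTM = triangle(0.45,
#' 0.6, 0.75)`, `TM = trapezoid(0.65, 0.85, 1, 1)`.
#'
#' @param input_terms Named list of `membership_function`s for the input
#'   terms `HL` and `TM` (shared by the three inputs).
#' @param output_terms Named list of `membership_function`s for the output
#'   terms `HL`, `PHL`, `PTM`, `TM`.
#' @param rules Rule base data frame, see [default_rule_base()].
#' @return A `fuzzy_system` object.
#' @export
fuzzy_system <- function(input_terms = NULL, output_terms = NULL,
                         rules = default_rule_base()) {
  if (is.null(input_terms)) {
    input_terms <- list(HL = mf_trapezoid(0, 0, 0.2, 0.55),
                        TM = mf_trapezoid(0.45, 0.8, 1, 1))
  }
  if (is.null(output_terms)) {
    output_terms <- list(HL = mf_trapezoid(0, 0, 0.15, 0.35),
                         PHL = mf_triangle(0.25, 0.4, 0.55),
                         PTM = mf_triangle(0.45, 0.6, 0.75),
                         TM = mf_trapezoid(0.65, 0.85, 1, 1))
  }
  if (!all(c("HL", "TM") %in% names(input_terms))) {
    .stopf("input_terms must contain HL and TM")
  }
  if (!all(c("HL", "PHL", "PTM", "TM") %in% names(output_terms))) {
    .stopf("output_terms must contain HL, PHL, PTM and TM")
  }
  .validate_rule_base(rules)
  structure(list(input_terms = input_terms, output_terms = output_terms,
                 rules = rules),
            class = "fuzzy_system")
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat(sprintf("fuzzy_system: 3 inputs (terms %s), output terms %s, %d rules\n",
              paste(names(x$input_terms), collapse = "/"),
              paste(names(x$output_terms), collapse = "/"), nrow(x$rules)))
  invisible(x)
}

#' Default fuzzy fusion system
#'
#' @return The [fuzzy_system()] with default membership layout and the
#'   8-rule majority base.
#' @export
default_fuzzy_system <- function() fuzzy_system()

#' Mamdani inference
#'
#' Computes the crisp final-state value FS for one or more triples of crisp
#' classifier outputs. Per rule the activation is the `min` of its three
#' antecedent memberships; each consequent term is clipped at its rule's
#' activation; the accumulated output membership is the pointwise `max` over
#' rules; FS is the centroid `sum(x mu(x)) / sum(mu(x))` over a uniform grid
#' of `grid_n` points. If the accumulated function is identically zero, FS
#' is 0.5 with a warning.
#'
#' @param system A [fuzzy_system()].
#' @param x_svm,x_cart,x_rf Numeric vectors of crisp inputs in `[0, 1]`
#'   (recycled to a common length by strict equality check).
#' @param grid_n Defuzzification grid size >= 101 (default 1001).
#' @return Numeric vector of FS values in `[0, 1]`.
#' @examples
#' fs <- fuzzy_infer(default_fuzzy_system(), 1, 1, 1)
#' round(fs, 3) # ~0.868, the centroid of the output TM trapezoid
#' @export
fuzzy_infer <- function(system, x_svm, x_cart, x_rf, grid_n = 1001) {
  stopifnot(inherits(system, "fuzzy_system"))
  if (grid_n < 101) .stopf("grid_n must be >= 101")
  n <- length(x_svm)
  if (length(x_cart) != n || length(x_rf) != n) {
    .stopf("input vectors must have equal length")
  }
  grid <- seq(0, 1, length.out = grid_n)
  out_mu <- lapply(system$output_terms, membership, x = grid)
  in_mu <- lapply(system$input_terms, function(mf) {
    cbind(svm = membership(mf, x_svm), cart = membership(mf, x_cart),
          rf = membership(mf, x_rf))
  })
  agg <- matrix(0, n, grid_n)
  for (r in seq_len(nrow(system$rules))) {
    act <- pmin(in_mu[[system$rules$x_svm[r]]][, "svm"],
                in_mu[[system$rules$x_cart[r]]][, "cart"],
                in_mu[[system$rules$x_rf[r]]][, "rf"])
    if (all(act == 0)) next
    cons <- out_mu[[system$rules$fs[r]]]
    clipped <- pmin(matrix(act, n, grid_n),
                    matrix(cons, n, grid_n, byrow = TRUE))
    agg <- pmax(agg, clipped)
  }
  mass <- rowSums(agg)
  fs <- numeric(n)
  zero <- mass == 0
  if (any(zero)) {
    .warnf("accumulated membership identically zero for %d input(s): FS = 0.5",
           sum(zero))
    fs[zero] <- 0.5
  }
  if (any(!zero)) {
    fs[!zero] <- as.vector(agg[!zero, , drop = FALSE] %*% grid) / mass[!zero]
  }
  fs
}

#' Crisp final decision
#'
#' @param fs FS values in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5); ties go to tumor.
#' @return Integer vector: 1 (tumor) iff `fs >= threshold`, else 0 (healthy).
#' @export
final_class <- function(fs, threshold = 0.5) {
  as.integer(fs >= threshold)
}

#' Fuse three classifiers on a test set and score the fusion
#'
#' Scores each test sample with the SVM, CART and RF models (tumor
#' probabilities by default, hard 0/1 predictions optionally), runs Mamdani
#' inference on the triple, thresholds FS into the final class and evaluates
#' the fused decisions against the truth.
#'
#' @param models Named list with elements `svm`, `cart`, `rf` of class
#'   `px_model`.
#' @param x_test Numeric test matrix.
#' @param y_test Integer 0/1 truth labels.
#' @param system A [fuzzy_system()] (default [default_fuzzy_system()]).
#' @param grid_n Defuzzification grid size.
#' @param threshold Decision threshold on FS.
#' @param use_probabilities If `FALSE`, feed hard 0/1 predictions into the
#'   system instead of probabilities.
#' @return List with `per_sample` (data.frame `x_svm, x_cart, x_rf, fs,
#'   class, truth`), `metrics` (see [classifier_metrics()]) and `auc` of the
#'   FS scores.
#' @export
fuse_and_score <- function(models, x_test, y_test,
                           system = default_fuzzy_system(), grid_n = 1001,
                           threshold = 0.5, use_probabilities = TRUE) {
  if (!all(c("svm", "cart", "rf") %in% names(models))) {
    .stopf("models must be a named list with svm, cart and rf")
  }
  x_test <- as.matrix(x_test)
  y_test <- as.integer(y_test)
  getx <- function(m) {
    if (use_probabilities) px_score(m, x_test) else
      as.numeric(predict(m, x_test))
  }
  xs <- getx(models$svm)
  xc <- getx(models$cart)
  xr <- getx(models$rf)
  fs <- fuzzy_infer(system, xs, xc, xr, grid_n = grid_n)
  cls <- final_class(fs, threshold)
  cm <- confusion(y_test, cls)
  list(
    per_sample = data.frame(x_svm = xs, x_cart = xc, x_rf = xr, fs = fs,
                            class = cls, truth = y_test),
    metrics = classifier_metrics(cm),
    auc = roc_auc(y_test, fs)$auc
  )
}

#' Serialise a fuzzy system to YAML
#'
#' @param system A [fuzzy_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fuzzy_system <- function(system, path) {
  stopifnot(inherits(system, "fuzzy_system"))
  ser_mf <- function(mf) list(shape = mf$shape, points = as.numeric(mf$pts))
  obj <- list(
    input_terms = lapply(system$input_terms, ser_mf),
    output_terms = lapply(system$output_terms, ser_mf),
    rules = lapply(seq_len(nrow(system$rules)), function(i) {
      as.list(system$rules[i, c("x_svm", "x_cart", "x_rf", "fs")])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a fuzzy system from YAML
#'
#' @param path Path written by [write_fuzzy_system()].
#' @return A [fuzzy_system()].
#' @export
read_fuzzy_system <- function(path) {
  obj <- yaml::read_yaml(path)
  de_mf <- function(s) {
    if (s$shape == "trapezoid") do.call(mf_trapezoid, as.list(s$points))
    else do.call(mf_triangle, as.list(s$points))
  }
  rules <- do.call(rbind, lapply(obj$rules, function(r) {
    data.frame(x_svm = r$x_svm, x_cart = r$x_cart, x_rf = r$x_rf, fs = r$fs,
               stringsAsFactors = FALSE)
  }))
  fuzzy_system(input_terms = lapply(obj$input_terms, de_mf),
               output_terms = lapply(obj$output_terms, de_mf),
               rules = rules)
}
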