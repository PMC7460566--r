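# End-to-end orchestration of the stepwise extraction procedure:
# filter -> SOTA levels 1..N -> per-level cluster selection -> per-level
# classifier bank -> per-level fuzzy fusion -> report.

#' Run the stepwise gene-extraction pipeline
#'
#' Executes the full procedure on an in-memory dataset: boundary-scan
#' filtering, level-wise SOTA clustering of the kept genes, selection of the
#' best cluster per hierarchical level, training/evaluation of the
#' classifier bank on each selected cluster under a stratified 60/40 split,
#' and Mamdani fusion of the SVM/CART/RF outputs. The "chosen" level is the
#' selectable level with the highest fused F-measure; the full per-level
#' table is retained so an analyst can override that rule.
#'
#' @param dataset An [expression_dataset()].
#' @param labels A [sample_labels()] covering the dataset.
#' @param max_level Deepest hierarchical level (default 4).
#' @param n_bins Entropy bins for filtering (default 10).
#' @param n_steps Boundary-scan steps (default 50).
#' @param filter_mode Keep semantics, see [apply_boundaries()].
#' @param size_bounds Per-level cluster size bounds (default `c(10, Inf)`).
#' @param train_frac Training fraction for the stratified split (default 0.6).
#' @param seed One pipeline seed; split and classifier seeds fan out from it.
#' @param sota A [sota_params()] object.
#' @param system A [fuzzy_system()] for the fusion stage.
#' @param classifiers Classifier kinds to train (default all four).
#' @param grid_n Defuzzification grid size.
#' @param out_dir Optional directory; when given, per-stage CSVs, the tree
#'   JSON, the kept-gene list and the report JSON are written there.
#' @return A `pipeline_report` list: `filter` (per-step table + best step),
#'   `selection` (per-level best clusters), `metrics` (per level x
#'   classifier), `fusion` (per-level fused metrics), `chosen_level`,
#'   `chosen_genes`, `seed` and the configuration echo.
#' @export
run_pipeline <- function(dataset, labels, max_level = 4, n_bins = 10,
                         n_steps = 50,
                         filter_mode = c("all_pass", "all_fail_removed"),
                         size_bounds = c(10, Inf), train_frac = 0.6,
                         seed = 1, sota = sota_params(),
                         system = default_fuzzy_system(),
                         classifiers = c("glm", "svm", "cart", "rf"),
                         grid_n = 1001, out_dir = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  filter_mode <- match.arg(filter_mode)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (!all(c("svm", "cart", "rf") %in% classifiers)) {
    .stopf("fusion requires svm, cart and rf among the classifiers")
  }

  filt <- scan_boundaries(dataset, labels, n_bins = n_bins, n_steps = n_steps,
                          mode = filter_mode)
  kept <- subset_genes(dataset, filt$kept_mask)

  tree <- grow_levels(kept, max_level, sota)
  selection <- select_per_level(tree, kept, labels, size_bounds)
  sel_genes <- attr(selection, "genes")

  split <- stratified_split(labels, train_frac, seed = seed)
  tr_idx <- match(split$train, kept$sample_ids)
  te_idx <- match(split$test, kept$sample_ids)
  y_tr <- as.integer(labels[split$train])
  y_te <- as.integer(labels[split$test])

  metric_rows <- list()
  fusion_rows <- list()
  fusion_samples <- list()
  for (L in which(selection$selectable)) {
    gidx <- sel_genes[[L]]
    x_tr <- kept$values[tr_idx, gidx, drop = FALSE]
    x_te <- kept$values[te_idx, gidx, drop = FALSE]
    models <- list()
    for (kind in classifiers) {
      model <- train_classifier(kind, x_tr, y_tr, seed = seed + L)
      models[[kind]] <- model
      pred <- predict(model, x_te)
      met <- classifier_metrics(confusion(y_te, pred))
      auc <- roc_auc(y_te, px_score(model, x_te))$auc
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        level = L, classifier = kind, n_genes = length(gidx),
        AC = met[["AC"]], PR = met[["PR"]], RC = met[["RC"]], F = met[["F"]],
        MCC = met[["MCC"]], AUC = auc)
    }
    fused <- fuse_and_score(models[c("svm", "cart", "rf")], x_te, y_te,
                            system = system, grid_n = grid_n)
    fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
      level = L, n_genes = length(gidx), AC = fused$metrics[["AC"]],
      PR = fused$metrics[["PR"]], RC = fused$metrics[["RC"]],
      F = fused$metrics[["F"]], MCC = fused$metrics[["MCC"]],
      AUC = fused$auc)
    ps <- fused$per_sample
    ps$sample_id <- split$test
    ps$level <- L
    fusion_samples[[length(fusion_samples) + 1L]] <- ps
  }
  metrics <- do.call(rbind, metric_rows)
  fusion <- do.call(rbind, fusion_rows)

  chosen_level <- NA_integer_
  chosen_genes <- character(0)
  if (!is.null(fusion) && nrow(fusion)) {
    chosen_level <- fusion$level[which.max(fusion$F)]
    chosen_genes <- kept$gene_ids[sel_genes[[chosen_level]]]
  }

  report <- structure(
    list(filter = list(steps = filt$steps, best_step = filt$best_step,
                       boundaries_at_best = filt$boundaries_at_best,
                       genes_kept = sum(filt$kept_mask),
                       kept_gene_ids = kept$gene_ids),
         selection = as.data.frame(selection),
         metrics = metrics,
         fusion = fusion,
         chosen_level = chosen_level,
         chosen_genes = chosen_genes,
         split = split,
         seed = seed,
         config = list(max_level = max_level, n_bins = n_bins,
                       n_steps = n_steps, filter_mode = filter_mode,
                       size_bounds = size_bounds, train_frac = train_frac,
                       grid_n = grid_n, classifiers = classifiers)),
    class = "pipeline_report"
  )
  report$tree <- tree
  report$fusion_samples <- if (length(fusion_samples)) {
    do.call(rbind, fusion_samples)
  } else {
    NULL
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline_report: filter kept %d genes (step %d); levels 1..%d; chosen level %s (%d genes)\n",
    x$filter$genes_kept, x$filter$best_step, x$config$max_level,
    ifelse(is.na(x$chosen_level), "none", x$chosen_level),
    length(x$chosen_genes)))
  invisible(x)
}

#' Persist the pipeline report and per-stage tables
#'
#' Writes `filter_steps.csv`, `level_selection.csv`, `classifier_metrics.csv`,
#' `fusion_metrics.csv`, `fusion_samples.csv`, `sota_tree.json`,
#' `kept_genes.txt`, `chosen_genes.txt` and `report.json` into `out_dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$filter$steps, "filter_steps.csv")
  wcsv(report$selection, "level_selection.csv")
  if (!is.null(report$metrics)) wcsv(report$metrics, "classifier_metrics.csv")
  if (!is.null(report$fusion)) wcsv(report$fusion, "fusion_metrics.csv")
  if (!is.null(report$fusion_samples)) {
    wcsv(report$fusion_samples, "fusion_samples.csv")
  }
  tree_obj <- lapply(report$tree$levels, function(l) {
    stats::setNames(
      lapply(l$clusters, function(idx) report$tree$gene_ids[idx]),
      paste0("cluster", seq_along(l$clusters)))
  })
  names(tree_obj) <- paste0("level", seq_along(tree_obj))
  jsonlite::write_json(tree_obj, file.path(out_dir, "sota_tree.json"))
  writeLines(report$filter$kept_gene_ids, file.path(out_dir, "kept_genes.txt"))
  writeLines(report$chosen_genes, file.path(out_dir, "chosen_genes.txt"))
  summary_obj <- list(
    seed = report$seed,
    config = report$config,
    filter = list(best_step = report$filter$best_step,
                  boundaries_at_best = as.list(report$filter$boundaries_at_best),
                  genes_kept = report$filter$genes_kept),
    chosen_level = report$chosen_level,
    chosen_genes = report$chosen_genes,
    selection = report$selection,
    metrics = report$metrics,
    fusion = report$fusion
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Run the pipeline from files
#'
#' Thin file-based front-end over [run_pipeline()]: reads the expression
#' table and labels, runs the pipeline and (optionally) persists the report.
#'
#' @param expr_path Expression table path.
#' @param labels_path Labels CSV path (`sample_id,class`).
#' @param orientation On-disk orientation of the expression table.
#' @param out_dir Optional output directory.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return A `pipeline_report`.
#' @export
run_pipeline_files <- function(expr_path, labels_path,
                               orientation = c("genes_in_rows",
                                               "samples_in_rows"),
                               out_dir = NULL, ...) {
  orientation <- match.arg(orientation)
  dataset <- read_expression_table(expr_path, orientation)
  labels <- read_labels(labels_path, dataset)
  run_pipeline(dataset, labels, out_dir = out_dir, ...)
}

#' Reference classifier benchmark table
#'
#' Published per-level test metrics (AC, PR, RC, F, MCC) of the GLM, SVM,
#' CART and RF classifiers on the GSE19188 lung-cancer benchmark
#' (hierarchical levels 5-10), bundled as plain CSV. Used by the consistency
#' checks that re-derive the F-measure from the printed precision/recall
#' pairs.
#'
#' @return Data frame with columns `classifier`, `level`, `AC`, `PR`, `RC`,
#'   `F`, `MCC`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv", package = "profilex",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
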