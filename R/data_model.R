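# Core dataset containers and delimited-text I/O.
#
# The internal orientation is fixed as samples x genes: `values[i, j]` is the
# (log-scale) expression of gene j in sample i. On disk, expression tables in
# the wild are usually gene-major (one row per gene, as in GEO series-matrix
# exports), so the readers take an explicit orientation flag instead of
# guessing.

#' Construct an expression dataset
#'
#' Bundles a numeric samples x genes expression matrix with its sample and
#' gene identifiers and validates the container invariants: no missing or
#' non-finite entries, unique identifiers, at least 2 samples and 2 genes.
#' (Individual analyses impose stronger requirements, e.g. correlation
#' distance needs at least 3 features and the classifier stages at least 2
#' samples per class.)
#'
#' @param values Numeric matrix, rows = samples, columns = genes.
#' @param sample_ids Character vector of unique sample identifiers (length
#'   `nrow(values)`).
#' @param gene_ids Character vector of unique gene identifiers (length
#'   `ncol(values)`).
#' @return An object of class `expression_dataset` with elements `values`,
#'   `sample_ids`, `gene_ids`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4)
#' ds <- expression_dataset(m, paste0("s", 1:4), paste0("g", 1:5))
#' dim(ds$values)
#' @export
expression_dataset <- function(values, sample_ids, gene_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(sample_ids)) {
    .stopf("number of rows (%d) != number of sample ids (%d)",
           nrow(values), length(sample_ids))
  }
  if (ncol(values) != length(gene_ids)) {
    .stopf("number of columns (%d) != number of gene ids (%d)",
           ncol(values), length(gene_ids))
  }
  if (anyDuplicated(sample_ids)) {
    .stopf("duplicate sample ids: %s",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    .stopf("duplicate gene ids: %s",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    .stopf("non-finite expression value at sample '%s', gene '%s'",
           sample_ids[bad[1]], gene_ids[bad[2]])
  }
  if (nrow(values) < 2) .stopf("need at least 2 samples, got %d", nrow(values))
  if (ncol(values) < 2) .stopf("need at least 2 genes, got %d", ncol(values))
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, sample_ids = sample_ids, gene_ids = gene_ids),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes\n",
              length(x$sample_ids), length(x$gene_ids)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table (delimiter auto-detected) with one header
#' row of identifiers and one leading identifier column, and returns a
#' samples x genes [expression_dataset()] regardless of the on-disk
#' orientation.
#'
#' @param path Path to the delimited file.
#' @param orientation `"genes_in_rows"` (the common gene-major layout, default)
#'   or `"samples_in_rows"`.
#' @return An [expression_dataset()].
#' @examples
#' ds <- expression_dataset(matrix(1:20 / 2, 4, 5),
#'                          paste0("s", 1:4), paste0("g", 1:5))
#' f <- tempfile(fileext = ".tsv")
#' write_expression_table(ds, f, orientation = "genes_in_rows")
#' ds2 <- read_expression_table(f, orientation = "genes_in_rows")
#' all.equal(ds$values, ds2$values)
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) .stopf("expression table '%s' has no data columns", path)
  row_ids <- as.character(dt[[1]])
  col_ids <- colnames(dt)[-1]
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      .stopf("non-numeric value in column '%s', row '%s' of %s",
             col_ids[j], row_ids[bad %||% 1], path)
    }
  }
  mat <- as.matrix(body)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    .stopf("missing value at row '%s', column '%s' of %s",
           row_ids[bad[1]], col_ids[bad[2]], path)
  }
  if (orientation == "genes_in_rows") {
    expression_dataset(t(mat), sample_ids = col_ids, gene_ids = row_ids)
  } else {
    expression_dataset(mat, sample_ids = row_ids, gene_ids = col_ids)
  }
}

#' Write an expression dataset to a delimited file
#'
#' Values are written with 6 significant digits, tab-separated, UTF-8.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @param orientation On-disk layout, `"genes_in_rows"` (default) or
#'   `"samples_in_rows"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (orientation == "genes_in_rows") {
    mat <- t(dataset$values)
    out <- data.frame(gene_id = dataset$gene_ids,
                      signif(mat, 6), check.names = FALSE)
    colnames(out) <- c("gene_id", dataset$sample_ids)
  } else {
    out <- data.frame(sample_id = dataset$sample_ids,
                      signif(dataset$values, 6), check.names = FALSE)
    colnames(out) <- c("sample_id", dataset$gene_ids)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read binary sample labels
#'
#' Reads a two-column delimited file `sample_id,class` and validates it
#' against a dataset: every dataset sample must be labelled and both classes
#' must be present. Classes may be given either as 0/1 or as names from
#' `class_levels` (first name maps to 0, second to 1).
#'
#' @param path Path to the labels file.
#' @param dataset The [expression_dataset()] the labels refer to.
#' @param class_levels Two-element character vector naming the class alphabet;
#'   default `c("healthy", "tumor")` maps healthy to 0 and tumor to 1.
#' @return Named integer vector (0 = first level, 1 = second level), names =
#'   `dataset$sample_ids` in dataset order, of class `sample_labels`.
#' @export
read_labels <- function(path, dataset, class_levels = c("healthy", "tumor")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(class_levels) != 2) .stopf("class_levels must have length 2")
  if (!file.exists(path)) .stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2) .stopf("labels file '%s' needs columns sample_id,class", path)
  ids <- as.character(dt[[1]])
  cls <- as.character(dt[[2]])
  if (anyDuplicated(ids)) {
    .stopf("duplicate sample ids in labels file: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  unknown <- setdiff(ids, dataset$sample_ids)
  if (length(unknown)) {
    .stopf("labels refer to unknown sample ids: %s",
           paste(unknown, collapse = ", "))
  }
  missing <- setdiff(dataset$sample_ids, ids)
  if (length(missing)) {
    .stopf("labels missing for samples: %s", paste(missing, collapse = ", "))
  }
  lab <- rep(NA_integer_, length(cls))
  if (all(cls %in% c("0", "1"))) {
    lab <- as.integer(cls)
  } else {
    lab[cls == class_levels[1]] <- 0L
    lab[cls == class_levels[2]] <- 1L
    if (anyNA(lab)) {
      .stopf("unknown class value(s): %s (expected %s)",
             paste(unique(cls[is.na(lab)]), collapse = ", "),
             paste(class_levels, collapse = "/"))
    }
  }
  names(lab) <- ids
  lab <- lab[dataset$sample_ids]
  sample_labels(lab)
}

#' Construct sample labels
#'
#' @param labels Named integer vector of 0/1 class codes (0 = healthy,
#'   1 = tumor), one per sample.
#' @return Validated `sample_labels` object.
#' @export
sample_labels <- function(labels) {
  if (is.null(names(labels))) .stopf("labels must be named by sample id")
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    .stopf("labels must be 0 (healthy) or 1 (tumor)")
  }
  if (length(unique(labels)) < 2) {
    .stopf("both classes required: labels contain only class %d", labels[1])
  }
  structure(labels, class = c("sample_labels", "integer"))
}

#' @export
print.sample_labels <- function(x, ...) {
  cat(sprintf("sample_labels: %d samples (%d healthy, %d tumor)\n",
              length(x), sum(x == 0), sum(x == 1)))
  invisible(x)
}

#' Write a gene subset of a dataset
#'
#' Writes the columns selected by a logical gene mask as a gene-major TSV;
#' reading the file back reproduces the submatrix (to 6 significant digits).
#'
#' @param dataset An [expression_dataset()].
#' @param gene_mask Logical vector of length `ncol(dataset$values)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_subset <- function(dataset, gene_mask, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  gene_mask <- as.logical(gene_mask)
  if (length(gene_mask) != length(dataset$gene_ids)) {
    .stopf("gene_mask length (%d) != number of genes (%d)",
           length(gene_mask), length(dataset$gene_ids))
  }
  if (!any(gene_mask)) .stopf("gene_mask selects no genes")
  kept <- dataset$values[, gene_mask, drop = FALSE]
  sub <- structure(
    list(values = kept,
         sample_ids = dataset$sample_ids,
         gene_ids = dataset$gene_ids[gene_mask]),
    class = "expression_dataset"
  )
  write_expression_table(sub, path, orientation = "genes_in_rows")
}

#' Subset a dataset by gene mask or indices
#'
#' @param dataset An [expression_dataset()].
#' @param genes Logical mask of length m, or integer/character gene indices.
#' @return A new [expression_dataset()] with the selected genes.
#' @export
subset_genes <- function(dataset, genes) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.logical(genes)) {
    if (length(genes) != length(dataset$gene_ids)) {
      .stopf("logical gene mask has wrong length")
    }
    idx <- which(genes)
  } else if (is.character(genes)) {
    idx <- match(genes, dataset$gene_ids)
    if (anyNA(idx)) {
      .stopf("unknown gene ids: %s", paste(genes[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(genes)
  }
  expression_dataset(dataset$values[, idx, drop = FALSE],
                     dataset$sample_ids, dataset$gene_ids[idx])
}
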