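# Composite cluster-validity criterion under correlation distance.
#
# The criterion multiplies the WB-index with the reciprocal Calinski-Harabasz
# ratio:
#
#   QC_int = K (K - 1) QC_W^2 / ((N - K) QC_B^2)
#
# where QC_W is the mean correlation distance of objects to their own cluster
# centre and QC_B the mean pairwise correlation distance between the K
# cluster centres. Smaller is better: a low value means compact clusters with
# well-separated centres. Throughout the pipeline the "objects" are either
# gene profiles (when clustering genes) or samples restricted to a gene
# subset (when judging how well a gene set separates the two known classes).

#' Correlation distance between two vectors
#'
#' `d(x, y) = 1 - r(x, y)` with Pearson `r`, so perfectly correlated vectors
#' are at distance 0 and anti-correlated vectors at distance 2. A constant
#' vector has undefined correlation; by convention its distance is 1
#' (neutral), with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Distance in `[0, 2]`.
#' @examples
#' correlation_distance(c(1, 2, 3), c(3, 2, 1)) # 2
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) .stopf("vectors differ in length")
  if (length(x) < 3) .stopf("correlation distance needs length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .warnf("constant vector: correlation undefined, using distance 1")
    return(1)
  }
  .cor_dist(x, y)
}

# Partition helper: validates an assignment vector into K non-empty clusters.
.as_partition <- function(assignment) {
  assignment <- as.integer(assignment)
  if (anyNA(assignment)) .stopf("partition assignment contains NA")
  ids <- sort(unique(assignment))
  sizes <- tabulate(match(assignment, ids))
  list(assignment = assignment, ids = ids, K = length(ids), N = length(assignment),
       sizes = sizes)
}

#' Cluster centres
#'
#' Componentwise arithmetic means of the cluster members.
#'
#' @param x Numeric object x feature matrix.
#' @param assignment Integer cluster id per row of `x`.
#' @return Matrix with one row per cluster (in increasing cluster-id order).
#' @export
cluster_centers <- function(x, assignment) {
  x <- as.matrix(x)
  p <- .as_partition(assignment)
  if (p$N != nrow(x)) .stopf("assignment length != number of objects")
  centers <- matrix(0, p$K, ncol(x))
  for (k in seq_len(p$K)) {
    centers[k, ] <- colMeans(x[p$assignment == p$ids[k], , drop = FALSE])
  }
  rownames(centers) <- p$ids
  centers
}

#' Mean within-cluster distance QC_W
#'
#' Average correlation distance from every object to the centre of its own
#' cluster: `QC_W = (1/N) sum_s sum_i d(x_i^s, C_s)`.
#'
#' @param x Object x feature matrix.
#' @param assignment Integer cluster id per object.
#' @param centers Optional precomputed [cluster_centers()].
#' @return Non-negative scalar.
#' @export
qc_w <- function(x, assignment, centers = NULL) {
  x <- as.matrix(x)
  p <- .as_partition(assignment)
  if (is.null(centers)) centers <- cluster_centers(x, assignment)
  xc <- x - rowMeans(x)
  rx <- sqrt(rowSums(xc * xc))
  total <- 0
  for (k in seq_len(p$K)) {
    sel <- p$assignment == p$ids[k]
    total <- total + sum(.cor_dist_rows(xc[sel, , drop = FALSE], rx[sel],
                                        centers[k, ]))
  }
  total / p$N
}

#' Mean between-centre distance QC_B
#'
#' `QC_B = (2 / (K (K - 1))) sum_{i<j} d(C_i, C_j)`.
#'
#' @param centers Matrix of cluster centres, one row per cluster, K >= 2.
#' @return Non-negative scalar.
#' @export
qc_b <- function(centers) {
  centers <- as.matrix(centers)
  K <- nrow(centers)
  if (K < 2) .stopf("qc_b needs at least 2 cluster centres")
  total <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      total <- total + .cor_dist(centers[i, ], centers[j, ])
    }
  }
  2 * total / (K * (K - 1))
}

#' Composite clustering-quality criterion QC_int
#'
#' Evaluates `QC_int = K (K - 1) QC_W^2 / ((N - K) QC_B^2)` for a partition
#' of the rows of `x` under correlation distance. The minimum over candidate
#' partitions marks the best clustering.
#'
#' @param x Object x feature matrix (features of length >= 3).
#' @param assignment Integer cluster id per row; K >= 2 clusters, N > K.
#' @return A `qc_breakdown` list: `qc_w`, `qc_b`, `qc_int`, `centers`, `K`,
#'   `N`. `qc_int` is `+Inf` (with a warning) when the centres coincide
#'   (`QC_B = 0`).
#' @export
qc_int <- function(x, assignment) {
  x <- as.matrix(x)
  if (ncol(x) < 3) .stopf("qc_int needs >= 3 features for correlation distance")
  p <- .as_partition(assignment)
  if (p$K < 2) .stopf("qc_int needs K >= 2 clusters")
  if (p$N <= p$K) .stopf("qc_int needs more objects than clusters (N > K)")
  centers <- cluster_centers(x, assignment)
  w <- qc_w(x, assignment, centers)
  b <- qc_b(centers)
  val <- if (b <= 0) {
    .warnf("QC_B = 0 (coincident centres): QC_int is +Inf")
    Inf
  } else {
    p$K * (p$K - 1) * w^2 / ((p$N - p$K) * b^2)
  }
  structure(list(qc_w = w, qc_b = b, qc_int = val, centers = centers,
                 K = p$K, N = p$N),
            class = "qc_breakdown")
}

#' @export
print.qc_breakdown <- function(x, ...) {
  cat(sprintf("qc_breakdown: K=%d N=%d QC_W=%.6g QC_B=%.6g QC_int=%.6g\n",
              x$K, x$N, x$qc_w, x$qc_b, x$qc_int))
  invisible(x)
}

#' Class-separation score of a gene subset
#'
#' Scores how well a gene subset separates the two known sample classes:
#' the samples (restricted to the subset's columns) are the objects, the
#' class labels the K = 2 partition, and the value is their [qc_int()].
#' Lower scores mean the classes form tighter, better-separated groups in
#' the subspace spanned by these genes.
#'
#' @param dataset An [expression_dataset()].
#' @param labels A [sample_labels()] covering the dataset.
#' @param gene_subset Logical mask, or integer/character indices, selecting
#'   at least 3 genes.
#' @return A `qc_breakdown` (see [qc_int()]).
#' @export
sample_space_score <- function(dataset, labels, gene_subset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  lab <- .match_labels(dataset, labels)
  if (is.logical(gene_subset)) {
    idx <- which(gene_subset)
  } else if (is.character(gene_subset)) {
    idx <- match(gene_subset, dataset$gene_ids)
    if (anyNA(idx)) .stopf("unknown gene ids in gene_subset")
  } else {
    idx <- as.integer(gene_subset)
  }
  if (length(idx) < 3) {
    .stopf("gene_subset must select >= 3 genes (got %d)", length(idx))
  }
  qc_int(dataset$values[, idx, drop = FALSE], lab + 1L)
}

# Align a sample_labels vector with a dataset, verifying coverage.
.match_labels <- function(dataset, labels) {
  if (is.null(names(labels))) .stopf("labels must be named by sample id")
  missing <- setdiff(dataset$sample_ids, names(labels))
  if (length(missing)) {
    .stopf("labels missing for samples: %s", paste(missing, collapse = ", "))
  }
  lab <- as.integer(labels[dataset$sample_ids])
  if (length(unique(lab)) < 2) .stopf("both classes required")
  names(lab) <- dataset$sample_ids
  lab
}
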