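# Level-wise binary SOTA clustering of gene expression profiles.
#
# The self-organizing tree algorithm splits a set of profiles into two
# clusters per division by training a pair of daughter cells (Kohonen-style
# prototype vectors) under correlation distance. Growing every leaf once per
# hierarchical level yields at most 2^L clusters at level L; the level-wise
# hierarchy is then mined by selecting, per level, the cluster whose genes
# best separate the known sample classes.
#
# The whole procedure is deterministic: daughters are initialised from the
# parent centroid with a fixed alternating +/- 1e-6 perturbation and profiles
# are presented in input order, so no RNG is involved.

#' SOTA training parameters
#'
#' @param lr_winner Learning rate of the winning cell (default 0.1).
#' @param lr_mother Learning rate reserved for the mother cell in deeper-tree
#'   SOTA variants; unused by the pure two-cell split but kept as a parameter
#'   (default 0.05).
#' @param lr_sister Learning rate of the sister cell (default 0.01).
#' @param max_epochs Maximum training epochs per split (default 100).
#' @param tol Relative-change convergence threshold on the total training
#'   error (default 1e-6).
#' @param min_split_size Leaves smaller than this are carried through levels
#'   unsplit (default 2).
#' @return A validated `sota_params` list.
#' @export
sota_params <- function(lr_winner = 0.1, lr_mother = 0.05, lr_sister = 0.01,
                        max_epochs = 100, tol = 1e-6, min_split_size = 2) {
  if (!(lr_winner > lr_mother && lr_mother > lr_sister && lr_sister > 0)) {
    .stopf("learning rates must satisfy lr_winner > lr_mother > lr_sister > 0")
  }
  if (lr_winner >= 1) .stopf("learning rates must be below 1")
  if (max_epochs < 1) .stopf("max_epochs must be >= 1")
  if (tol <= 0) .stopf("tol must be positive")
  if (min_split_size < 2) .stopf("min_split_size must be >= 2")
  structure(list(lr_winner = lr_winner, lr_mother = lr_mother,
                 lr_sister = lr_sister, max_epochs = max_epochs, tol = tol,
                 min_split_size = min_split_size),
            class = "sota_params")
}

#' Two-cell SOTA split
#'
#' Splits a set of profiles into two clusters. Two daughter cells start at
#' the parent centroid, perturbed by +/- 1e-6 on alternating coordinates.
#' Each epoch presents the profiles in input order: the cell closer in
#' correlation distance moves towards the profile with rate `lr_winner`, its
#' sister with rate `lr_sister`. Training stops when the relative change of
#' the total error `sum_i d(x_i, winner cell)` drops below `tol`, or after
#' `max_epochs`. The final assignment sends each profile to its nearest cell.
#'
#' @param profiles Numeric object x feature matrix (>= 2 rows, >= 3 columns).
#' @param params A [sota_params()] object.
#' @return List with `assignment` (integer 1/2 per profile), `prototypes`
#'   (2 x feature matrix), `epochs`, `error`, `error_trace` (total error at
#'   the end of each epoch), and `collapsed` (`TRUE` when every profile
#'   landed in one cell, e.g. for identical profiles).
#' @export
sota_two_cell <- function(profiles, params = sota_params()) {
  x <- as.matrix(profiles)
  if (nrow(x) < 2) .stopf("need at least 2 profiles to split")
  if (ncol(x) < 3) .stopf("profiles need >= 3 features for correlation distance")
  stopifnot(inherits(params, "sota_params"))
  nfeat <- ncol(x)
  centroid <- colMeans(x)
  eps <- 1e-6 * rep_len(c(1, -1), nfeat)
  c1 <- centroid + eps
  c2 <- centroid - eps

  xc <- x - rowMeans(x)
  rx <- sqrt(rowSums(xc * xc))
  total_error <- function() {
    d1 <- .cor_dist_rows(xc, rx, c1)
    d2 <- .cor_dist_rows(xc, rx, c2)
    sum(pmin(d1, d2))
  }

  prev <- Inf
  epochs <- 0L
  trace <- numeric(0)
  for (epoch in seq_len(params$max_epochs)) {
    for (i in seq_len(nrow(x))) {
      xi <- x[i, ]
      d1 <- .cor_dist(xi, c1)
      d2 <- .cor_dist(xi, c2)
      if (d1 <= d2) {
        c1 <- c1 + params$lr_winner * (xi - c1)
        c2 <- c2 + params$lr_sister * (xi - c2)
      } else {
        c2 <- c2 + params$lr_winner * (xi - c2)
        c1 <- c1 + params$lr_sister * (xi - c1)
      }
    }
    epochs <- epoch
    err <- total_error()
    trace <- c(trace, err)
    if (is.finite(prev)) {
      rel <- abs(prev - err) / max(prev, .Machine$double.eps)
      if (rel < params$tol) {
        prev <- err
        break
      }
    }
    prev <- err
  }

  d1 <- .cor_dist_rows(xc, rx, c1)
  d2 <- .cor_dist_rows(xc, rx, c2)
  assignment <- ifelse(d1 <= d2, 1L, 2L)
  collapsed <- length(unique(assignment)) < 2
  list(assignment = assignment,
       prototypes = rbind(c1, c2),
       epochs = epochs,
       error = prev,
       error_trace = trace,
       collapsed = collapsed)
}

#' Grow the SOTA hierarchy level by level
#'
#' Objects are the gene profiles (feature dimension = samples). At each level
#' every current leaf with at least `min_split_size` members is split with
#' [sota_two_cell()]; smaller leaves, and splits that collapse (one empty
#' daughter), carry through unchanged, so the cluster count at level L is at
#' most 2^L.
#'
#' @param dataset An [expression_dataset()].
#' @param max_level Deepest hierarchical level N >= 1.
#' @param params A [sota_params()] object.
#' @return A `sota_tree`: list with `levels` — one entry per level holding
#'   `assignment` (cluster id per gene), `clusters` (list of gene-index
#'   vectors) — plus `gene_ids`, `max_level` and `params`.
#' @export
grow_levels <- function(dataset, max_level, params = sota_params()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (max_level < 1) .stopf("max_level must be >= 1")
  x <- t(dataset$values) # genes x samples
  m <- nrow(x)
  leaves <- list(seq_len(m))
  levels <- vector("list", max_level)
  for (L in seq_len(max_level)) {
    nxt <- list()
    any_split <- FALSE
    for (leaf in leaves) {
      if (length(leaf) >= params$min_split_size) {
        sp <- sota_two_cell(x[leaf, , drop = FALSE], params)
        if (!sp$collapsed) {
          nxt[[length(nxt) + 1L]] <- leaf[sp$assignment == 1L]
          nxt[[length(nxt) + 1L]] <- leaf[sp$assignment == 2L]
          any_split <- TRUE
          next
        }
      }
      nxt[[length(nxt) + 1L]] <- leaf
    }
    leaves <- nxt
    assignment <- integer(m)
    for (k in seq_along(leaves)) assignment[leaves[[k]]] <- k
    levels[[L]] <- list(assignment = assignment, clusters = leaves)
    if (!any_split && L < max_level) {
      .warnf("no leaf split at level %d; deeper levels repeat this partition", L)
      for (L2 in (L + 1):max_level) levels[[L2]] <- levels[[L]]
      break
    }
  }
  structure(list(levels = levels, gene_ids = dataset$gene_ids,
                 max_level = max_level, params = params),
            class = "sota_tree")
}

#' @export
print.sota_tree <- function(x, ...) {
  counts <- vapply(x$levels, function(l) length(l$clusters), integer(1))
  cat(sprintf("sota_tree: %d genes, levels 1..%d with cluster counts %s\n",
              length(x$gene_ids), x$max_level, paste(counts, collapse = ", ")))
  invisible(x)
}

#' Select the best cluster at every hierarchical level
#'
#' Scores each cluster of each level with [sample_space_score()] (restricted
#' to the cluster's genes) and selects, per level, the cluster of minimal
#' score among those whose gene count lies within `size_bounds`. Levels with
#' no eligible cluster are marked unselectable.
#'
#' @param tree A [grow_levels()] result.
#' @param dataset The [expression_dataset()] the tree was grown on.
#' @param labels A [sample_labels()] covering the dataset.
#' @param size_bounds Length-2 numeric `(min_genes, max_genes)`; default
#'   `c(10, Inf)`. Clusters also need >= 3 genes for the correlation-based
#'   score.
#' @return A `level_selection` data.frame: `level`, `cluster`, `n_genes`,
#'   `qc_int`, `selectable`, with the selected gene-index vectors in
#'   `attr(, "genes")`.
#' @export
select_per_level <- function(tree, dataset, labels, size_bounds = c(10, Inf)) {
  stopifnot(inherits(tree, "sota_tree"), inherits(dataset, "expression_dataset"))
  if (!identical(tree$gene_ids, dataset$gene_ids)) {
    .stopf("tree and dataset gene ids differ")
  }
  lo <- max(size_bounds[1], 3)
  hi <- size_bounds[2]
  out <- data.frame(level = seq_len(tree$max_level), cluster = NA_integer_,
                    n_genes = NA_integer_, qc_int = NA_real_,
                    selectable = FALSE)
  genes <- vector("list", tree$max_level)
  for (L in seq_len(tree$max_level)) {
    cl <- tree$levels[[L]]$clusters
    best_val <- Inf
    best_k <- NA_integer_
    for (k in seq_along(cl)) {
      sz <- length(cl[[k]])
      if (sz < lo || sz > hi) next
      val <- sample_space_score(dataset, labels, cl[[k]])$qc_int
      if (val < best_val) {
        best_val <- val
        best_k <- k
      }
    }
    if (!is.na(best_k)) {
      out$cluster[L] <- best_k
      out$n_genes[L] <- length(cl[[best_k]])
      out$qc_int[L] <- best_val
      out$selectable[L] <- TRUE
      genes[[L]] <- cl[[best_k]]
    }
  }
  attr(out, "genes") <- genes
  class(out) <- c("level_selection", "data.frame")
  out
}
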