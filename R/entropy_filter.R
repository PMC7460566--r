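# Non-informative gene removal by a stepwise boundary scan.
#
# Per-gene statistics: sample variance, mean absolute expression and a
# James-Stein shrinkage estimate of the Shannon entropy of the discretised
# profile. Genes with low variance and low absolute expression carry no
# signal; genes whose values vary chaotically across samples (high entropy)
# blur the class structure. Three boundaries are advanced together over a
# shared step grid (variance and mean upward, entropy downward) and the
# class-separation criterion QC_int is evaluated on the surviving genes at
# each step; the boundaries at the first QC minimum define the kept set.

#' James-Stein shrinkage Shannon entropy of a profile
#'
#' Discretises the profile into `n_bins` equal-width bins over its own range,
#' shrinks the bin frequencies towards the uniform distribution with
#' data-driven intensity
#' `lambda = (1 - sum(theta^2)) / ((n - 1) * sum((1/B - theta)^2))`
#' (clipped to `[0, 1]`; `lambda = 1` when the denominator vanishes), and
#' returns the Shannon entropy of the shrunk frequencies in nats. A constant
#' profile returns 0 by convention.
#'
#' @param profile Numeric vector of length >= 2.
#' @param n_bins Number of bins B >= 2 (default 10).
#' @return Entropy in nats, in `[0, log(n_bins)]`.
#' @examples
#' shannon_entropy_js(c(1, 1, 1, 2), n_bins = 2) # log(2): full shrinkage
#' @export
shannon_entropy_js <- function(profile, n_bins = 10) {
  if (length(profile) < 2) .stopf("entropy needs at least 2 values")
  if (n_bins < 2) .stopf("n_bins must be >= 2")
  n <- length(profile)
  rng <- range(profile)
  if (rng[1] == rng[2]) return(0)
  # equal-width binning over the profile's own range; max value -> last bin
  idx <- pmin(n_bins, floor((profile - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  theta_hat <- counts / n
  num <- 1 - sum(theta_hat^2)
  den <- (n - 1) * sum((1 / n_bins - theta_hat)^2)
  lambda <- if (den == 0) 1 else min(max(num / den, 0), 1)
  theta <- lambda / n_bins + (1 - lambda) * theta_hat
  pos <- theta > 0
  -sum(theta[pos] * log(theta[pos]))
}

#' Per-gene filtering statistics
#'
#' Computes, for every gene profile (column): the unbiased sample variance,
#' the mean of absolute expression values, and the shrinkage Shannon entropy
#' ([shannon_entropy_js()]).
#'
#' @param dataset An [expression_dataset()] with n >= 2 samples.
#' @param n_bins Bin count for the entropy estimate (default 10).
#' @return A `gene_stats` object: data.frame-like list with `gene_id`,
#'   `variance`, `mean_abs`, `entropy` (all length m) and the `n_bins` used.
#' @export
gene_statistics <- function(dataset, n_bins = 10) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  if (nrow(v) < 2) .stopf("variance undefined for fewer than 2 samples")
  variance <- apply(v, 2, stats::var)
  mean_abs <- colMeans(abs(v))
  entropy <- apply(v, 2, shannon_entropy_js, n_bins = n_bins)
  structure(
    list(gene_id = dataset$gene_ids, variance = unname(variance),
         mean_abs = unname(mean_abs), entropy = unname(entropy),
         n_bins = n_bins),
    class = "gene_stats"
  )
}

#' @export
print.gene_stats <- function(x, ...) {
  cat(sprintf(
    "gene_stats: %d genes | var [%.3g, %.3g] | |e| [%.3g, %.3g] | H [%.3g, %.3g] nats\n",
    length(x$gene_id), min(x$variance), max(x$variance),
    min(x$mean_abs), max(x$mean_abs), min(x$entropy), max(x$entropy)))
  invisible(x)
}

#' Build the shared boundary grid
#'
#' Linear grids of `n_steps` boundary triples spanning the observed range of
#' each statistic: variance and mean absolute value ascend from their minima
#' to their maxima while entropy descends from its maximum to its minimum,
#' all three sharing one step index.
#'
#' @param stats A [gene_statistics()] result.
#' @param n_steps Number of scan steps (default 50).
#' @return A `boundary_grid`: list with `n_steps`, `v_grid`, `m_grid`,
#'   `h_grid`.
#' @export
build_grid <- function(stats, n_steps = 50) {
  stopifnot(inherits(stats, "gene_stats"))
  if (n_steps < 1) .stopf("n_steps must be >= 1")
  mk <- function(lo, hi) {
    if (lo == hi) .warnf("degenerate statistic range [%g, %g]: constant grid", lo, hi)
    seq(lo, hi, length.out = n_steps)
  }
  boundary_grid(v_grid = mk(min(stats$variance), max(stats$variance)),
                m_grid = mk(min(stats$mean_abs), max(stats$mean_abs)),
                h_grid = mk(max(stats$entropy), min(stats$entropy)))
}

#' Construct a boundary grid from explicit boundary vectors
#'
#' @param v_grid Non-decreasing variance boundaries.
#' @param m_grid Non-decreasing mean-absolute boundaries.
#' @param h_grid Non-increasing entropy boundaries.
#' @return A `boundary_grid` object.
#' @export
boundary_grid <- function(v_grid, m_grid, h_grid) {
  n <- length(v_grid)
  if (length(m_grid) != n || length(h_grid) != n) {
    .stopf("all three grids must have the same length")
  }
  if (is.unsorted(v_grid)) .stopf("v_grid must be non-decreasing")
  if (is.unsorted(m_grid)) .stopf("m_grid must be non-decreasing")
  if (is.unsorted(rev(h_grid))) .stopf("h_grid must be non-increasing")
  structure(list(n_steps = n, v_grid = as.numeric(v_grid),
                 m_grid = as.numeric(m_grid), h_grid = as.numeric(h_grid)),
            class = "boundary_grid")
}

#' Apply one boundary triple to the gene statistics
#'
#' Under the default `"all_pass"` mode a gene is kept iff its variance and
#' mean absolute value strictly exceed their boundaries and its entropy is
#' strictly below the entropy boundary. The alternative `"all_fail_removed"`
#' mode removes a gene only when it fails all three criteria simultaneously
#' (keeps it if any single criterion passes); the two differ for genes
#' failing only some criteria.
#'
#' @param stats A [gene_statistics()] result.
#' @param v_b,m_b,h_b Finite boundary values for variance, mean absolute
#'   expression and entropy.
#' @param mode `"all_pass"` (default) or `"all_fail_removed"`.
#' @return Logical kept-mask of length m.
#' @export
apply_boundaries <- function(stats, v_b, m_b, h_b,
                             mode = c("all_pass", "all_fail_removed")) {
  stopifnot(inherits(stats, "gene_stats"))
  mode <- match.arg(mode)
  if (!all(is.finite(c(v_b, m_b, h_b)))) .stopf("boundaries must be finite")
  if (mode == "all_pass") {
    stats$variance > v_b & stats$mean_abs > m_b & stats$entropy < h_b
  } else {
    !(stats$variance <= v_b & stats$mean_abs <= m_b & stats$entropy >= h_b)
  }
}

#' Stepwise boundary scan
#'
#' Runs the full filtering scan: at every step of the grid the kept-gene mask
#' is formed with [apply_boundaries()] and the class-separation criterion
#' ([sample_space_score()]) of the surviving genes is evaluated on the known
#' two-class sample partition. Steps leaving fewer than 3 genes are
#' infeasible and scored `+Inf`. The best step is the first minimum of the
#' criterion.
#'
#' @param dataset An [expression_dataset()].
#' @param labels A [sample_labels()] with both classes present.
#' @param grid A `boundary_grid`, or `NULL` to build one with [build_grid()].
#' @param n_bins Entropy bin count (default 10).
#' @param n_steps Steps for the default grid (default 50).
#' @param mode Keep semantics, see [apply_boundaries()].
#' @return A `filter_result`: `steps` (data.frame `step, v_b, m_b, h_b,
#'   genes_kept, qc_int`), `best_step`, `boundaries_at_best`, `kept_mask`,
#'   `stats`, `mode`.
#' @export
scan_boundaries <- function(dataset, labels, grid = NULL, n_bins = 10,
                            n_steps = 50,
                            mode = c("all_pass", "all_fail_removed")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mode <- match.arg(mode)
  .match_labels(dataset, labels)
  stats <- gene_statistics(dataset, n_bins = n_bins)
  if (is.null(grid)) grid <- build_grid(stats, n_steps = n_steps)
  stopifnot(inherits(grid, "boundary_grid"))
  qc <- numeric(grid$n_steps)
  kept_n <- integer(grid$n_steps)
  for (s in seq_len(grid$n_steps)) {
    mask <- apply_boundaries(stats, grid$v_grid[s], grid$m_grid[s],
                             grid$h_grid[s], mode = mode)
    kept_n[s] <- sum(mask)
    qc[s] <- if (kept_n[s] < 3) {
      Inf
    } else {
      sample_space_score(dataset, labels, mask)$qc_int
    }
  }
  if (all(!is.finite(qc))) .stopf("all scan steps infeasible")
  best <- which.min(qc) # first minimum on ties
  kept_mask <- apply_boundaries(stats, grid$v_grid[best], grid$m_grid[best],
                                grid$h_grid[best], mode = mode)
  structure(
    list(
      steps = data.frame(step = seq_len(grid$n_steps), v_b = grid$v_grid,
                         m_b = grid$m_grid, h_b = grid$h_grid,
                         genes_kept = kept_n, qc_int = qc),
      best_step = best,
      boundaries_at_best = c(v_b = grid$v_grid[best], m_b = grid$m_grid[best],
                             h_b = grid$h_grid[best]),
      kept_mask = kept_mask,
      stats = stats,
      mode = mode
    ),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(
    "filter_result: best step %d/%d keeps %d/%d genes (QC_int = %.6g)\n",
    x$best_step, nrow(x$steps), sum(x$kept_mask), length(x$kept_mask),
    x$steps$qc_int[x$best_step]))
  invisible(x)
}
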