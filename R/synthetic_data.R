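# Seeded generators of two-class expression data with planted structure.
#
# Three gene regimes are planted, matching what the filtering and clustering
# stages are built to tell apart:
#   * informative blocks — correlated genes sharing a per-block latent
#     factor, mean-shifted between the classes (alternating up/down per
#     block);
#   * chaotic noise genes — uniformly distributed, class-independent, high
#     Shannon entropy;
#   * low genes — low mean, low variance, carrying nothing.

#' Synthetic dataset configuration
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 50 samples per class, 4 informative blocks of 25 genes, 50 chaotic
#' noise genes, 50 low-expression genes, class effect 2 log-expression
#' units, within-block latent loading 0.9 and residual noise SD 0.5 around a
#' base mean of 7 (a typical log2 microarray intensity).
#'
#' @param n_samples_per_class Samples per class.
#' @param n_blocks Number of informative gene blocks.
#' @param genes_per_block Genes per block.
#' @param n_noise_genes Chaotic high-entropy genes.
#' @param n_low_genes Low-expression/low-variance genes.
#' @param effect Between-class mean shift delta (log-expression units).
#' @param within_block_rho Latent-factor loading in `[0, 1]`.
#' @param noise_sd Residual noise standard deviation.
#' @param base_mean Baseline log-expression level.
#' @param seed Integer seed fixing the whole output.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_samples_per_class = 50, n_blocks = 4,
                         genes_per_block = 25, n_noise_genes = 50,
                         n_low_genes = 50, effect = 2,
                         within_block_rho = 0.9, noise_sd = 0.5,
                         base_mean = 7, seed = 1) {
  counts <- c(n_samples_per_class, n_blocks, genes_per_block, n_noise_genes,
              n_low_genes)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (effect < 0) .stopf("effect must be >= 0")
  if (within_block_rho < 0 || within_block_rho > 1) {
    .stopf("within_block_rho must lie in [0, 1]")
  }
  total_genes <- n_blocks * genes_per_block + n_noise_genes + n_low_genes
  if (total_genes == 0) .stopf("configuration yields zero genes")
  structure(list(n_samples_per_class = n_samples_per_class,
                 n_blocks = n_blocks, genes_per_block = genes_per_block,
                 n_noise_genes = n_noise_genes, n_low_genes = n_low_genes,
                 effect = effect, within_block_rho = within_block_rho,
                 noise_sd = noise_sd, base_mean = base_mean,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic two-class expression dataset
#'
#' Block gene g of block k for sample s:
#' `e = base_mean + class_s * effect * sign_k + within_block_rho * z_{k,s} +
#' eps`, with `z_{k,s} ~ N(0, 1)` a per-block per-sample latent factor
#' (inducing within-block correlation), `eps ~ N(0, noise_sd^2)`, and
#' `sign_k` alternating +1/-1 so consecutive blocks are up-/down-regulated
#' in the tumor class. Noise genes are
#' `Uniform(base_mean - 3 effect, base_mean + 3 effect)` independent of
#' class; low genes are `N(0.1 base_mean, (0.1 noise_sd)^2)`.
#'
#' @param config A [synth_config()].
#' @return List with `dataset` ([expression_dataset()]), `labels`
#'   ([sample_labels()]) and `truth` (data.frame `gene_id, role, block` with
#'   role in block/noise/low).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- 2 * config$n_samples_per_class
  cls <- rep(c(0L, 1L), each = config$n_samples_per_class)
  sample_ids <- sprintf("s%03d", seq_len(n))
  gene_ids <- character(0)
  roles <- character(0)
  blocks <- integer(0)
  cols <- list()
  with_seed(config$seed, {
    for (k in seq_len(config$n_blocks)) {
      sign_k <- if (k %% 2 == 1) 1 else -1
      z <- stats::rnorm(n)
      for (g in seq_len(config$genes_per_block)) {
        e <- config$base_mean + cls * config$effect * sign_k +
          config$within_block_rho * z +
          stats::rnorm(n, sd = config$noise_sd)
        cols[[length(cols) + 1L]] <- e
        gene_ids <- c(gene_ids, sprintf("blk%d_g%02d", k, g))
        roles <- c(roles, "block")
        blocks <- c(blocks, k)
      }
    }
    if (config$n_noise_genes > 0) {
      half <- 3 * config$effect
      for (g in seq_len(config$n_noise_genes)) {
        cols[[length(cols) + 1L]] <-
          stats::runif(n, config$base_mean - half, config$base_mean + half)
        gene_ids <- c(gene_ids, sprintf("noise_g%02d", g))
        roles <- c(roles, "noise")
        blocks <- c(blocks, NA_integer_)
      }
    }
    if (config$n_low_genes > 0) {
      for (g in seq_len(config$n_low_genes)) {
        cols[[length(cols) + 1L]] <-
          stats::rnorm(n, 0.1 * config$base_mean, 0.1 * config$noise_sd)
        gene_ids <- c(gene_ids, sprintf("low_g%02d", g))
        roles <- c(roles, "low")
        blocks <- c(blocks, NA_integer_)
      }
    }
  })
  values <- do.call(cbind, cols)
  dataset <- expression_dataset(values, sample_ids, gene_ids)
  labels <- sample_labels(stats::setNames(cls, sample_ids))
  truth <- data.frame(gene_id = gene_ids, role = roles, block = blocks,
                      stringsAsFactors = FALSE)
  list(dataset = dataset, labels = labels, truth = truth)
}

#' Generate hierarchically separable gene blocks
#'
#' Builds a deterministic dataset of `2^n_levels` gene blocks whose
#' prototypes are signed sums of orthogonal Hadamard-basis "level bands"
#' with geometrically decaying weights: block b with binary code
#' `(s_1..s_L)` has prototype `sum_l s_l sqrt(2)^{L-l} h_l`, where the `h_l`
#' are zero-mean mutually orthogonal columns of a Hadamard matrix. Band l
#' carries as much energy as all deeper bands combined, so within any
#' subtree the two halves are anti-correlated along the first band on which
#' they disagree, with a worst-case correlation margin independent of
#' depth. Genes are laid out in bit-reversed block order, so any contiguous
#' presentation of a subtree's genes alternates between its two halves —
#' the recursively separable regime in which a level-wise binary clustering
#' resolves exactly one block per cluster at level `n_levels`. Genes within
#' a block are identical copies of the prototype.
#'
#' @param n_levels Depth L of the hierarchy; `2^L` blocks.
#' @param genes_per_block Copies of each prototype (default 2).
#' @param n_samples Feature dimension (samples); a power of 2 with at least
#'   `n_levels + 2` columns (default `max(16, next power of 2)`).
#' @return List with `dataset` ([expression_dataset()]; samples x genes) and
#'   `truth` (data.frame `gene_id, block`).
#' @export
generate_separable_blocks <- function(n_levels, genes_per_block = 2,
                                      n_samples = NULL) {
  if (n_levels < 1) .stopf("n_levels must be >= 1")
  if (genes_per_block < 1) .stopf("genes_per_block must be >= 1")
  if (is.null(n_samples)) {
    n_samples <- max(16, 2^ceiling(log2(n_levels + 2)))
  }
  if (bitwAnd(n_samples, n_samples - 1L) != 0 || n_samples < n_levels + 2) {
    .stopf("n_samples must be a power of 2 with at least n_levels + 2 columns")
  }
  # Sylvester construction: H_{2n} = [H H; H -H]; columns 2.. are zero-mean
  # and mutually orthogonal.
  h <- matrix(1, 1, 1)
  while (nrow(h) < n_samples) h <- rbind(cbind(h, h), cbind(h, -h))
  bands <- h[, 2:(n_levels + 1), drop = FALSE]
  n_blocks <- 2^n_levels
  weights <- sqrt(2)^(n_levels - seq_len(n_levels))
  codes <- matrix(0L, n_blocks, n_levels)
  for (l in seq_len(n_levels)) {
    codes[, l] <-
      (bitwAnd(seq_len(n_blocks) - 1L, bitwShiftL(1L, n_levels - l)) > 0) * 1L
  }
  signs <- 2 * codes - 1
  prototypes <- signs %*% (t(bands) * weights) # n_blocks x n_samples
  # bit-reversed block order; copies of a block in separate passes
  rev_order <- vapply(0:(n_blocks - 1), function(i) {
    r <- 0L
    for (b in seq_len(n_levels)) {
      r <- bitwOr(bitwShiftL(r, 1), bitwAnd(i, 1L))
      i <- bitwShiftR(i, 1)
    }
    r
  }, integer(1)) + 1L
  block_seq <- rep(rev_order, genes_per_block)
  values <- t(prototypes[block_seq, , drop = FALSE])
  gene_ids <- sprintf("g%05d_b%04d", seq_along(block_seq), block_seq)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  dataset <- expression_dataset(values, sample_ids, gene_ids)
  truth <- data.frame(gene_id = gene_ids, block = block_seq,
                      stringsAsFactors = FALSE)
  list(dataset = dataset, truth = truth)
}
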