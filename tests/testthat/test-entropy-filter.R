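test_that("shrinkage entropy matches hand evaluations", {
  expect_equal(shannon_entropy_js(rep(3.2, 6)), 0) # degenerate range
  # one value per bin -> exactly uniform frequencies -> log(B)
  expect_equal(shannon_entropy_js(seq(0.05, 0.95, by = 0.1), n_bins = 10),
               log(10), tolerance = 1e-12)
  # length-4 profile, bin counts (3, 1), B = 2:
  # lambda = (1 - 0.625) / (3 * 0.125) = 1 -> full shrinkage -> log(2)
  expect_equal(shannon_entropy_js(c(0, 0.1, 0.2, 1), n_bins = 2), log(2),
               tolerance = 1e-12)
  expect_error(shannon_entropy_js(1), "at least 2")
  expect_error(shannon_entropy_js(1:5, n_bins = 1), "n_bins")
})

test_that("per-gene statistics use the unbiased variance and are scale-covariant", {
  v <- rbind(c(5, 1, -1), c(5, -1, 1), c(5, 1, -1), c(5, -1, 1))
  ds <- expression_dataset(v, paste0("s", 1:4), paste0("g", 1:3))
  st <- gene_statistics(ds)
  expect_equal(st$variance[1], 0)
  expect_equal(st$mean_abs[1], 5)
  expect_equal(st$entropy[1], 0)
  expect_equal(st$variance[2], 4 / 3) # (1,-1,1,-1) with n-1 denominator
  expect_equal(st$mean_abs[2], 1)

  ds2 <- toy_dataset(8, 4, seed = 3)
  doubled <- expression_dataset(2 * ds2$values, ds2$sample_ids, ds2$gene_ids)
  s1 <- gene_statistics(ds2)
  s2 <- gene_statistics(doubled)
  expect_equal(s2$variance, 4 * s1$variance, tolerance = 1e-12)
  expect_equal(s2$mean_abs, 2 * s1$mean_abs, tolerance = 1e-12)
  # equal-width binning over each profile's own range: entropy is unchanged
  expect_equal(s2$entropy, s1$entropy, tolerance = 1e-12)
})

test_that("boundary grids are linear, monotone and span the observed ranges", {
  st <- structure(list(gene_id = paste0("g", 1:3),
                       variance = c(0, 0.4, 1), mean_abs = c(0, 0.9, 1),
                       entropy = c(0, 0.2, 1), n_bins = 10),
                  class = "gene_stats")
  g1 <- build_grid(st, n_steps = 1)
  expect_equal(c(g1$v_grid, g1$m_grid, g1$h_grid), c(0, 0, 1))
  g3 <- build_grid(st, n_steps = 3)
  expect_equal(g3$v_grid, c(0, 0.5, 1))
  expect_equal(g3$h_grid, c(1, 0.5, 0))

  set.seed(2)
  for (r in 1:5) {
    stats <- structure(list(gene_id = paste0("g", 1:20),
                            variance = runif(20, 0, 5),
                            mean_abs = runif(20, 1, 9),
                            entropy = runif(20, 0.1, 2.3), n_bins = 10),
                       class = "gene_stats")
    g <- build_grid(stats, n_steps = 12)
    expect_false(is.unsorted(g$v_grid))
    expect_false(is.unsorted(rev(g$h_grid)))
    expect_equal(range(g$v_grid), range(stats$variance))
    expect_equal(range(g$h_grid), range(stats$entropy))
    expect_equal(range(g$m_grid), range(stats$mean_abs))
  }
})

test_that("boundary application keeps and removes the right genes", {
  ds <- toy_dataset(6, 20, seed = 4)
  v <- ds$values
  v[, 1:5] <- 7 # five constant genes: variance 0
  ds <- expression_dataset(v, ds$sample_ids, ds$gene_ids)
  st <- gene_statistics(ds)

  all_kept <- apply_boundaries(st, min(st$variance) - 1, min(st$mean_abs) - 1,
                               max(st$entropy) + 1)
  expect_true(all(all_kept))
  none <- apply_boundaries(st, max(st$variance), max(st$mean_abs),
                           min(st$entropy))
  expect_false(any(none))
  # planted zero-variance genes are exactly the ones dropped
  kept <- apply_boundaries(st, 1e-6, min(st$mean_abs) - 1, max(st$entropy) + 1)
  expect_equal(which(!kept), 1:5)

  # remove-only-if-all-fail keeps genes that pass any single criterion
  kept2 <- apply_boundaries(st, 1e-6, min(st$mean_abs) - 1,
                            max(st$entropy) + 1, mode = "all_fail_removed")
  expect_true(all(kept2)) # constant genes still pass the entropy criterion
})

test_that("the scan matches a brute-force per-step evaluation", {
  sim <- generate_synthetic(synth_config(n_samples_per_class = 5, n_blocks = 2,
                                         genes_per_block = 5, n_noise_genes = 10,
                                         n_low_genes = 5, seed = 8))
  fr <- scan_boundaries(sim$dataset, sim$labels, n_steps = 8)
  st <- fr$stats
  for (s in seq_len(nrow(fr$steps))) {
    mask <- st$variance > fr$steps$v_b[s] & st$mean_abs > fr$steps$m_b[s] &
      st$entropy < fr$steps$h_b[s]
    expect_equal(fr$steps$genes_kept[s], sum(mask))
    if (sum(mask) >= 3) {
      want <- naive_qc(sim$dataset$values[, mask, drop = FALSE],
                       as.integer(sim$labels) + 1)$qc_int
      expect_equal(fr$steps$qc_int[s], want, tolerance = 1e-10)
    } else {
      expect_equal(fr$steps$qc_int[s], Inf)
    }
  }
  expect_equal(fr$best_step, which.min(fr$steps$qc_int))
  # boundaries only tighten along the scan
  expect_true(all(diff(fr$steps$genes_kept) <= 0))
})

test_that("a single-step keep-all grid scores the full dataset", {
  sim <- generate_synthetic(synth_config(n_samples_per_class = 6, n_blocks = 2,
                                         genes_per_block = 5, n_noise_genes = 5,
                                         n_low_genes = 0, seed = 14))
  st <- gene_statistics(sim$dataset)
  grid <- boundary_grid(min(st$variance) - 1, min(st$mean_abs) - 1,
                        max(st$entropy) + 1)
  fr <- scan_boundaries(sim$dataset, sim$labels, grid = grid)
  expect_equal(nrow(fr$steps), 1L)
  expect_true(all(fr$kept_mask))
  full <- sample_space_score(sim$dataset, sim$labels,
                             seq_along(sim$dataset$gene_ids))$qc_int
  expect_equal(fr$steps$qc_int[1], full, tolerance = 1e-12)
})

test_that("filtering is equivariant under gene permutation", {
  sim <- generate_synthetic(synth_config(n_samples_per_class = 8, n_blocks = 2,
                                         genes_per_block = 6, n_noise_genes = 8,
                                         n_low_genes = 4, seed = 5))
  fr <- scan_boundaries(sim$dataset, sim$labels, n_steps = 10)
  set.seed(1)
  perm <- sample(seq_along(sim$dataset$gene_ids))
  ds_p <- subset_genes(sim$dataset, perm)
  fr_p <- scan_boundaries(ds_p, sim$labels, n_steps = 10)
  expect_equal(fr_p$best_step, fr$best_step)
  expect_equal(fr_p$kept_mask, fr$kept_mask[perm])
})

test_that("the QC-minimal step preferentially removes chaotic noise genes", {
  noise_removed <- integer(0)
  for (seed in 1:5) {
    sim <- generate_synthetic(synth_config(n_blocks = 4, genes_per_block = 5,
                                           n_noise_genes = 20, n_low_genes = 0,
                                           seed = seed))
    fr <- scan_boundaries(sim$dataset, sim$labels)
    is_noise <- sim$truth$role == "noise"
    nr <- sum(!fr$kept_mask[is_noise])
    ir <- sum(!fr$kept_mask[!is_noise])
    noise_removed <- c(noise_removed, nr)
    # removal is always enriched for noise over informative genes
    expect_gte(nr / sum(is_noise), ir / sum(!is_noise))
  }
  expect_gte(median(noise_removed), 18)
})
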