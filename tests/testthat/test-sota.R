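test_that("two-cell split separates anti-correlated groups exactly", {
  up <- c(1, 2, 3, 4, 2)
  x <- rbind(up, 2 * up, up + 1, rev(up), 2 * rev(up), rev(up) + 1)
  sp <- sota_two_cell(x)
  expect_false(sp$collapsed)
  expect_equal(sp$assignment[1:3], rep(sp$assignment[1], 3))
  expect_equal(sp$assignment[4:6], rep(sp$assignment[4], 3))
  expect_false(sp$assignment[1] == sp$assignment[4])
})

test_that("two distinct profiles get one cell each; identical profiles collapse", {
  x <- rbind(c(1, 2, 3), c(3, 2, 1))
  sp <- sota_two_cell(x)
  expect_setequal(sp$assignment, c(1L, 2L))

  dup <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  sp2 <- sota_two_cell(dup)
  expect_true(sp2$collapsed)
  expect_equal(length(unique(sp2$assignment)), 1L)

  expect_error(sota_two_cell(x[1, , drop = FALSE]), "at least 2")
})

test_that("two-cell split agrees with the exhaustive 2-partition minimiser", {
  sim <- generate_synthetic(synth_config(
    n_samples_per_class = 8, n_blocks = 2, genes_per_block = 6,
    n_noise_genes = 0, n_low_genes = 0, within_block_rho = 0.9,
    noise_sd = 0.3, seed = 7))
  x <- t(sim$dataset$values) # 12 genes x 16 samples
  sp <- sota_two_cell(x)
  expect_false(sp$collapsed)
  # brute force over all 2^(n-1)-1 bipartitions
  n <- nrow(x)
  best <- NULL
  best_err <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    a <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(a)) < 2) next
    err <- naive_partition_error(x, a)
    if (err < best_err) {
      best_err <- err
      best <- a
    }
  }
  agree <- mean(sp$assignment == best)
  expect_true(agree == 1 || agree == 0) # identical up to label swap
  # and the split recovers the planted blocks
  expect_equal(length(unique(sp$assignment[sim$truth$block == 1])), 1L)
  expect_equal(length(unique(sp$assignment[sim$truth$block == 2])), 1L)
})

test_that("training error decreases across epochs up to tolerance slack", {
  sim <- generate_synthetic(synth_config(
    n_samples_per_class = 10, n_blocks = 2, genes_per_block = 10,
    n_noise_genes = 0, n_low_genes = 0, seed = 3))
  sp <- sota_two_cell(t(sim$dataset$values))
  tr <- sp$error_trace
  if (length(tr) > 1) {
    expect_true(all(diff(tr) <= 1e-6 * pmax(tr[-length(tr)], 1)))
  }
  expect_false(sp$collapsed)
})

test_that("planted two-block profiles are recovered across seeds", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(seed) {
    sim <- generate_synthetic(synth_config(
      n_samples_per_class = 10, n_blocks = 2, genes_per_block = 15,
      n_noise_genes = 0, n_low_genes = 0, within_block_rho = 0.9,
      noise_sd = 0.3, seed = seed))
    sp <- sota_two_cell(t(sim$dataset$values))
    mclust::adjustedRandIndex(sp$assignment, sim$truth$block)
  }, numeric(1))
  expect_true(all(aris == 1))
})

test_that("level growth yields nested partitions bounded by 2^L", {
  g <- generate_separable_blocks(n_levels = 2, genes_per_block = 5)
  tree <- grow_levels(g$dataset, 2)
  expect_equal(length(tree$levels[[1]]$clusters), 2L)
  expect_equal(length(tree$levels[[2]]$clusters), 4L)
  # level-2 clusters match the planted blocks exactly
  for (cl in tree$levels[[2]]$clusters) {
    expect_equal(length(unique(g$truth$block[cl])), 1L)
    expect_equal(length(cl), 5L)
  }
  m <- length(g$dataset$gene_ids)
  for (L in 1:2) {
    clusters <- tree$levels[[L]]$clusters
    expect_lte(length(clusters), 2^L)
    expect_setequal(unlist(clusters), seq_len(m)) # exhaustive
    expect_equal(sum(lengths(clusters)), m)       # disjoint
  }
  # nesting: every level-2 cluster lies inside exactly one level-1 cluster
  for (cl in tree$levels[[2]]$clusters) {
    parents <- vapply(tree$levels[[1]]$clusters,
                      function(p) all(cl %in% p), logical(1))
    expect_equal(sum(parents), 1L)
  }
})

test_that("per-level selection is the argmin over eligible clusters", {
  sim <- generate_synthetic(synth_config(
    n_samples_per_class = 10, n_blocks = 4, genes_per_block = 10,
    n_noise_genes = 0, n_low_genes = 0, seed = 17))
  tree <- grow_levels(sim$dataset, 2)
  sel <- select_per_level(tree, sim$dataset, sim$labels, size_bounds = c(3, Inf))
  for (L in 1:2) {
    clusters <- tree$levels[[L]]$clusters
    scores <- vapply(clusters, function(cl) {
      if (length(cl) < 3) return(Inf)
      sample_space_score(sim$dataset, sim$labels, cl)$qc_int
    }, numeric(1))
    expect_true(sel$selectable[L])
    expect_equal(sel$cluster[L], which.min(scores))
    expect_equal(sel$qc_int[L], min(scores), tolerance = 1e-12)
  }
  # determinism of the whole stage
  tree2 <- grow_levels(sim$dataset, 2)
  sel2 <- select_per_level(tree2, sim$dataset, sim$labels, size_bounds = c(3, Inf))
  expect_identical(as.data.frame(sel), as.data.frame(sel2))
})

test_that("selection honours size bounds and flags unselectable levels", {
  sim <- generate_synthetic(synth_config(
    n_samples_per_class = 8, n_blocks = 2, genes_per_block = 4,
    n_noise_genes = 0, n_low_genes = 0, seed = 23))
  tree <- grow_levels(sim$dataset, 1)
  sel <- select_per_level(tree, sim$dataset, sim$labels,
                          size_bounds = c(100, Inf))
  expect_false(any(sel$selectable))
})
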