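# Small in-code fixtures shared across test files.

toy_dataset <- function(n = 4, m = 5, seed = 42) {
  set.seed(seed)
  expression_dataset(matrix(rnorm(n * m, mean = 7), n, m),
                     sprintf("s%d", seq_len(n)), sprintf("g%d", seq_len(m)))
}

toy_labels <- function(dataset) {
  n <- length(dataset$sample_ids)
  sample_labels(stats::setNames(rep(c(0L, 1L), length.out = n)[order(seq_len(n) %% 2,
                                                                     decreasing = TRUE)],
                                dataset$sample_ids))
}

balanced_labels <- function(ids) {
  sample_labels(stats::setNames(rep(c(0L, 1L), each = length(ids) / 2), ids))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
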