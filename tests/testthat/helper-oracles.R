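# Independent naive re-implementations used as oracles. These deliberately
# avoid the package's internal code paths: plain loops and stats::cor.

naive_cor_dist <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
  1 - stats::cor(x, y)
}

naive_centers <- function(x, assignment) {
  ids <- sort(unique(assignment))
  out <- matrix(NA_real_, length(ids), ncol(x))
  for (k in seq_along(ids)) {
    rows <- which(assignment == ids[k])
    for (j in seq_len(ncol(x))) out[k, j] <- mean(x[rows, j])
  }
  out
}

naive_qc <- function(x, assignment) {
  ids <- sort(unique(assignment))
  K <- length(ids)
  N <- nrow(x)
  centers <- naive_centers(x, assignment)
  w <- 0
  for (i in seq_len(N)) {
    k <- match(assignment[i], ids)
    w <- w + naive_cor_dist(x[i, ], centers[k, ])
  }
  w <- w / N
  b <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) b <- b + naive_cor_dist(centers[i, ], centers[j, ])
  }
  b <- 2 * b / (K * (K - 1))
  list(qc_w = w, qc_b = b,
       qc_int = K * (K - 1) * w^2 / ((N - K) * b^2))
}

naive_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  safe <- function(num, den) if (den == 0) 0 else num / den
  pr <- safe(tp, tp + fp)
  rc <- safe(tp, tp + fn)
  f <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(AC = (tp + tn) / total, PR = pr, RC = rc, F = f, MCC = mcc)
}

# AUC by explicit pair counting with ties counted one half
naive_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# total within-cluster error of a 2-partition under correlation distance
naive_partition_error <- function(x, assignment) {
  centers <- naive_centers(x, assignment)
  ids <- sort(unique(assignment))
  tot <- 0
  for (i in seq_len(nrow(x))) {
    tot <- tot + naive_cor_dist(x[i, ], centers[match(assignment[i], ids), ])
  }
  tot
}
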