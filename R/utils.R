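# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed` and restores
#' the previous state afterwards, so library code never clobbers a user's RNG
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fast Pearson correlation distance between two numeric vectors.
# Constant vectors have undefined correlation; by convention their distance to
# anything is 1 (neutral), optionally with a warning at user-facing call sites.
.cor_dist <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  s2 <- sum(xm * xm) * sum(ym * ym)
  if (s2 <= 0) {
    return(1)
  }
  d <- 1 - sum(xm * ym) / sqrt(s2)
  # clamp tiny numerical excursions outside [0, 2]
  min(max(d, 0), 2)
}

# Correlation distance from each row of a (pre-centred) matrix to a vector.
# `xc` rows centred, `rx` their L2 norms (0 for constant rows).
.cor_dist_rows <- function(xc, rx, y) {
  ym <- y - mean(y)
  ry <- sqrt(sum(ym * ym))
  d <- rep(1, nrow(xc))
  if (ry > 0) {
    ok <- rx > 0
    if (any(ok)) {
      d[ok] <- 1 - as.vector(xc[ok, , drop = FALSE] %*% ym) / (rx[ok] * ry)
    }
  }
  pmin(pmax(d, 0), 2)
}

# round-half-up, used for per-class train counts
.round_half_up <- function(x) floor(x + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
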