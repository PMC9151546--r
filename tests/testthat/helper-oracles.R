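# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the trend statistic is a naive double loop and
# the exact null distribution is built from the full n! permutation matrix
# (the package enumerates distinct group assignments recursively instead).

.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) {
    return(.perm_cache[[key]])
  }
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      k <- nrow(P)
      out <- matrix(0L, k * m, m)
      for (pos in 1:m) {
        rows <- ((pos - 1) * k + 1):(pos * k)
        out[rows, pos] <- m
        out[rows, -pos] <- P
      }
      P <- out
    }
  }
  .perm_cache[[key]] <- P
  P
}

# naive pairwise count, ties as half
jt_stat_slow <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (x in groups[[i]]) {
        for (y in groups[[j]]) {
          s <- s + (x < y) + 0.5 * (x == y)
        }
      }
    }
  }
  s
}

# exact one-sided (increasing) p-value over all n! relabelings
jt_exact_oracle_p <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  n <- length(v)
  g <- rep(seq_along(groups), lengths(groups))
  P <- perm_matrix(n)
  V <- matrix(v[P], nrow(P), n)
  J <- numeric(nrow(P))
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      if (g[p] < g[q]) {
        J <- J + (V[, p] < V[, q]) + 0.5 * (V[, p] == V[, q])
      }
    }
  }
  obs <- jt_stat_slow(groups)
  mean(J >= obs - 1e-9)
}

# seeded Monte-Carlo permutation p-value (for sizes where n! is infeasible)
jt_mc_oracle_p <- function(groups, n_perm = 4000, seed = 1) {
  set.seed(seed)
  v <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  obs <- jt_stat_slow(groups)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- sample(v)
    gperm <- split(perm, rep(seq_along(sizes), sizes))
    if (jt_stat_slow(gperm) >= obs - 1e-9) hits <- hits + 1
  }
  hits / n_perm
}

# all ordered compositions of n into k positive parts
compositions <- function(n, k) {
  if (k == 1) {
    return(matrix(n, 1, 1))
  }
  out <- list()
  for (first in 1:(n - k + 1)) {
    rest <- compositions(n - first, k - 1)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}
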