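#' Jonckheere-Terpstra test for an ordered concentration trend
#'
#' Rank-based test for a monotone increase across groups ordered by
#' concentration, used as the concentration-response condition of the hazard
#' decision tree. The statistic is the number of cross-group pairs
#' (lower-dose value, higher-dose value) in increasing order, with ties
#' counted as half:
#' \deqn{J = \sum_{i<j} \#\{x \in g_i, y \in g_j : x < y\} + \tfrac12 \#\{x = y\}.}
#'
#' The p-value for the one-sided increasing alternative is exact — computed by
#' full enumeration of the permutation distribution — when the total sample
#' size is at most `exact_limit` and the number of distinct group assignments
#' (the multinomial coefficient) is at most `enum_cap`; otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param groups List of numeric vectors, ordered by increasing concentration
#'   (at least 3 groups, each non-empty).
#' @param alternative Only `"increasing"` is supported.
#' @param exact_limit Maximum total n for the exact enumeration (default 10).
#' @param enum_cap Maximum number of enumerated assignments (default 1e5).
#' @return Object of class `jonckheere_trend`: a list with `statistic`,
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `n_groups`,
#'   `n_total`, and `alternative`.
#' @examples
#' jonckheere_test(list(1, 2, 3)) # J = 3, exact p = 1/6
#' @export
jonckheere_test <- function(groups, alternative = "increasing",
                            exact_limit = 10, enum_cap = 1e5) {
  alternative <- match.arg(alternative, "increasing")
  if (!is.list(groups) || length(groups) < 3) {
    stop("need at least 3 ordered groups")
  }
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must contain at least one observation")
  v <- unlist(groups, use.names = FALSE)
  if (anyNA(v)) stop("missing observations are not allowed")
  n <- length(v)
  k <- length(groups)

  stat <- .jt_statistic(groups)

  if (length(unique(v)) == 1L) {
    return(.jt_result(stat, 1, "exact", k, n, alternative))
  }

  n_assign <- .jt_n_assignments(sizes)
  if (n <= exact_limit && n_assign <= enum_cap) {
    dist <- .jt_exact_dist(v, sizes)
    p <- sum(dist >= stat - 1e-9) / length(dist)
    return(.jt_result(stat, p, "exact", k, n, alternative))
  }

  mu <- (n^2 - sum(sizes^2)) / 4
  tt <- table(v)
  A <- n * (n - 1) * (2 * n + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(tt * (tt - 1) * (2 * tt + 5))
  B <- sum(sizes * (sizes - 1) * (sizes - 2)) * sum(tt * (tt - 1) * (tt - 2))
  C <- sum(sizes * (sizes - 1)) * sum(tt * (tt - 1))
  v2 <- A / 72 + B / (36 * n * (n - 1) * (n - 2)) + C / (8 * n * (n - 1))
  if (v2 <= 0) {
    return(.jt_result(stat, 1, "normal_approx", k, n, alternative))
  }
  p <- pnorm((stat - mu) / sqrt(v2), lower.tail = FALSE)
  .jt_result(stat, p, "normal_approx", k, n, alternative)
}

.jt_result <- function(stat, p, method, k, n, alternative) {
  structure(
    list(
      statistic = stat, p_value = min(max(p, 0), 1), method = method,
      n_groups = k, n_total = n, alternative = alternative
    ),
    class = "jonckheere_trend"
  )
}

#' @export
print.jonckheere_trend <- function(x, ...) {
  cat(
    "Jonckheere-Terpstra trend test (", x$alternative, ")\n",
    "J = ", format(x$statistic), ", p = ", format.pval(x$p_value),
    " [", x$method, ", ", x$n_groups, " groups, n = ", x$n_total, "]\n",
    sep = ""
  )
  invisible(x)
}

.jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- outer(groups[[i]], groups[[j]], function(x, y) (x < y) + 0.5 * (x == y))
      s <- s + sum(d)
    }
  }
  s
}

.jt_n_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- 1
  for (s in sizes) {
    out <- out * choose(n, s)
    n <- n - s
    if (!is.finite(out)) break
  }
  out
}

## Exact permutation distribution of J by recursive assignment of the pooled
## values to the ordered groups. Each leaf is one distinct index assignment;
## cross-pair contributions are accumulated group by group against the values
## still to be assigned (which all belong to later, higher-dose groups).
.jt_exact_dist <- function(v, sizes) {
  k <- length(sizes)
  rec <- function(idx, g, acc) {
    if (g == k) {
      return(acc)
    }
    combs <- utils::combn(seq_along(idx), sizes[g])
    out <- vector("list", ncol(combs))
    for (ci in seq_len(ncol(combs))) {
      take <- combs[, ci]
      x <- v[idx[take]]
      rest <- idx[-take]
      y <- v[rest]
      contrib <- sum(outer(x, y, function(a, b) (a < b) + 0.5 * (a == b)))
      out[[ci]] <- rec(rest, g + 1L, acc + contrib)
    }
    unlist(out, use.names = FALSE)
  }
  rec(seq_along(v), 1L, 0)
}
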