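# Independent oracles used across the suite. Each re-derives a quantity by
# brute force or direct arithmetic, never through the code path it checks.

# average ranks by direct pairwise comparison
oracle_rank <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# Pearson correlation from raw sum formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# one-sided hypergeometric tail by explicit binomial-coefficient enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; K <- a + c; N <- a + b + c + d
  xs <- max(0, m + K - N):min(m, K)
  probs <- choose(K, xs) * choose(N - K, m - xs) / choose(N, m)
  sum(probs[xs >= a])
}

# naive O(n^3) average-linkage (UPGMA) agglomeration; returns merge heights
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  d <- D
  heights <- numeric(0)
  while (length(active) > 1L) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    ni <- length(active[[i]]); nj <- length(active[[j]])
    newd <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    if (length(keep)) {
      d2[seq_along(keep), seq_along(keep)] <- d[keep, keep, drop = FALSE]
      d2[length(keep) + 1L, seq_along(keep)] <- newd[keep]
      d2[seq_along(keep), length(keep) + 1L] <- newd[keep]
    }
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    d <- d2
  }
  heights
}

# brute-force kNN imputation of one missing cell (gene i, sample j)
oracle_knn_cell <- function(x, i, j, k) {
  n_genes <- nrow(x)
  d2 <- rep(Inf, n_genes)
  for (g in seq_len(n_genes)) {
    if (g == i) next
    shared <- !is.na(x[i, ]) & !is.na(x[g, ])
    if (!any(shared)) next
    d2[g] <- sum((x[i, shared] - x[g, shared])^2) / sum(shared)
  }
  elig <- which(is.finite(d2) & !is.na(x[, j]))
  ord <- order(d2[elig], rownames(x)[elig])
  mean(x[elig[ord][seq_len(min(k, length(elig)))], j])
}

# direct evaluation of the five coloc hypothesis posteriors from lABF vectors
oracle_coloc_pp <- function(l1, l2, p1, p2, p12) {
  bf1 <- exp(l1); bf2 <- exp(l2)
  s1 <- sum(bf1); s2 <- sum(bf2); s12 <- sum(bf1 * bf2)
  w <- c(1, p1 * s1, p2 * s2, p1 * p2 * (s1 * s2 - s12), p12 * s12)
  w / sum(w)
}

# adjusted Rand index from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
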