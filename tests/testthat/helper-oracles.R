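# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: explicit
# loops, naive formulas, and a linear solve instead of the closed form.

# geNorm M by explicit double loop over candidate pairs
brute_m_values <- function(rq) {
  k <- nrow(rq)
  n <- ncol(rq)
  out <- numeric(k)
  for (j in seq_len(k)) {
    vs <- c()
    for (kk in seq_len(k)) {
      if (kk == j) next
      ratios <- log2(rq[j, ] / rq[kk, ])
      mu <- sum(ratios) / n
      vs <- c(vs, sqrt(sum((ratios - mu)^2) / (n - 1)))
    }
    out[j] <- mean(vs)
  }
  names(out) <- rownames(rq)
  out
}

# geNorm iterative ranking re-implemented naively on a Cq-free RQ matrix
brute_genorm_order <- function(rq) {
  remaining <- rownames(rq)
  removed <- character(0)
  while (length(remaining) > 2) {
    m <- brute_m_values(rq[remaining, , drop = FALSE])
    worst <- min(names(m)[m >= max(m) - 1e-12])
    removed <- c(removed, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(removed = removed, final = sort(remaining))
}

# BestKeeper index and r from first principles
brute_bestkeeper_index <- function(cqm) {
  n <- ncol(cqm)
  out <- numeric(n)
  for (s in seq_len(n)) out[s] <- prod(cqm[, s])^(1 / nrow(cqm))
  names(out) <- colnames(cqm)
  out
}

brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# NormFinder candidate variances by solving the k x k moment system
# E[s_i^2] = ((k-1)/k)^2 sigma_i^2 + (1/k^2) sum_{i' != i} sigma_{i'}^2
brute_normfinder_sigma2 <- function(logq) {
  k <- nrow(logq); n <- ncol(logq)
  r <- matrix(0, k, n)
  for (i in seq_len(k)) {
    for (j in seq_len(n)) {
      r[i, j] <- logq[i, j] - mean(logq[i, ]) - mean(logq[, j]) + mean(logq)
    }
  }
  s2 <- numeric(k)
  for (i in seq_len(k)) s2[i] <- sum(r[i, ]^2) / (n - 1)
  A <- matrix(1 / k^2, k, k)
  diag(A) <- ((k - 1) / k)^2
  sigma2 <- solve(A, s2)
  names(sigma2) <- rownames(logq)
  sigma2
}

# Sidak-sharpened Holm by direct definition (no cummax tricks)
brute_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(i)
    for (j in seq_len(i)) vals[j] <- 1 - (1 - p[ord[j]])^(m - j + 1)
    adj[ord[i]] <- min(1, max(vals))
  }
  adj
}
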