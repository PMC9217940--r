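# Independent brute-force oracles used to validate the fast implementations.

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided rank-sum p by enumerating all choose(N, n1) assignments
enumRankSumP <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Kendall tau-b oracle: C/D from explicit pair loops, tie counts from
# value tables
tauOracle <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# topological overlap by explicit triple loop
tomOracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Anderson group-sum pseudo-F for a two-level grouping
andersonF <- function(D, groups) {
  D <- as.matrix(D)
  N <- nrow(D)
  a <- length(unique(groups))
  ss_t <- sum(D[upper.tri(D)]^2) / N
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    Dg <- D[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(Dg[upper.tri(Dg)]^2) / length(idx)
  }
  ss_a <- ss_t - ss_w
  list(F = (ss_a / (a - 1)) / (ss_w / (N - a)),
       R2 = ss_a / ss_t)
}

# a permutation of 1..n with exactly m inversions (greedy construction)
permWithInversions <- function(n, m) {
  stopifnot(m <= n * (n - 1) / 2)
  perm <- integer(0)
  remaining <- seq_len(n)
  for (pos in seq_len(n)) {
    left <- length(remaining)
    max_rest <- (left - 1) * (left - 2) / 2
    take <- min(left - 1, max(0, m - max_rest)) + 1
    # placing the take-th smallest remaining element adds (take - 1) inversions
    perm <- c(perm, remaining[take])
    m <- m - (take - 1)
    remaining <- remaining[-take]
  }
  perm
}
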