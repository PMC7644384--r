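# Independent brute-force oracles for the exact rank tests, written
# against the documented two-sided convention
# p = min(1, 2 * min(lower tail, upper tail)).

oracle_wilcoxon <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  min(1, 2 * min(mean(dist <= v + 1e-9), mean(dist >= v - 1e-9)))
}

oracle_mann_whitney <- function(g1, g2) {
  n1 <- length(g1); N <- n1 + length(g2)
  r <- rank(c(g1, g2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dist <- apply(combn(N, n1), 2, function(ix) sum(r[ix])) -
    n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(dist <= u + 1e-9), mean(dist >= u - 1e-9)))
}

oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  A <- sum(R^2); C <- n * k * (k + 1)^2 / 4
  statf <- function(Rs) if (A - C <= 1e-12) 0 else
    (k - 1) * sum((Rs - n * (k + 1) / 2)^2) / (A - C)
  obs <- statf(colSums(R))
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), n)))
  pk <- penlaws:::.perm_matrix(k)
  hits <- 0
  for (i in seq_len(nrow(perms))) {
    Rs <- colSums(do.call(rbind, lapply(seq_len(n), function(s)
      R[s, pk[perms[i, s], ]])))
    if (statf(Rs) >= obs - 1e-9) hits <- hits + 1
  }
  hits / nrow(perms)
}
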