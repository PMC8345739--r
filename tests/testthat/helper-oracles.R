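# Independent oracles used across the suite. Each is a direct, brute-force
# or closed-form computation kept free of the code paths it checks.

# Closed-form Tofts concentration for a single-exponential AIF
# Cp(t) = c0 exp(-m t) (t in min, rates in 1/min).
tofts_exp_oracle <- function(ktrans, kep, c0, m, t_min) {
  ktrans * c0 * (exp(-m * t_min) - exp(-kep * t_min)) / (kep - m)
}

# Closed-form irreversible-2TC tissue curve for Cp(t) = c0 exp(-m t)
# (t min, rates 1/min); returns (1 - vb)(C1 + C2) + vb Cp.
tc2_exp_oracle <- function(k1, k2, k3, vb, c0, m, t_min) {
  beta <- k2 + k3
  c1 <- k1 * c0 * (exp(-m * t_min) - exp(-beta * t_min)) / (beta - m)
  c2 <- k3 * k1 * c0 / (beta - m) *
    ((1 - exp(-m * t_min)) / m - (1 - exp(-beta * t_min)) / beta)
  (1 - vb) * (c1 + c2) + vb * c0 * exp(-m * t_min)
}

# All set partitions of n elements as restricted-growth strings.
enumerate_set_partitions <- function(n) {
  res <- list()
  rec <- function(a, k) {
    if (length(a) == n) { res[[length(res) + 1]] <<- a; return(invisible()) }
    for (lab in seq_len(k + 1)) rec(c(a, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  res
}

# Signed spin-glass coupling matrix, re-derived from the Hamiltonian
# definition (independent of the package's internal builder).
oracle_coupling <- function(W, gamma_pos = 1, gamma_neg = 1) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  null_term <- function(Wl) {
    m <- sum(Wl) / 2
    if (m > 0) outer(rowSums(Wl), rowSums(Wl)) / (2 * m) else 0 * Wl
  }
  A <- (Wp - gamma_pos * null_term(Wp)) - (Wn - gamma_neg * null_term(Wn))
  diag(A) <- 0
  A
}

# Exhaustive minimum of H over all partitions of the nodes of a small graph.
exhaustive_min_energy <- function(W, gamma_pos = 1, gamma_neg = 1) {
  n <- nrow(W)
  A <- oracle_coupling(W, gamma_pos, gamma_neg)
  parts <- enumerate_set_partitions(n)
  P <- do.call(rbind, parts)
  h <- numeric(nrow(P))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      h <- h - A[i, j] * (P[, i] == P[, j])
  min(h)
}

# Exact two-sided permutation p-value for the Spearman correlation of a
# length-6 pair, over all 720 orderings.
spearman_exact_p6 <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  obs <- cor(x, y, method = "spearman")
  vals <- vapply(perms(y), function(yy) cor(x, yy, method = "spearman"),
                 numeric(1))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
# (no ties, no zeros).
wilcoxon_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# random signed weighted graph on n nodes with edge probability p_edge
random_signed_graph <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, -1, 1)
  dimnames(W) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  W
}

graph_from_w <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
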