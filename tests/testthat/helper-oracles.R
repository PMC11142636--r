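# Independent oracles used across the suite. These are deliberately written
# as plain elementwise loops so they share no code path with the package's
# vectorized implementations.

# cosine of two vectors with the zero-vector-gives-0 convention
oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(0)
  }
  s <- 0
  for (k in seq_along(a)) s <- s + a[k] * b[k]
  s / (na * nb)
}

# per-row mixed-cosine scores -> softmax weights, evaluated row by row
oracle_retrieval_weights <- function(S, C, qs, qc, tau, sw = 1, cw = 1) {
  n <- nrow(S)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    sc[i] <- sw * oracle_cosine(qs, S[i, ]) + cw * oracle_cosine(qc, C[i, ])
  }
  e <- exp(sc / tau - max(sc / tau))
  e / sum(e)
}

# weighted average by explicit loop
oracle_weighted_average <- function(M, w) {
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    for (i in seq_len(nrow(M))) out[j] <- out[j] + w[i] * M[i, j]
  }
  out
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x
    xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# finite differences over a matrix-valued parameter
fd_gradient_matrix <- function(f, M, h = 1e-5) {
  G <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      Mp <- M
      Mm <- M
      Mp[i, j] <- Mp[i, j] + h
      Mm[i, j] <- Mm[i, j] - h
      G[i, j] <- (f(Mp) - f(Mm)) / (2 * h)
    }
  }
  G
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# build a small populated store
toy_store <- function(S, C, O) {
  st <- memory_store(ncol(S), ncol(C), ncol(O))
  for (i in seq_len(nrow(S))) memory_append(st, S[i, ], C[i, ], O[i, ])
  st
}

onehot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}
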