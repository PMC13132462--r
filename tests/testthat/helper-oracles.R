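# Independent literal re-evaluations of the model's linear-algebra
# operations, written as plain loops so they share no code with the
# implementation under test.

oracle_normalized_adjacency <- function(A) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- rowSums(At)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) S[i, j] <- At[i, j] / sqrt(D[i] * D[j])
  S
}

oracle_gconv <- function(S, H, W, b, relu = TRUE) {
  out <- S %*% H %*% W
  for (j in seq_len(ncol(out))) out[, j] <- out[, j] + b[j]
  if (relu) out[out < 0] <- 0
  out
}

oracle_attention <- function(Za, Zp, WQ, WK, WV) {
  n <- nrow(Za)
  d <- ncol(Za)
  Z <- matrix(0, n, d)
  for (i in 1:n) {
    H <- rbind(Za[i, ], Zp[i, ])          # 2 x d stack of channel slots
    Q <- H %*% WQ; K <- H %*% WK; V <- H %*% WV
    Sc <- Q %*% t(K) / sqrt(d)
    Att <- matrix(0, 2, 2)
    for (r in 1:2) Att[r, ] <- exp(Sc[r, ] - max(Sc[r, ])) /
        sum(exp(Sc[r, ] - max(Sc[r, ])))
    Hatt <- Att %*% V
    Z[i, ] <- (Hatt[1, ] + Hatt[2, ]) / 2  # Aggregate = mean over slots
  }
  Z
}

oracle_ppmi <- function(C, L_walk) {
  n <- nrow(C)
  P <- matrix(0, n, n)
  for (u in 1:n) {
    s <- sum(C[u, ])
    if (s > 0) for (v in 1:n) P[u, v] <- C[u, v] / s
  }
  Pv <- numeric(n)
  for (v in 1:n) Pv[v] <- sum(P[, v])
  out <- matrix(0, n, n)
  for (u in 1:n) for (v in 1:n) {
    if (P[u, v] > 0 && Pv[v] > 0) {
      out[u, v] <- max(0, log(P[u, v] / Pv[v] * n / L_walk))
    }
  }
  out
}

oracle_walk_counts <- function(A, L_walk, walks_per_node) {
  n <- nrow(A)
  Tm <- matrix(0, n, n)
  for (i in 1:n) if (sum(A[i, ]) > 0) Tm[i, ] <- A[i, ] / sum(A[i, ])
  C <- matrix(0, n, n)
  P <- diag(n)
  for (t in 1:L_walk) {
    P <- P %*% Tm
    C <- C + P
  }
  C <- C * walks_per_node
  diag(C) <- 0
  C
}

relu_ref <- function(M, b) {
  out <- M
  for (j in seq_len(ncol(out))) out[, j] <- out[, j] + b[j]
  out[out < 0] <- 0
  out
}

random_sym_graph <- function(n, p = 0.5) {
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  # ensure no fully isolated graph pathologies in oracle comparisons
  if (all(A == 0)) A[1, 2] <- A[2, 1] <- 1
  A
}
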