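test_that("kNN graphs connect nearest neighbours with deterministic ties", {
  # 3 collinear points at 0, 1, 10: nearest neighbours 0->1, 1->0, 2->1
  X <- matrix(c(0, 1, 10), ncol = 1)
  g <- build_knn_graph(X, k = 1, metric = "euclidean")
  expect_equal(g$A, t(g$A))
  expect_equal(g$A[1, 2], 1)
  expect_equal(g$A[2, 3], 1)
  expect_equal(g$A[1, 3], 0)

  # two identical points: one mutual edge
  g2 <- build_knn_graph(matrix(c(1, 1, 1, 1), 2, 2), k = 1, metric = "euclidean")
  expect_equal(g2$A, rbind(c(0, 1), c(1, 0)))

  # k = n-1 gives the complete graph
  withr::with_seed(1, X5 <- matrix(rnorm(10), 5, 2))
  g5 <- build_knn_graph(X5, k = 4, metric = "cosine")
  expect_true(all(g5$A[upper.tri(g5$A)] == 1))

  expect_error(build_knn_graph(X5, k = 5), "k <")
  expect_error(build_knn_graph(rbind(c(0, 0), c(1, 1), c(2, 2)), k = 1,
                               metric = "cosine"), "zero-norm")
})

test_that("normalized adjacency matches its defining formula", {
  expect_equal(normalized_adjacency(rbind(c(0, 1), c(1, 0))),
               matrix(0.5, 2, 2))
  expect_equal(normalized_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # 3-node path against the literal oracle
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(normalized_adjacency(A), oracle_normalized_adjacency(A),
               tolerance = 1e-12)
  # spectral radius bounded by 1
  withr::with_seed(2, A6 <- random_sym_graph(6))
  expect_lte(max(abs(eigen(normalized_adjacency(A6))$values)), 1 + 1e-12)
})

test_that("closed-form walk counts follow the transition-power formula", {
  A <- rbind(c(0, 1), c(1, 0))
  C <- walk_cooccurrence(A, L_walk = 1, walks_per_node = 7)
  expect_equal(C, rbind(c(0, 7), c(7, 0)))

  # isolated node yields an all-zero count row
  A3 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  C3 <- walk_cooccurrence(A3, L_walk = 2, walks_per_node = 10)
  expect_true(all(C3[3, ] == 0))

  withr::with_seed(4, A5 <- random_sym_graph(5))
  expect_equal(walk_cooccurrence(A5, L_walk = 3, walks_per_node = 100),
               oracle_walk_counts(A5, 3, 100), tolerance = 1e-10)
})

test_that("Monte-Carlo walks converge to the closed-form expectation", {
  # 5-node ring
  A <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; A[i, j] <- A[j, i] <- 1 }
  cf <- walk_cooccurrence(A, L_walk = 3, walks_per_node = 10000)
  mc <- walk_cooccurrence(A, L_walk = 3, walks_per_node = 10000,
                          mode = "monte_carlo", seed = 0)
  norm <- function(C) C / rowSums(C)
  expect_lt(max(abs(norm(mc) - norm(cf))), 0.05)
  # seeded determinism of the Monte-Carlo mode
  mc2 <- walk_cooccurrence(A, L_walk = 3, walks_per_node = 100,
                           mode = "monte_carlo", seed = 9)
  mc3 <- walk_cooccurrence(A, L_walk = 3, walks_per_node = 100,
                           mode = "monte_carlo", seed = 9)
  expect_identical(mc2, mc3)
})

test_that("PPMI matches hand evaluation and is scale-invariant in closed form", {
  # 2-node single-edge graph, L=1: both off-diagonals equal ln 2
  C <- rbind(c(0, 5), c(5, 0))
  P <- ppmi_from_counts(C, L_walk = 1)
  expect_equal(unclass(P)[1, 2], log(2), tolerance = 1e-12)
  expect_equal(unclass(P)[2, 1], log(2), tolerance = 1e-12)
  expect_true(all(diag(P) == 0))

  expect_true(all(ppmi_from_counts(matrix(0, 3, 3), 2) == 0))

  # invariance to walks_per_node: counts scale cancels in P(v|u)
  withr::with_seed(5, A <- random_sym_graph(6))
  p1 <- ppmi_from_counts(walk_cooccurrence(A, 3, walks_per_node = 10), 3)
  p2 <- ppmi_from_counts(walk_cooccurrence(A, 3, walks_per_node = 5000), 3)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-10)

  # nonnegative with zero diagonal on arbitrary inputs
  withr::with_seed(6, Cr <- {m <- matrix(rpois(36, 3), 6); diag(m) <- 0; m})
  Pr <- ppmi_from_counts(Cr, 4)
  expect_true(all(Pr >= 0) && all(diag(Pr) == 0))
})

test_that("PPMI normalisation symmetrises and handles zero-degree rows", {
  S <- normalize_ppmi(rbind(c(0, 2.5), c(2.5, 0)))
  expect_equal(S, rbind(c(0, 1), c(1, 0)))
  expect_equal(normalize_ppmi(matrix(0, 2, 2)), diag(2))
  # algebraic identity: S_P = D^{-1/2} P D^{-1/2} implies
  # (D^{1/2} S_P D^{1/2}) 1 = P 1
  withr::with_seed(7, P <- {m <- matrix(runif(25), 5); diag(m) <- 0; m})
  Psym <- (P + t(P)) / 2
  d <- rowSums(Psym)
  S5 <- normalize_ppmi(P)
  expect_equal(as.vector(sqrt(d) * (S5 %*% sqrt(d))), as.vector(Psym %*% rep(1, 5)),
               tolerance = 1e-10)
})

test_that("derived operators are equivariant under node relabeling", {
  withr::with_seed(8, A <- random_sym_graph(6))
  perm <- sample(6)
  Pm <- diag(6)[perm, ]
  expect_equal(normalized_adjacency(A[perm, perm]),
               (Pm %*% normalized_adjacency(A) %*% t(Pm)), tolerance = 1e-12)
  ppmi <- function(M) {
    p <- ppmi_from_counts(walk_cooccurrence(M, 3, 100), 3)
    matrix(as.numeric(p), nrow(p), ncol(p))
  }
  expect_equal(ppmi(A[perm, perm]), Pm %*% ppmi(A) %*% t(Pm), tolerance = 1e-10)
})
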