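test_that("accessibility head evaluates the sigmoid link exactly", {
  p <- init_embedder_params(4, hidden = c(3, 2), n_cell = 2, seed = 0)
  p$W_o <- cbind(c(1, 0), c(-1, 0))
  p$b_o <- c(0, 0)
  Z <- rbind(c(1, 0))
  expect_equal(as.vector(forward_accessibility(Z, p)),
               c(1 / (1 + exp(-1)), 1 / (1 + exp(1))), tolerance = 1e-12)

  # zero logits give exactly 0.5, and probabilities rise monotonically in the logit
  p$W_o <- matrix(0, 2, 2)
  expect_true(all(forward_accessibility(matrix(0, 3, 2), p) == 0.5))
  s <- vapply(c(2, 4, 8), function(l) {
    q <- p; q$W_o <- matrix(l, 2, 2)
    forward_accessibility(matrix(c(1, 1), 1), q)[1, 1]
  }, numeric(1))
  expect_true(all(diff(s) > 0) && all(s < 1))
})

test_that("binary cross-entropy matches closed-form values", {
  Y <- rbind(c(1, 0), c(0, 1))
  expect_equal(bce_loss(matrix(0.5, 2, 2), Y), log(2), tolerance = 1e-9)
  expect_lte(bce_loss(Y, Y), 1.1e-7)
  expect_equal(bce_loss(rbind(c(0.9, 0.2)), rbind(c(1, 0))),
               (-log(0.9) - log(0.8)) / 2, tolerance = 1e-9)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 2)), "shape")
})

test_that("analytic reconstruction gradient matches central finite differences", {
  withr::with_seed(42, {
    Z <- matrix(rnorm(6), 3, 2)       # 3 peaks, hidden width 2
    Y <- matrix(rbinom(6, 1, 0.5), 3, 2)
    W_o <- matrix(rnorm(4), 2, 2)
    b_o <- rnorm(2)
  })
  p <- list(W_o = W_o, b_o = b_o)
  Yhat <- forward_accessibility(Z, p)
  analytic <- crossprod(Z, (Yhat - Y) / length(Y))
  eps <- 1e-6
  for (i in 1:2) for (j in 1:2) {
    pp <- p; pp$W_o[i, j] <- pp$W_o[i, j] + eps
    pm <- p; pm$W_o[i, j] <- pm$W_o[i, j] - eps
    fd <- (bce_loss(forward_accessibility(Z, pp), Y) -
           bce_loss(forward_accessibility(Z, pm), Y)) / (2 * eps)
    expect_equal(analytic[i, j], fd, tolerance = 1e-4)
  }
})

test_that("full embedder backward pass agrees with finite differences", {
  withr::with_seed(1, {
    Z0 <- matrix(rnorm(5 * 4), 5, 4)
    Y <- matrix(rbinom(5 * 3, 1, 0.4), 5, 3)
  })
  params <- init_embedder_params(4, hidden = c(4, 3), n_cell = 3, seed = 2)
  loss_at <- function(p) {
    fw <- atacGDA:::embedder_hidden_forward(p, Z0)
    bce_loss(forward_accessibility(fw$H, p), Y)
  }
  fw <- atacGDA:::embedder_hidden_forward(params, Z0)
  Yhat <- forward_accessibility(fw$H, params)
  g <- atacGDA:::embedder_backward(params, fw, Z0, Yhat, Y)
  eps <- 1e-6
  probes <- list(c("W1", 1, 2), c("W2", 3, 1), c("W_o", 2, 2),
                 c("b1", 1, NA), c("b_o", 3, NA))
  for (pr in probes) {
    nm <- pr[1]; i <- as.integer(pr[2]); j <- suppressWarnings(as.integer(pr[3]))
    bump <- function(p, by) {
      if (nm %in% c("W1", "W2")) {
        l <- as.integer(substr(nm, 2, 2)); p$W[[l]][i, j] <- p$W[[l]][i, j] + by
      } else if (nm == "b1") p$b[[1]][i] <- p$b[[1]][i] + by
      else if (nm == "W_o") p$W_o[i, j] <- p$W_o[i, j] + by
      else p$b_o[i] <- p$b_o[i] + by
      p
    }
    fd <- (loss_at(bump(params, eps)) - loss_at(bump(params, -eps))) / (2 * eps)
    analytic <- if (is.na(j)) g[[nm]][i] else g[[nm]][i, j]
    expect_equal(analytic, fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("training is seeded-deterministic and epochs=0 returns the init", {
  sim <- tiny_sim()
  pe <- encode_peaks(sim$peaks, kmer_encoder(2))
  e1 <- train_cell_embedder(pe, sim$source$acc, hidden = c(16, 8), epochs = 5, seed = 3)
  e2 <- train_cell_embedder(pe, sim$source$acc, hidden = c(16, 8), epochs = 5, seed = 3)
  expect_identical(e1$params, e2$params)
  expect_identical(e1$history, e2$history)
  expect_length(e1$history, 5)
  expect_true(all(is.finite(e1$history)))
  expect_lte(tail(e1$history, 1), e1$history[1])

  e0 <- train_cell_embedder(pe, sim$source$acc, hidden = c(16, 8), epochs = 0, seed = 3)
  expect_identical(e0$params,
                   init_embedder_params(ncol(pe$values), c(16, 8),
                                        ncol(sim$source$acc$values), seed = 3))
  expect_length(e0$history, 0)
})

test_that("cell embeddings are the head weight columns", {
  p <- init_embedder_params(4, hidden = c(4, 3), n_cell = 3, seed = 0)
  p$W_o <- diag(3)
  ce <- extract_cell_embeddings(p, barcodes = c("a", "b", "c"))
  expect_equal(ce$values, diag(3))
  expect_equal(t(ce$values), p$W_o)   # transpose round trip
  expect_error(extract_cell_embeddings(p, barcodes = c("a", "b")), "barcode count")
})

test_that("embeddings organise cells by type on a clean fixture", {
  # full-scale reconstruction training, no batch effect, three seeds
  purities <- sils <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_domain_pair(sim_config(beta = 0, n_cells_target = 2,
                                           seed = i - 1))
    pe <- encode_peaks(sim$peaks, kmer_encoder(4))
    emb <- train_cell_embedder(pe, sim$source$acc, seed = i - 1)
    X <- extract_cell_embeddings(emb)$values
    y <- sim$source$labels$label
    purities[i] <- nn_purity(X, y)
    sils[i] <- mean_silhouette(X, y)
  }
  expect_gte(mean(purities), 0.9)
  expect_gt(mean(sils), 0)
})
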