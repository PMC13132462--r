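test_that("graph convolution layers match a literal evaluation of the rule", {
  S <- matrix(0.5, 2, 2)
  expect_equal(agconv_forward(S, diag(2), diag(2), c(0, 0)), matrix(0.5, 2, 2))
  # large negative bias clamps a hidden layer to zero
  expect_true(all(agconv_forward(S, diag(2), diag(2), c(-10, -10)) == 0))

  withr::with_seed(10, {
    A <- random_sym_graph(4)
    H <- matrix(rnorm(12), 4, 3)
    W <- matrix(rnorm(6), 3, 2)
    b <- rnorm(2)
  })
  Sn <- normalized_adjacency(A)
  expect_equal(agconv_forward(Sn, H, W, b), oracle_gconv(Sn, H, W, b),
               tolerance = 1e-12)
  expect_equal(agconv_forward(Sn, H, W, b, activation = "linear"),
               oracle_gconv(Sn, H, W, b, relu = FALSE), tolerance = 1e-12)

  # the global channel is the same rule under a different operator,
  # and with identical operators the outputs coincide
  expect_equal(pgconv_forward(Sn, H, W, b), agconv_forward(Sn, H, W, b))
  expect_equal(pgconv_forward(diag(4), H, W, b), relu_ref(H %*% W, b))
})

test_that("the convolution channels share one weight object", {
  td <- toy_domains()
  m <- train_gda(td$s, td$t, train_config(epochs = 3, seed = 0))
  # both channels and both domains reference the same W1/W2: mutating the
  # shared weight changes both channel outputs
  p <- m$params
  h_a <- agconv_forward(td$s$S, td$s$X, p$W1, p$b1)
  h_p <- pgconv_forward(td$s$Sp, td$s$X, p$W1, p$b1)
  p$W1 <- p$W1 * 2
  expect_false(isTRUE(all.equal(agconv_forward(td$s$S, td$s$X, p$W1, p$b1), h_a)))
  expect_false(isTRUE(all.equal(pgconv_forward(td$s$Sp, td$s$X, p$W1, p$b1), h_p)))
})

test_that("attention fusion matches a per-node literal evaluation", {
  withr::with_seed(11, {
    Za <- matrix(rnorm(5 * 4), 5, 4)
    Zp <- matrix(rnorm(5 * 4), 5, 4)
    WQ <- matrix(rnorm(16), 4, 4)
    WK <- matrix(rnorm(16), 4, 4)
    WV <- matrix(rnorm(16), 4, 4)
  })
  expect_equal(attention_fuse(Za, Zp, WQ, WK, WV),
               oracle_attention(Za, Zp, WQ, WK, WV), tolerance = 1e-12)

  # identical inputs are a fixed point mapped through W_V
  expect_equal(attention_fuse(Za, Za, WQ, WK, WV), Za %*% WV, tolerance = 1e-12)

  # zero query/key projections give exactly uniform attention
  fz <- attention_fuse(Za, Zp, WQ * 0, WK * 0, diag(4), return_weights = TRUE)
  expect_true(all(abs(fz$weights - 0.5) < 1e-15))
  expect_equal(fz$Z, (Za + Zp) / 2, tolerance = 1e-12)
  # weights are a proper softmax: rows of each slot pair sum to 1
  fw <- attention_fuse(Za, Zp, WQ, WK, WV, return_weights = TRUE)
  expect_equal(fw$weights[, "a11"] + fw$weights[, "a12"], rep(1, 5))
  expect_equal(fw$weights[, "a21"] + fw$weights[, "a22"], rep(1, 5))
})

test_that("gradient reversal is the identity forward and exact negation backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_equal(as.vector(grl(x, 2)), as.vector(x))
  expect_equal(grl_gradient(x, 0), x * 0)

  # scalar toy model: feature z = theta, discriminator p = sigmoid(w z),
  # loss -log p. The gradient reaching theta through the reversal layer
  # must equal -lambda times the unreversed derivative, exactly.
  theta <- 0.7; w <- -1.3; lambda <- 1.8
  p <- 1 / (1 + exp(-w * theta))
  d_plain <- -(1 - p) * w              # d(-log p)/d theta without reversal
  expect_identical(grl_gradient(d_plain, lambda), -lambda * d_plain)
  # numeric cross-check of the unreversed derivative
  eps <- 1e-7
  f <- function(t) -log(1 / (1 + exp(-w * t)))
  expect_equal(d_plain, (f(theta + eps) - f(theta - eps)) / (2 * eps),
               tolerance = 1e-6)
})

test_that("classifier and discriminator heads are proper probability maps", {
  withr::with_seed(12, Z <- matrix(rnorm(40), 10, 4))
  params <- init_gda_params(3, c(3, 4), n_classes = 3, seed = 1)
  post <- classify(Z, params)
  expect_equal(rowSums(post), rep(1, 10), tolerance = 1e-6)
  pz <- params; pz$Wc <- pz$Wc * 0; pz$bc <- pz$bc * 0
  expect_true(all(abs(classify(Z, pz) - 1 / 3) < 1e-12))
  # raising one logit strictly raises its posterior
  p1 <- classify(Z, params)
  pb <- params; pb$bc[2] <- pb$bc[2] + 0.5
  expect_true(all(classify(Z, pb)[, 2] > p1[, 2]))

  ps <- discriminate(Z, params)
  expect_true(all(ps > 0 & ps < 1))
  pzd <- params; pzd$Wd1 <- pzd$Wd1 * 0; pzd$Wd2 <- pzd$Wd2 * 0
  expect_true(all(discriminate(Z, pzd) == 0.5))
  expect_equal(ps + (1 - ps), rep(1, 10))
})

test_that("the full model gradient agrees with finite differences of the loss", {
  td <- toy_domains(n_s = 7, n_t = 6, d = 4, C = 2, seed = 3)
  params <- init_gda_params(4, c(3, 4), n_classes = 2, disc_hidden = 3, seed = 5)
  lambda <- 0.7
  ev <- atacGDA:::gda_forward_backward(params, td$s, td$t, lambda, grl_mult = 1)
  loss_parts <- function(p) {
    e <- atacGDA:::gda_forward_backward(p, td$s, td$t, lambda, compute_grads = FALSE)
    c(cls = e$loss_cls, grl = e$loss_grl)
  }
  eps <- 1e-6
  # encoder parameters see dL_cls - lambda * dL_grl (reversal);
  # classifier head sees dL_cls; discriminator sees +lambda * dL_grl
  probes <- list(W1 = c(2, 1), b1 = 3, W2 = c(1, 2), b2 = 2, WQ = c(3, 3),
                 WK = c(1, 4), WV = c(2, 2), Wc = c(4, 1), bc = 2,
                 Wd1 = c(2, 3), bd1 = 1, Wd2 = c(3, 1), bd2 = 1)
  for (nm in names(probes)) {
    idx <- probes[[nm]]
    bump <- function(p, by) {
      if (length(idx) == 2) p[[nm]][idx[1], idx[2]] <- p[[nm]][idx[1], idx[2]] + by
      else p[[nm]][idx] <- p[[nm]][idx] + by
      p
    }
    fd <- (loss_parts(bump(params, eps)) - loss_parts(bump(params, -eps))) / (2 * eps)
    expected <- if (nm %in% c("Wc", "bc")) fd["cls"]
      else if (nm %in% c("Wd1", "bd1", "Wd2", "bd2")) lambda * fd["grl"]
      else fd["cls"] - lambda * fd["grl"]
    analytic <- if (length(idx) == 2) ev$grads[[nm]][idx[1], idx[2]]
      else ev$grads[[nm]][idx]
    expect_equal(analytic, unname(expected), tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("forward pass and predictions are node-permutation equivariant", {
  td <- toy_domains(n_s = 8, n_t = 5, seed = 6)
  m <- train_gda(td$s, td$t, train_config(epochs = 5, seed = 1))
  pred <- predict(m, td$t)
  perm <- c(3, 5, 1, 2, 4)
  tp <- td$t
  tp$X <- tp$X[perm, ]; tp$S <- tp$S[perm, perm]; tp$Sp <- tp$Sp[perm, perm]
  tp$barcodes <- tp$barcodes[perm]
  pred_p <- predict(m, tp)
  expect_identical(pred_p$labels, pred$labels[perm])
  expect_equal(pred_p$posteriors, pred$posteriors[perm, ], tolerance = 1e-12)
})
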