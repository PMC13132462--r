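# Dual-channel graph network for domain adaptation. One set of GCN weights
# is shared by the local channel (AgConv, propagating with the normalised
# self-loop adjacency S) and the global channel (PgConv, propagating with
# the normalised PPMI operator Sp), and across the source and target
# graphs. Channel outputs are fused per node by scaled dot-product
# attention over the two channel slots; fused features feed a softmax
# classifier (source supervision) and, through a gradient reversal layer, a
# sigmoid domain discriminator.

#' Initialise GDA model parameters
#'
#' Layer weights are single objects referenced by both convolution channels
#' and both domains; sharing is structural, not copied.
#'
#' @param d_in Input feature width (cell-embedding dimension, default 128).
#' @param hidden GCN widths, default `c(100, 16)` (two layers).
#' @param n_classes Number of source classes.
#' @param disc_hidden Hidden width of the domain discriminator MLP
#'   (default 40; the discriminator is `hidden[2] -> disc_hidden -> 1`).
#' @param seed Integer seed.
#' @return A `gda_params` list: `W1`, `b1`, `W2`, `b2`, `WQ`, `WK`, `WV`,
#'   `Wc`, `bc`, `Wd1`, `bd1`, `Wd2`, `bd2`.
#' @export
init_gda_params <- function(d_in = 128, hidden = c(100, 16), n_classes,
                            disc_hidden = 40, seed = 0) {
  stopifnot(length(hidden) == 2)
  with_substream(seed, "gda-init", {
    d_out <- hidden[2]
    structure(list(
      W1 = glorot(d_in, hidden[1]), b1 = numeric(hidden[1]),
      W2 = glorot(hidden[1], d_out), b2 = numeric(d_out),
      WQ = glorot(d_out, d_out), WK = glorot(d_out, d_out),
      WV = glorot(d_out, d_out),
      Wc = glorot(d_out, n_classes), bc = numeric(n_classes),
      Wd1 = glorot(d_out, disc_hidden), bd1 = numeric(disc_hidden),
      Wd2 = glorot(disc_hidden, 1), bd2 = 0,
      hidden = hidden), class = "gda_params")
  })
}

#' Local-channel graph convolution layer
#'
#' `H' = phi(S %*% H %*% W + b)` with `phi = ReLU` on hidden layers; the
#' final layer is linear (`activation = "linear"`) so pre-activation
#' features feed the attention fusion.
#'
#' @param S Normalised adjacency operator (precompute once per graph with
#'   [normalized_adjacency()]; it only changes when the graph does).
#' @param H Node features.
#' @param W,b Layer weights (shared with [pgconv_forward()]).
#' @param activation `"relu"` (default) or `"linear"`.
#' @return Propagated node features.
#' @export
agconv_forward <- function(S, H, W, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  out <- add_bias(S %*% H %*% W, b)
  if (activation == "relu") out <- relu(out)
  out
}

#' Global-channel graph convolution layer
#'
#' Identical propagation rule to [agconv_forward()] but over the normalised
#' PPMI operator; call it with the *same* `W`, `b` objects as the matching
#' local layer — weight sharing between the channels is part of the model.
#'
#' @inheritParams agconv_forward
#' @param S_P Normalised PPMI operator (see [normalize_ppmi()]).
#' @export
pgconv_forward <- function(S_P, H, W, b, activation = c("relu", "linear")) {
  agconv_forward(S_P, H, W, b, activation = activation)
}

# Vectorised two-slot scaled dot-product attention over all nodes at once.
# Returns the fused features plus every intermediate needed for backprop.
attention_forward <- function(Za, Zp, WQ, WK, WV) {
  d <- ncol(Za)
  sc <- 1 / sqrt(d)
  Qa <- Za %*% WQ; Qp <- Zp %*% WQ
  Ka <- Za %*% WK; Kp <- Zp %*% WK
  Va <- Za %*% WV; Vp <- Zp %*% WV
  s11 <- rowSums(Qa * Ka) * sc; s12 <- rowSums(Qa * Kp) * sc
  s21 <- rowSums(Qp * Ka) * sc; s22 <- rowSums(Qp * Kp) * sc
  soft2 <- function(x, y) {
    m <- pmax(x, y)
    ex <- exp(x - m); ey <- exp(y - m)
    ex / (ex + ey)
  }
  a11 <- soft2(s11, s12); a12 <- 1 - a11
  a21 <- soft2(s21, s22); a22 <- 1 - a21
  R1 <- a11 * Va + a12 * Vp
  R2 <- a21 * Va + a22 * Vp
  list(Z = 0.5 * (R1 + R2), Qa = Qa, Qp = Qp, Ka = Ka, Kp = Kp, Va = Va,
       Vp = Vp, a11 = a11, a12 = a12, a21 = a21, a22 = a22, sc = sc,
       Za = Za, Zp = Zp)
}

attention_backward <- function(cache, dZ, WQ, WK, WV) {
  dR <- 0.5 * dZ   # both slot rows receive half of the mean's gradient
  da11 <- rowSums(dR * cache$Va); da12 <- rowSums(dR * cache$Vp)
  da21 <- rowSums(dR * cache$Va); da22 <- rowSums(dR * cache$Vp)
  dVa <- (cache$a11 + cache$a21) * dR
  dVp <- (cache$a12 + cache$a22) * dR
  # softmax over two slots, per query row
  g1 <- cache$a11 * da11 + cache$a12 * da12
  ds11 <- cache$a11 * (da11 - g1); ds12 <- cache$a12 * (da12 - g1)
  g2 <- cache$a21 * da21 + cache$a22 * da22
  ds21 <- cache$a21 * (da21 - g2); ds22 <- cache$a22 * (da22 - g2)
  sc <- cache$sc
  dQa <- (ds11 * cache$Ka + ds12 * cache$Kp) * sc
  dQp <- (ds21 * cache$Ka + ds22 * cache$Kp) * sc
  dKa <- (ds11 * cache$Qa + ds21 * cache$Qp) * sc
  dKp <- (ds12 * cache$Qa + ds22 * cache$Qp) * sc
  list(
    dWQ = crossprod(cache$Za, dQa) + crossprod(cache$Zp, dQp),
    dWK = crossprod(cache$Za, dKa) + crossprod(cache$Zp, dKp),
    dWV = crossprod(cache$Za, dVa) + crossprod(cache$Zp, dVp),
    dZa = tcrossprod(dQa, WQ) + tcrossprod(dKa, WK) + tcrossprod(dVa, WV),
    dZp = tcrossprod(dQp, WQ) + tcrossprod(dKp, WK) + tcrossprod(dVp, WV))
}

#' Attention fusion of local and global channel features
#'
#' Per node, the two 16-d channel vectors are stacked into a 2-slot
#' sequence; shared projections produce queries, keys and values, attention
#' weights are `softmax(Q K' / sqrt(d))` over the two slots, and the fused
#' feature is the mean of the two attended rows.
#'
#' @param Z_A Local-channel features (nodes x d).
#' @param Z_P Global-channel features, same shape.
#' @param W_Q,W_K,W_V Shared projection matrices (d x d).
#' @param return_weights If TRUE, also return per-node attention weights.
#' @return Fused features (nodes x d), or a list with `Z` and `weights`.
#' @export
attention_fuse <- function(Z_A, Z_P, W_Q, W_K, W_V, return_weights = FALSE) {
  if (!all(dim(Z_A) == dim(Z_P))) stop_gda("channel feature shapes differ")
  fw <- attention_forward(Z_A, Z_P, W_Q, W_K, W_V)
  if (return_weights) {
    list(Z = fw$Z, weights = cbind(a11 = fw$a11, a12 = fw$a12,
                                   a21 = fw$a21, a22 = fw$a22))
  } else {
    fw$Z
  }
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; during backpropagation the gradient
#' flowing upstream is multiplied by `-lambda` (see [grl_gradient()]).
#' The training loop applies the reversal analytically; this function
#' documents and exposes the forward contract.
#'
#' @param x Input (returned unchanged).
#' @param lambda Reversal strength, `>= 0`.
#' @return `x`, with the reversal strength attached as an attribute.
#' @export
grl <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  attr(x, "grl_lambda") <- lambda
  x
}

#' Backward rule of the gradient reversal layer
#'
#' @param grad Gradient arriving from downstream.
#' @param lambda Reversal strength.
#' @return `-lambda * grad`.
#' @export
grl_gradient <- function(grad, lambda = 1) {
  -lambda * grad
}

#' Class posteriors from fused features
#' @param Z Fused node features.
#' @param params `gda_params` (uses `Wc`, `bc`).
#' @return Matrix of posteriors, rows summing to 1.
#' @export
classify <- function(Z, params) {
  softmax_rows(add_bias(Z %*% params$Wc, params$bc))
}

#' Domain discriminator probability of "source"
#'
#' A one-hidden-layer MLP (ReLU, then a single sigmoid logit) applied to
#' (gradient-reversed) fused features; `p_source` is the probability the
#' node comes from the source domain and `1 - p_source` the probability it
#' is a target node.
#'
#' @param Z Fused node features (conceptually `grl(Z)`).
#' @param params `gda_params` (uses `Wd1`, `bd1`, `Wd2`, `bd2`).
#' @return Vector of probabilities strictly inside `(0, 1)`.
#' @export
discriminate <- function(Z, params) {
  discriminate_cache(Z, params)$p
}

discriminate_cache <- function(Z, params) {
  pre <- add_bias(Z %*% params$Wd1, params$bd1)
  Hd <- relu(pre)
  list(p = clamp_prob(as.vector(sigmoid(Hd %*% params$Wd2 + params$bd2))),
       Hd = Hd, pre = pre)
}

# Full forward through both GCN layers and fusion for one domain.
gda_forward_domain <- function(params, ds) {
  XW <- ds$X %*% params$W1
  pre1a <- add_bias(ds$S %*% XW, params$b1)
  pre1p <- add_bias(ds$Sp %*% XW, params$b1)
  H1a <- relu(pre1a)
  H1p <- relu(pre1p)
  Za <- add_bias(ds$S %*% (H1a %*% params$W2), params$b2)
  Zp <- add_bias(ds$Sp %*% (H1p %*% params$W2), params$b2)
  att <- attention_forward(Za, Zp, params$WQ, params$WK, params$WV)
  list(Z = att$Z, att = att, pre1a = pre1a, pre1p = pre1p,
       H1a = H1a, H1p = H1p)
}

# Backward through fusion and both GCN layers for one domain; accumulates
# into the grads environment.
gda_backward_domain <- function(params, ds, fw, dZ, g) {
  ab <- attention_backward(fw$att, dZ, params$WQ, params$WK, params$WV)
  g$WQ <- g$WQ + ab$dWQ
  g$WK <- g$WK + ab$dWK
  g$WV <- g$WV + ab$dWV
  SdZa <- crossprod(ds$S, ab$dZa)    # S symmetric; crossprod for speed
  SpdZp <- crossprod(ds$Sp, ab$dZp)
  g$W2 <- g$W2 + crossprod(fw$H1a, SdZa) + crossprod(fw$H1p, SpdZp)
  g$b2 <- g$b2 + colSums(ab$dZa) + colSums(ab$dZp)
  dH1a <- tcrossprod(SdZa, params$W2) * (fw$pre1a > 0)
  dH1p <- tcrossprod(SpdZp, params$W2) * (fw$pre1p > 0)
  g$W1 <- g$W1 + crossprod(ds$X, crossprod(ds$S, dH1a) + crossprod(ds$Sp, dH1p))
  g$b1 <- g$b1 + colSums(dH1a) + colSums(dH1p)
  invisible(g)
}

# One full forward + loss + gradient evaluation over both domains.
# Returns loss components, fused features, posteriors, and gradients for
# every parameter. lambda enters the total loss (and hence the
# discriminator's own gradient); the sign-flipped gradient into the shared
# encoder is additionally scaled by grl_mult, the gradient reversal
# layer's internal multiplier (ramped during training for stability).
gda_forward_backward <- function(params, source, target, lambda,
                                 grl_mult = 1, compute_grads = TRUE) {
  fs <- gda_forward_domain(params, source)
  ft <- gda_forward_domain(params, target)
  n_s <- nrow(fs$Z)
  n_t <- nrow(ft$Z)
  C <- ncol(params$Wc)

  post <- classify(fs$Z, params)
  Y1 <- matrix(0, n_s, C)
  Y1[cbind(seq_len(n_s), source$labels + 1L)] <- 1
  l_cls <- -mean(log(clamp_prob(post)[Y1 == 1]))

  dc_s <- discriminate_cache(fs$Z, params)
  dc_t <- discriminate_cache(ft$Z, params)
  p_src_s <- dc_s$p
  p_src_t <- dc_t$p
  l_grl <- -mean(log(p_src_s)) - mean(log(1 - p_src_t))
  loss <- l_cls + lambda * l_grl

  out <- list(loss = loss, loss_cls = l_cls, loss_grl = l_grl,
              Z_S = fs$Z, Z_T = ft$Z, posteriors = post)
  if (!compute_grads) return(out)

  g <- new.env()
  for (nm in c("W1", "W2", "WQ", "WK", "WV", "Wc")) g[[nm]] <- params[[nm]] * 0
  g$b1 <- params$b1 * 0; g$b2 <- params$b2 * 0; g$bc <- params$bc * 0

  # classifier head (source only)
  dlog <- (post - Y1) / n_s
  g$Wc <- crossprod(fs$Z, dlog)
  g$bc <- colSums(dlog)
  dZ_S <- tcrossprod(dlog, params$Wc)

  # discriminator MLP; encoder receives the reversed gradient
  du_s <- matrix(-(1 - p_src_s) / n_s, ncol = 1)
  du_t <- matrix(p_src_t / n_t, ncol = 1)
  g$Wd2 <- lambda * (crossprod(dc_s$Hd, du_s) + crossprod(dc_t$Hd, du_t))
  g$bd2 <- lambda * (sum(du_s) + sum(du_t))
  dHd_s <- (du_s %*% t(params$Wd2)) * (dc_s$pre > 0)
  dHd_t <- (du_t %*% t(params$Wd2)) * (dc_t$pre > 0)
  g$Wd1 <- lambda * (crossprod(fs$Z, dHd_s) + crossprod(ft$Z, dHd_t))
  g$bd1 <- lambda * (colSums(dHd_s) + colSums(dHd_t))
  dZ_S <- dZ_S + grl_gradient(tcrossprod(dHd_s, params$Wd1), lambda * grl_mult)
  dZ_T <- grl_gradient(tcrossprod(dHd_t, params$Wd1), lambda * grl_mult)

  gda_backward_domain(params, source, fs, dZ_S, g)
  gda_backward_domain(params, target, ft, dZ_T, g)
  out$grads <- as.list(g)
  out
}
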