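# Stage 1: accessibility reconstruction. An MLP maps each peak's sequence
# embedding (d') through hidden layers 512-256-128 to a d = 128 code; a
# dense sigmoid head with one output unit per cell predicts the binary
# accessibility of the peak in every cell. After training, column j of the
# head weight matrix W_o is taken as the embedding of cell j: it is the
# direction in peak-code space along which peak accessibility in that cell
# is maximally predictable.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialise stage-1 embedder parameters
#'
#' The MLP body initialisation is drawn from a substream of `seed` that does
#' not depend on the number of cells, so source and target embedders started
#' from the same seed share their body init (their heads differ); the two
#' learned embedding spaces then start in comparable bases.
#'
#' @param d_in Input (sequence-embedding) dimension d'.
#' @param hidden Hidden widths; the last entry is the cell-embedding
#'   dimension d (default `c(512, 256, 128)`).
#' @param n_cell Number of cells (head width).
#' @param seed Integer seed.
#' @return An `embedder_params` list with `W`, `b` (per layer), `W_o`, `b_o`.
#' @export
init_embedder_params <- function(d_in, hidden = c(512, 256, 128), n_cell, seed = 0) {
  dims <- c(d_in, hidden)
  body <- with_substream(seed, "embedder-body-init", {
    lapply(seq_len(length(dims) - 1), function(l) glorot(dims[l], dims[l + 1]))
  })
  W_o <- with_substream(seed, "embedder-head-init", glorot(dims[length(dims)], n_cell))
  structure(list(W = body, b = lapply(hidden, function(h) numeric(h)),
                 W_o = W_o, b_o = numeric(n_cell), hidden = hidden),
            class = "embedder_params")
}

embedder_hidden_forward <- function(params, Z0) {
  H <- Z0
  pre <- vector("list", length(params$W))
  for (l in seq_along(params$W)) {
    pre[[l]] <- add_bias(H %*% params$W[[l]], params$b[[l]])
    H <- if (l < length(params$W)) relu(pre[[l]]) else pre[[l]]
  }
  list(H = H, pre = pre)
}

#' Predicted accessibility from peak codes
#'
#' `Yhat = sigmoid(Z_hidden %*% W_o + b_o)`: the element `(i, j)` is the
#' predicted probability that peak `i` is accessible in cell `j`.
#'
#' @param Z_hidden Peak codes, `N_p x d`.
#' @param params `embedder_params` (uses `W_o`, `b_o`).
#' @return Matrix in `(0, 1)`, `N_p x N_cell`.
#' @export
forward_accessibility <- function(Z_hidden, params) {
  if (any(!is.finite(Z_hidden))) stop_gda("non-finite peak codes")
  sigmoid(add_bias(Z_hidden %*% params$W_o, params$b_o))
}

#' Mean binary cross-entropy between predicted and observed accessibility
#'
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logs, since
#' the loss is undefined at exactly 0 or 1.
#'
#' @param Yhat Predicted probabilities.
#' @param Y Observed 0/1 matrix (dense or sparse), same shape.
#' @return Scalar loss, `>= 0`.
#' @export
bce_loss <- function(Yhat, Y) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (!all(dim(Yhat) == dim(Y))) stop_gda("shape mismatch in bce_loss")
  p <- clamp_prob(Yhat)
  -mean(Y * log(p) + (1 - Y) * log(1 - p))
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the stage-1 cell embedder
#'
#' Minimises the binary cross-entropy between predicted and observed
#' accessibility by Adam, minibatching over peaks (all cells per batch).
#' Training is fully seeded: the same inputs and seed give bit-identical
#' parameters.
#'
#' @param peak_emb `peak_embedding` from [encode_peaks()].
#' @param acc `accessibility_matrix`, peak rows aligned with `peak_emb`.
#' @param hidden MLP widths (default `c(512, 256, 128)`).
#' @param lr Learning rate (default 1e-3).
#' @param epochs Training epochs (default 400).
#' @param batch_size Peaks per minibatch (default 256).
#' @param seed Integer seed.
#' @return A `cell_embedder`: `params`, per-epoch `history` of the loss
#'   (minibatch-weighted mean), plus bookkeeping fields.
#' @export
train_cell_embedder <- function(peak_emb, acc, hidden = c(512, 256, 128),
                                lr = 1e-3, epochs = 400, batch_size = 256,
                                seed = 0) {
  stopifnot(inherits(peak_emb, "peak_embedding"),
            inherits(acc, "accessibility_matrix"))
  if (!identical(peak_emb$peak_ids, acc$peak_ids)) {
    stop_gda("peak order differs between embeddings and accessibility matrix")
  }
  Z0 <- peak_emb$values
  n_p <- nrow(Z0)
  n_cell <- ncol(acc$values)
  params <- init_embedder_params(ncol(Z0), hidden, n_cell, seed)
  opt <- adam_init(params_flat(params))
  t <- 0
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    perm <- with_substream(seed, paste0("epoch-", epoch), sample.int(n_p))
    starts <- seq(1, n_p, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n_p)]
      Zb <- Z0[idx, , drop = FALSE]
      Yb <- as.matrix(acc$values[idx, , drop = FALSE])
      fw <- embedder_hidden_forward(params, Zb)
      logits <- add_bias(fw$H %*% params$W_o, params$b_o)
      Yhat <- sigmoid(logits)
      loss <- bce_loss(Yhat, Yb)
      if (!is.finite(loss)) {
        stop_gda("NaN/Inf loss at epoch ", epoch, "; last finite epoch loss: ",
                 if (epoch > 1) history[epoch - 1] else NA)
      }
      ep_loss <- ep_loss + loss * length(idx)
      grads <- embedder_backward(params, fw, Zb, Yhat, Yb)
      t <- t + 1
      upd <- adam_update_all(params_flat(params), grads, opt, lr, t)
      opt <- upd$opt
      params <- params_unflat(upd$params, params)
    }
    history[epoch] <- ep_loss / n_p
  }
  structure(list(params = params, history = history,
                 cell_barcodes = acc$cell_barcodes, d = utils::tail(hidden, 1),
                 encoder_name = peak_emb$encoder_name, seed = seed),
            class = "cell_embedder")
}

embedder_backward <- function(params, fw, Zb, Yhat, Yb) {
  n_b <- nrow(Zb)
  dlogits <- (Yhat - Yb) / length(Yhat)
  g <- list()
  g$W_o <- crossprod(fw$H, dlogits)
  g$b_o <- colSums(dlogits)
  dH <- tcrossprod(dlogits, params$W_o)
  L <- length(params$W)
  for (l in rev(seq_len(L))) {
    if (l < L) dH <- dH * (fw$pre[[l]] > 0)
    Hin <- if (l == 1) Zb else {
      if (l - 1 < L) relu(fw$pre[[l - 1]]) else fw$pre[[l - 1]]
    }
    g[[paste0("W", l)]] <- crossprod(Hin, dH)
    g[[paste0("b", l)]] <- colSums(dH)
    if (l > 1) dH <- tcrossprod(dH, params$W[[l]])
  }
  g
}

params_flat <- function(params) {
  out <- list(W_o = params$W_o, b_o = params$b_o)
  for (l in seq_along(params$W)) {
    out[[paste0("W", l)]] <- params$W[[l]]
    out[[paste0("b", l)]] <- params$b[[l]]
  }
  out
}

params_unflat <- function(flat, template) {
  template$W_o <- flat$W_o
  template$b_o <- flat$b_o
  for (l in seq_along(template$W)) {
    template$W[[l]] <- flat[[paste0("W", l)]]
    template$b[[l]] <- flat[[paste0("b", l)]]
  }
  template
}

adam_update_all <- function(flat, grads, opt, lr, t) {
  for (nm in names(flat)) {
    if (is.null(grads[[nm]])) next
    res <- adam_step(flat[[nm]], grads[[nm]], opt[[nm]], lr, t)
    flat[[nm]] <- res$p
    opt[[nm]] <- res$st
  }
  list(params = flat, opt = opt)
}

#' Extract cell embeddings from a trained embedder
#'
#' Row `j` of the result is column `j` of the head weight matrix `W_o`.
#'
#' @param embedder A `cell_embedder` (or raw `embedder_params`).
#' @param barcodes Cell barcodes; length must equal the head width.
#' @param domain Optional domain tag stored on the result.
#' @return A `cell_embedding`: `values` (`N_cell x d`), `cell_barcodes`,
#'   `domain`.
#' @export
extract_cell_embeddings <- function(embedder, barcodes = NULL, domain = NA_character_) {
  params <- if (inherits(embedder, "cell_embedder")) embedder$params else embedder
  barcodes <- barcodes %||%
    (if (inherits(embedder, "cell_embedder")) embedder$cell_barcodes else NULL)
  if (is.null(barcodes) || length(barcodes) != ncol(params$W_o)) {
    stop_gda("barcode count does not match the number of head columns")
  }
  structure(list(values = t(params$W_o), cell_barcodes = barcodes,
                 domain = domain),
            class = "cell_embedding")
}

#' @export
print.cell_embedder <- function(x, ...) {
  cat("cell_embedder: d =", x$d, ",", length(x$cell_barcodes), "cells,",
      length(x$history), "epochs; final loss",
      format(utils::tail(x$history, 1), digits = 4), "\n")
  invisible(x)
}
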