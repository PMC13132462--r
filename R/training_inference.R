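# Stage 2: joint adversarial training over both cell graphs, prediction on
# target cells, and evaluation.

#' Stage-2 training configuration
#'
#' @param lr Learning rate (default 3e-3).
#' @param epochs Training epochs (default 100; dataset-dependent in
#'   practice).
#' @param lambda Adversarial weight in the composite loss
#'   `L = L_cls + lambda * L_grl` (default 1.0; the useful band is roughly
#'   0.9-1.1 — too large an adversarial signal suppresses the class
#'   objective).
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 3e-3, epochs = 100, lambda = 1.0, seed = 0) {
  stopifnot(lr > 0, epochs >= 0, lambda >= 0)
  structure(list(lr = lr, epochs = as.integer(epochs), lambda = lambda,
                 seed = as.integer(seed)), class = "train_config")
}

#' Source-classification loss
#'
#' Average multi-class negative log-likelihood of the true source labels
#' under the predicted posteriors, with probability clamping at 1e-7.
#'
#' @param posteriors Matrix, source cells x classes, rows summing to 1.
#' @param labels Integer labels in `0..C-1`.
#' @return Scalar loss.
#' @export
cls_loss <- function(posteriors, labels) {
  posteriors <- as.matrix(posteriors)
  if (any(labels < 0 | labels >= ncol(posteriors))) stop_gda("label out of range")
  p <- clamp_prob(posteriors[cbind(seq_len(nrow(posteriors)), labels + 1L)])
  -mean(log(p))
}

#' Domain-adversarial loss
#'
#' Binary cross-entropy of the domain discriminator over both domains:
#' `-mean(log p_source(source)) - mean(log(1 - p_source(target)))`, where
#' the probability a node is "target" is one minus its "source"
#' probability.
#'
#' @param p_source_on_source Discriminator outputs on source nodes.
#' @param p_source_on_target Discriminator outputs on target nodes.
#' @return Scalar loss.
#' @export
domain_loss <- function(p_source_on_source, p_source_on_target) {
  -mean(log(clamp_prob(p_source_on_source))) -
    mean(log(clamp_prob(1 - p_source_on_target)))
}

#' Composite training loss
#' @param cls Classification loss.
#' @param grl Domain-adversarial loss.
#' @param lambda Balance between the two terms.
#' @return `cls + lambda * grl`.
#' @export
total_loss <- function(cls, grl, lambda) {
  stopifnot(is.finite(cls), is.finite(grl))
  cls + lambda * grl
}

#' Train the graph-domain-adaptation annotator
#'
#' Full-batch joint training: every epoch, both graphs are passed through
#' the shared dual-channel network, the composite loss is evaluated, and
#' one Adam step is taken. The discriminator pushes fused features toward
#' domain invariance through the gradient reversal layer while the
#' classifier fits the source labels.
#'
#' The reversed gradient reaching the shared encoder is scaled by the
#' gradient-reversal layer's internal multiplier. With
#' `grl_schedule = "ramp"` (default) the multiplier follows the warm-up
#' `grl_cap * (2 / (1 + exp(-10 p)) - 1)` in training progress `p`: the
#' classifier shapes class structure before the adversarial signal reaches
#' its ceiling, and the ceiling `grl_cap` keeps the minimax game from
#' inverting the discriminator on small graphs. `"constant"` fixes the
#' multiplier at 1 throughout. `lambda` always weights the adversarial term
#' in the reported loss and in the discriminator's own updates.
#'
#' @param source `domain_dataset` with labels.
#' @param target `domain_dataset` (labels unused and typically absent).
#' @param cfg A [train_config()].
#' @param hidden GCN widths, default `c(100, 16)`.
#' @param grl_schedule `"ramp"` (default) or `"constant"` reversal
#'   multiplier.
#' @param grl_cap Ceiling of the ramped reversal multiplier (default 0.02).
#' @param disc_hidden Discriminator hidden width (default 40).
#' @return A `gda_model`: `params`, `classes`, `history` (data frame with
#'   per-epoch `loss_cls`, `loss_grl`, `loss`), `config`.
#' @export
train_gda <- function(source, target, cfg = train_config(), hidden = c(100, 16),
                      grl_schedule = c("ramp", "constant"), grl_cap = 0.02,
                      disc_hidden = 40) {
  grl_schedule <- match.arg(grl_schedule)
  stopifnot(inherits(source, "domain_dataset"), inherits(target, "domain_dataset"))
  if (is.null(source$labels)) stop_gda("source domain must carry labels")
  if (ncol(source$X) != ncol(target$X)) stop_gda("feature widths differ between domains")
  C <- length(source$classes)
  params <- init_gda_params(ncol(source$X), hidden, C, disc_hidden = disc_hidden,
                            seed = cfg$seed)
  flat_names <- c("W1", "b1", "W2", "b2", "WQ", "WK", "WV", "Wc", "bc",
                  "Wd1", "bd1", "Wd2", "bd2")
  opt <- adam_init(params[flat_names])
  history <- data.frame(epoch = integer(0), loss_cls = numeric(0),
                        loss_grl = numeric(0), loss = numeric(0))
  best <- params
  for (epoch in seq_len(cfg$epochs)) {
    mult <- if (grl_schedule == "ramp") {
      grl_cap * (2 / (1 + exp(-10 * epoch / cfg$epochs)) - 1)
    } else 1
    ev <- gda_forward_backward(params, source, target, cfg$lambda, grl_mult = mult)
    if (!is.finite(ev$loss)) {
      warning("non-finite loss at epoch ", epoch, "; returning last good parameters")
      params <- best
      break
    }
    best <- params
    history <- rbind(history, data.frame(epoch = epoch, loss_cls = ev$loss_cls,
                                         loss_grl = ev$loss_grl, loss = ev$loss))
    flat <- params[flat_names]
    upd <- adam_update_all(flat, ev$grads, opt, cfg$lr, epoch)
    opt <- upd$opt
    params[flat_names] <- upd$params
  }
  structure(list(params = params, classes = source$classes, history = history,
                 config = cfg, hidden = hidden),
            class = "gda_model")
}

#' @export
print.gda_model <- function(x, ...) {
  cat("gda_model:", length(x$classes), "classes, lambda =", x$config$lambda,
      ",", nrow(x$history), "epochs")
  if (nrow(x$history)) cat("; final loss", format(utils::tail(x$history$loss, 1),
                                                  digits = 4))
  cat("\n")
  invisible(x)
}

#' Predict cell types for target cells
#'
#' Forward pass of the trained model on the target graph; labels are the
#' posterior argmax, ties broken toward the lowest class index.
#'
#' @param object Trained `gda_model`.
#' @param target `domain_dataset` for the target domain.
#' @param ... Unused.
#' @return List with `labels` (character), `posteriors` (cells x classes),
#'   `barcodes`.
#' @export
predict.gda_model <- function(object, target, ...) {
  fw <- gda_forward_domain(object$params, target)
  post <- classify(fw$Z, object$params)
  colnames(post) <- object$classes
  idx <- apply(post, 1L, which.max)  # which.max takes the first (lowest) index on ties
  list(labels = object$classes[idx], posteriors = post,
       barcodes = target$barcodes)
}

#' k-nearest-neighbour label transfer baseline
#'
#' Assigns each target cell the majority label among its `k` nearest source
#' cells in the embedding space (majority ties broken toward the lowest
#' class index). This is the non-adaptive baseline the graph
#' domain-adaptation stage is compared against.
#'
#' @param source_emb,target_emb `cell_embedding`s (or matrices).
#' @param source_labels `label_table` for the source cells.
#' @param k Neighbours (default 6).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return Character vector of predicted target labels.
#' @export
knn_label_transfer <- function(source_emb, target_emb, source_labels, k = 6,
                               metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  Xs <- if (inherits(source_emb, "cell_embedding")) source_emb$values else source_emb
  Xt <- if (inherits(target_emb, "cell_embedding")) target_emb$values else target_emb
  bcs <- if (inherits(source_emb, "cell_embedding")) source_emb$cell_barcodes else
    rownames(Xs) %||% as.character(seq_len(nrow(Xs)))
  classes <- attr(source_labels, "classes")
  y <- match(source_labels$label[match(bcs, source_labels$barcode)], classes)
  if (anyNA(y)) stop_gda("labels missing for some source barcodes")
  if (metric == "cosine") {
    prox <- tcrossprod(Xt / sqrt(rowSums(Xt^2)), Xs / sqrt(rowSums(Xs^2)))
  } else {
    prox <- -outer(rowSums(Xt^2), rowSums(Xs^2), "+") + 2 * tcrossprod(Xt, Xs)
  }
  vapply(seq_len(nrow(Xt)), function(i) {
    ord <- order(-prox[i, ], seq_len(ncol(prox)), method = "radix")
    votes <- tabulate(y[ord[seq_len(k)]], nbins = length(classes))
    classes[which.max(votes)]
  }, character(1))
}

#' Evaluate predicted annotations against held-out truth
#'
#' @param predicted Character vector of predicted class names.
#' @param truth Character vector of true class names (subset of `classes`).
#' @param classes Source class set; per-class scores and the macro average
#'   run over exactly these classes. A class absent from both vectors gets
#'   F1 = 0 and still enters the macro mean.
#' @return An `eval_report`: `accuracy`, `macro_f1`, `per_class` (precision,
#'   recall, F1), `confusion` (rows = truth, columns = predicted).
#' @export
evaluate_annotation <- function(predicted, truth, classes = NULL) {
  classes <- classes %||% sort(unique(c(predicted, truth)))
  if (!all(truth %in% classes)) stop_gda("truth contains a class outside the source set")
  if (length(predicted) != length(truth)) stop_gda("length mismatch")
  pf <- factor(predicted, levels = classes)
  tf <- factor(truth, levels = classes)
  confusion <- table(truth = tf, predicted = pf)
  acc <- mean(predicted == truth)
  per_class <- t(vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  structure(list(accuracy = acc, macro_f1 = mean(per_class[, "f1"]),
                 per_class = per_class, confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, macro-F1 %.4f over %d classes\n",
              x$accuracy, x$macro_f1, nrow(x$per_class)))
  invisible(x)
}
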