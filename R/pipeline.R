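# End-to-end convenience layer: default configuration, YAML loading, and
# the full two-stage annotation pipeline.

#' Default pipeline configuration
#'
#' Nested list of every tunable, in the same shape accepted from YAML via
#' [read_config()]: `encoder` (type/k), `stage1` (hidden widths, lr,
#' epochs, batch size), `graph` (k, metric), `ppmi` (walk length, walks per
#' node, mode), `model` (hidden dims, lambda), `train` (lr, epochs).
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    encoder = list(type = "kmer", k = 4),
    stage1 = list(hidden = c(512, 256, 128), lr = 1e-3, epochs = 400,
                  batch_size = 256, mode = "joint"),
    graph = list(k = 6, metric = "cosine"),
    ppmi = list(walk_length = 3, walks_per_node = 1000, mode = "closed_form"),
    model = list(hidden_dims = c(100, 16), lambda = 1.0),
    train = list(lr = 3e-3, epochs = 100)
  )
}

#' Read a YAML pipeline configuration
#'
#' Keys missing from the file keep their [default_config()] values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    for (key in names(user[[section]])) {
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

config_encoder <- function(cfg) {
  if (identical(cfg$encoder$type, "kmer")) {
    kmer_encoder(cfg$encoder$k %||% 4)
  } else {
    stop_gda("encoder type '", cfg$encoder$type, "' requires the external ",
             "DNA language-model adapter; see ?llm_adapter_tokenize")
  }
}

#' Annotate target cells from a labeled source domain
#'
#' Runs the full two-stage pipeline on in-memory objects: encode the shared
#' peak sequences, train one accessibility-reconstruction embedder per
#' domain (same seed, so the bodies share their initialisation), build the
#' kNN/PPMI graphs, train the adversarial graph-domain-adaptation model,
#' and predict target cell types. Target labels are never consulted.
#'
#' @param source_acc,target_acc `accessibility_matrix` per domain over a
#'   shared peak set (identical `peak_ids`).
#' @param source_labels `label_table` for the source cells.
#' @param peaks Data frame of shared peaks with sequences.
#' @param config Nested configuration (see [default_config()]).
#' @param seed Integer seed driving every stage.
#' @param verbose Print stage progress.
#' @return List: `predictions` (data frame barcode/predicted_label),
#'   `posteriors`, `model`, `embeddings` (source/target `cell_embedding`s),
#'   `datasets` (the two `domain_dataset`s), `classes`.
#' @export
annotate_cells <- function(source_acc, target_acc, source_labels, peaks,
                           config = default_config(), seed = 0,
                           verbose = FALSE) {
  if (!identical(source_acc$peak_ids, target_acc$peak_ids)) {
    stop_gda("source and target must share one peak set")
  }
  say <- function(...) if (verbose) message(...)
  say("encoding ", nrow(peaks), " peak sequences")
  pe <- encode_peaks(peaks, config_encoder(config))

  s1 <- config$stage1
  n_s <- ncol(source_acc$values)
  if (identical(s1$mode %||% "joint", "joint")) {
    # One reconstruction model over the cells of both domains: every cell
    # embedding is a column of the same output weight matrix, so the two
    # domains share one embedding basis and stage 2 only has to remove the
    # batch-effect shift, not recover an arbitrary rotation.
    say("stage 1: joint embedder (", n_s, " + ", ncol(target_acc$values), " cells)")
    acc_all <- accessibility_matrix(
      cbind(source_acc$values, target_acc$values), source_acc$peak_ids,
      c(source_acc$cell_barcodes, target_acc$cell_barcodes))
    emb <- train_cell_embedder(pe, acc_all, hidden = s1$hidden, lr = s1$lr,
                               epochs = s1$epochs, batch_size = s1$batch_size,
                               seed = seed)
    ce_all <- extract_cell_embeddings(emb)
    ce_s <- structure(list(values = ce_all$values[seq_len(n_s), , drop = FALSE],
                           cell_barcodes = source_acc$cell_barcodes,
                           domain = "source"), class = "cell_embedding")
    ce_t <- structure(list(values = ce_all$values[-seq_len(n_s), , drop = FALSE],
                           cell_barcodes = target_acc$cell_barcodes,
                           domain = "target"), class = "cell_embedding")
  } else {
    say("stage 1: source embedder (", n_s, " cells)")
    emb_s <- train_cell_embedder(pe, source_acc, hidden = s1$hidden, lr = s1$lr,
                                 epochs = s1$epochs, batch_size = s1$batch_size,
                                 seed = seed)
    say("stage 1: target embedder (", ncol(target_acc$values), " cells)")
    emb_t <- train_cell_embedder(pe, target_acc, hidden = s1$hidden, lr = s1$lr,
                                 epochs = s1$epochs, batch_size = s1$batch_size,
                                 seed = seed)
    ce_s <- extract_cell_embeddings(emb_s, domain = "source")
    ce_t <- extract_cell_embeddings(emb_t, domain = "target")
  }

  say("building cell graphs and PPMI operators")
  ds_s <- domain_dataset(ce_s, labels = source_labels, k = config$graph$k,
                         metric = config$graph$metric,
                         L_walk = config$ppmi$walk_length,
                         walks_per_node = config$ppmi$walks_per_node,
                         ppmi_mode = config$ppmi$mode,
                         ppmi_seed = derive_seed(seed, "ppmi-source"),
                         domain = "source")
  ds_t <- domain_dataset(ce_t, k = config$graph$k, metric = config$graph$metric,
                         L_walk = config$ppmi$walk_length,
                         walks_per_node = config$ppmi$walks_per_node,
                         ppmi_mode = config$ppmi$mode,
                         ppmi_seed = derive_seed(seed, "ppmi-target"),
                         domain = "target")

  say("stage 2: adversarial graph domain adaptation")
  model <- train_gda(ds_s, ds_t,
                     cfg = train_config(lr = config$train$lr,
                                        epochs = config$train$epochs,
                                        lambda = config$model$lambda,
                                        seed = seed),
                     hidden = config$model$hidden_dims)
  pred <- predict(model, ds_t)
  list(predictions = data.frame(barcode = pred$barcodes,
                                predicted_label = pred$labels,
                                stringsAsFactors = FALSE),
       posteriors = pred$posteriors, model = model,
       embeddings = list(source = ce_s, target = ce_t),
       datasets = list(source = ds_s, target = ds_t),
       classes = model$classes)
}

#' Annotate from files on disk
#'
#' File-based wrapper around [annotate_cells()] reading MTX/BED/barcodes
#' per domain, a shared peak FASTA, and the source label TSV, and writing
#' the prediction TSV.
#'
#' @param source_dir,target_prefix,source_prefix Directory and file-name
#'   prefixes as written by [write_domain_pair()] (`source`, `target`).
#' @param out_path Prediction TSV output path (or `NULL` to skip writing).
#' @param config,seed,verbose Passed to [annotate_cells()].
#' @return The [annotate_cells()] result, invisibly when writing.
#' @export
annotate_from_files <- function(source_dir, source_prefix = "source",
                                target_prefix = "target", out_path = NULL,
                                config = default_config(), seed = 0,
                                verbose = FALSE) {
  rd <- function(prefix) {
    read_accessibility(file.path(source_dir, paste0(prefix, ".mtx")),
                       file.path(source_dir, paste0(prefix, "_peaks.bed")),
                       file.path(source_dir, paste0(prefix, "_barcodes.tsv")))
  }
  src <- rd(source_prefix)
  tgt <- rd(target_prefix)
  peaks <- read_peaks_bed(file.path(source_dir, paste0(source_prefix, "_peaks.bed")))
  fa <- read_peak_fasta(file.path(source_dir, "peaks.fa"))
  peaks$sequence <- fa$sequence[match(peaks$peak_id, fa$peak_id)]
  labels <- read_labels(file.path(source_dir, "source_labels.tsv"))
  res <- annotate_cells(src, tgt, labels, peaks, config = config, seed = seed,
                        verbose = verbose)
  if (!is.null(out_path)) {
    write_predictions(res$predictions$barcode, res$predictions$predicted_label,
                      res$posteriors, res$classes, out_path)
    return(invisible(res))
  }
  res
}
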