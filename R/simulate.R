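#' Configuration for the synthetic domain-pair generator
#'
#' The generator emulates a paired reference (source) / query (target)
#' scATAC-seq experiment over a shared peak set: each cell type owns a
#' disjoint block of marker peaks whose DNA sequences carry a planted
#' class-specific motif, cells are Bernoulli-accessible at rate `p_on` on
#' their own markers and `p_off` elsewhere, and the target domain is
#' perturbed by a platform-style batch effect of strength `beta`.
#'
#' Defaults describe the package's reference study condition: 600 peaks,
#' 300 cells per domain, 3 equally frequent cell types, 500 bp peaks, 15%
#' marker peaks per class, `p_on = 0.9`, `p_off = 0.05`, `beta = 0.5`.
#'
#' @param n_peaks Number of peaks (shared across domains).
#' @param n_cells_source,n_cells_target Cells per domain.
#' @param n_classes Number of cell types `C >= 2`.
#' @param peak_length Peak width in bp; must be at least the longest motif.
#' @param marker_fraction Fraction of all peaks assigned to each class as
#'   markers; `n_classes * marker_fraction <= 1`.
#' @param p_on Accessibility rate of a cell at its own class's marker peaks.
#' @param p_off Background accessibility rate; `0 <= p_off < p_on <= 1`.
#' @param beta Batch-effect strength in `[0, 1]`: a fraction `beta` of peaks
#'   has its per-class rates mixed toward a peak-specific Uniform(0,1)
#'   perturbation with weight `beta` in the target domain.
#' @param motifs Optional character vector of `n_classes` motifs over ACGT;
#'   when `NULL`, 8-mers are drawn from the seed.
#' @param class_props Class proportions summing to 1; default uniform.
#' @param seed Integer seed; all randomness flows from it through labelled
#'   substreams (sequences, accessibility, batch effect).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_peaks = 600, n_cells_source = 300, n_cells_target = 300,
                       n_classes = 3, peak_length = 500, marker_fraction = 0.15,
                       p_on = 0.9, p_off = 0.05, beta = 0.5, motifs = NULL,
                       class_props = NULL, seed = 0) {
  if (n_classes < 2) stop_gda("need n_classes >= 2")
  if (!(p_off >= 0 && p_off < p_on && p_on <= 1)) stop_gda("need 0 <= p_off < p_on <= 1")
  if (beta < 0 || beta > 1) stop_gda("beta must be in [0, 1]")
  class_props <- class_props %||% rep(1 / n_classes, n_classes)
  if (abs(sum(class_props) - 1) > 1e-8) stop_gda("class proportions must sum to 1")
  markers_per_class <- floor(n_peaks * marker_fraction)
  if (markers_per_class < 1) stop_gda("infeasible config: 0 marker peaks per class")
  if (markers_per_class * n_classes > n_peaks) {
    stop_gda("infeasible config: marker blocks exceed the peak set")
  }
  if (is.null(motifs)) {
    motifs <- with_substream(seed, "motifs", vapply(seq_len(n_classes), function(i) {
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    }, character(1)))
  }
  if (length(motifs) != n_classes) stop_gda("need one motif per class")
  if (max(nchar(motifs)) > peak_length) stop_gda("peak_length shorter than a motif")
  structure(list(n_peaks = n_peaks, n_cells_source = n_cells_source,
                 n_cells_target = n_cells_target, n_classes = n_classes,
                 peak_length = peak_length, marker_fraction = marker_fraction,
                 markers_per_class = markers_per_class, p_on = p_on,
                 p_off = p_off, beta = beta, motifs = motifs,
                 class_props = class_props, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# peaks x classes matrix of accessibility rates: p_on on a class's marker
# block, p_off elsewhere.
marker_rate_matrix <- function(cfg) {
  R <- matrix(cfg$p_off, cfg$n_peaks, cfg$n_classes)
  for (c in seq_len(cfg$n_classes)) {
    idx <- marker_block(cfg, c)
    R[idx, c] <- cfg$p_on
  }
  R
}

marker_block <- function(cfg, class) {
  ((class - 1) * cfg$markers_per_class + 1):(class * cfg$markers_per_class)
}

sample_binary <- function(rates_per_cell, n_peaks) {
  # rates_per_cell: peaks x cells matrix of Bernoulli rates
  m <- matrix(stats::runif(length(rates_per_cell)) < rates_per_cell,
              nrow = n_peaks)
  methods::as(Matrix::Matrix(m * 1, sparse = TRUE), "CsparseMatrix")
}

#' Simulate a paired source/target scATAC-seq domain
#'
#' Draws shared motif-structured peak sequences, class labels and binary
#' accessibility for both domains under one seed, applying the batch-effect
#' perturbation to the target domain only (see [sim_config()]). Target
#' labels are returned as a separate held-out truth table that the
#' annotation pipeline never reads.
#'
#' @param cfg A [sim_config()].
#' @return List with `peaks` (data frame incl. sequences), `source`
#'   (`acc`, `labels`), `target` (`acc`, `truth`), and `config`.
#' @export
simulate_domain_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_digits <- nchar(as.character(cfg$n_peaks))
  peaks <- data.frame(
    chrom = "chrS", start = (seq_len(cfg$n_peaks) - 1L) * (cfg$peak_length + 200L),
    end = (seq_len(cfg$n_peaks) - 1L) * (cfg$peak_length + 200L) + cfg$peak_length,
    peak_id = sprintf(paste0("peak_%0", n_digits, "d"), seq_len(cfg$n_peaks)),
    stringsAsFactors = FALSE)

  peaks$sequence <- with_substream(cfg$seed, "sequences", {
    seqs <- vapply(seq_len(cfg$n_peaks), function(i) random_dna(cfg$peak_length),
                   character(1))
    for (c in seq_len(cfg$n_classes)) {
      motif <- cfg$motifs[c]
      for (i in marker_block(cfg, c)) {
        off <- sample.int(cfg$peak_length - nchar(motif) + 1L, 1L)
        substr(seqs[i], off, off + nchar(motif) - 1L) <- motif
      }
    }
    seqs
  })

  R <- marker_rate_matrix(cfg)

  # target-domain rates: a fraction beta of peaks drifts toward a
  # peak-specific Uniform(0,1) rate with mixing weight beta
  R_target <- with_substream(cfg$seed, "batch-effect", {
    Rt <- R
    n_affected <- floor(cfg$beta * cfg$n_peaks)
    if (n_affected > 0) {
      affected <- sample.int(cfg$n_peaks, n_affected)
      pert <- stats::runif(n_affected)
      Rt[affected, ] <- (1 - cfg$beta) * R[affected, , drop = FALSE] + cfg$beta * pert
    }
    Rt
  })

  class_names <- paste0("type", LETTERS[seq_len(cfg$n_classes)])
  draw_domain <- function(n_cells, rates, stream) {
    with_substream(cfg$seed, stream, {
      cls <- sample.int(cfg$n_classes, n_cells, replace = TRUE,
                        prob = cfg$class_props)
      acc <- sample_binary(rates[, cls, drop = FALSE], cfg$n_peaks)
      list(cls = cls, acc = acc)
    })
  }
  src <- draw_domain(cfg$n_cells_source, R, "source-cells")
  tgt <- draw_domain(cfg$n_cells_target, R_target, "target-cells")

  src_bc <- sprintf("S_%04d", seq_len(cfg$n_cells_source))
  tgt_bc <- sprintf("T_%04d", seq_len(cfg$n_cells_target))
  list(
    peaks = peaks,
    source = list(
      acc = accessibility_matrix(src$acc, peaks$peak_id, src_bc),
      labels = label_table(src_bc, class_names[src$cls], classes = class_names)),
    target = list(
      acc = accessibility_matrix(tgt$acc, peaks$peak_id, tgt_bc),
      truth = label_table(tgt_bc, class_names[tgt$cls], classes = class_names)),
    config = cfg)
}

#' Write a simulated domain pair to disk
#'
#' Emits, per domain, MTX + BED + barcodes, plus a shared peak FASTA, the
#' source label TSV, and the target truth TSV (held out; the annotation
#' pipeline must never read it).
#'
#' @param sim Result of [simulate_domain_pair()].
#' @param out_dir Output directory.
#' @return Invisibly, a named vector of written paths.
#' @export
write_domain_pair <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_src <- write_accessibility(sim$source$acc, sim$peaks, out_dir, "source")
  p_tgt <- write_accessibility(sim$target$acc, sim$peaks, out_dir, "target")
  fa <- file.path(out_dir, "peaks.fa")
  write_peak_fasta(sim$peaks, fa)
  lab <- file.path(out_dir, "source_labels.tsv")
  write_labels(sim$source$labels, lab)
  truth <- file.path(out_dir, "target_truth_heldout.tsv")
  write_labels(sim$target$truth, truth)
  invisible(c(p_src, p_tgt, peaks_fasta = fa, source_labels = lab,
              target_truth = truth))
}

#' Content digest of a fixture's files
#'
#' Stable MD5-based digest over a set of files, used in regression tests of
#' seeded determinism. The digest of an empty file set is the MD5 of the
#' empty string.
#'
#' @param paths Character vector of file paths (all must exist), or a
#'   directory whose regular files are digested.
#' @return A 32-character hex digest string.
#' @export
checksum_fixture <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE, recursive = TRUE)
  }
  if (length(paths) == 0) return("d41d8cd98f00b204e9800998ecf8427e")
  if (!all(file.exists(paths))) {
    stop_gda("missing file(s): ", paste(paths[!file.exists(paths)], collapse = ", "))
  }
  sums <- tools::md5sum(sort(paths))
  listing <- paste0(basename(names(sums)), ":", unname(sums), collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(listing, tmp)
  unname(tools::md5sum(tmp))
}
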