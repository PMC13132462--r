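#' Read a binary peak-by-cell accessibility matrix
#'
#' Reads a Matrix Market count matrix together with its sidecar peak BED and
#' cell-barcode files, binarising on read: any nonzero count becomes 1, the
#' convention under which the accessibility-reconstruction loss is defined.
#'
#' @param matrix_path Matrix Market (`.mtx`) file, peaks in rows, cells in
#'   columns.
#' @param peaks_path BED file (>= 3 columns, 0-based half-open) with one row
#'   per matrix row; column 4, when present, is used as the peak identifier.
#' @param barcodes_path Text file with one cell barcode per line.
#' @return An `accessibility_matrix`: a list with `values` (sparse 0/1
#'   `dgCMatrix`), `peak_ids` and `cell_barcodes`, aligned to file order.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 1), dims = c(3, 2))
#' Matrix::writeMM(m, file.path(dir, "m.mtx"))
#' writeLines(c("chr1\t0\t100\tp1", "chr1\t200\t300\tp2", "chr1\t400\t500\tp3"),
#'            file.path(dir, "peaks.bed"))
#' writeLines(c("AAA", "CCC"), file.path(dir, "barcodes.tsv"))
#' acc <- read_accessibility(file.path(dir, "m.mtx"),
#'                           file.path(dir, "peaks.bed"),
#'                           file.path(dir, "barcodes.tsv"))
#' as.matrix(acc$values)
#' @export
read_accessibility <- function(matrix_path, peaks_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  peaks <- read_peaks_bed(peaks_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(peaks) != nrow(m)) {
    stop_gda("dimension mismatch: matrix has ", nrow(m), " rows but peaks file has ",
             nrow(peaks), " entries")
  }
  if (length(barcodes) != ncol(m)) {
    stop_gda("dimension mismatch: matrix has ", ncol(m), " columns but barcodes file has ",
             length(barcodes), " entries")
  }
  if (anyDuplicated(barcodes)) stop_gda("duplicate cell barcodes in ", barcodes_path)
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  if (length(m@x) && any(m@x %% 1 != 0)) {
    stop_gda("non-integer entries in accessibility matrix ", matrix_path)
  }
  accessibility_matrix(m, peaks$peak_id, barcodes)
}

#' Construct an accessibility matrix object
#'
#' Binarises `values` (nonzero -> 1) and checks alignment with the peak and
#' barcode vectors.
#'
#' @param values Matrix (dense or sparse) of counts or 0/1 indicators.
#' @param peak_ids Character vector, one id per row; must be unique.
#' @param cell_barcodes Character vector, one barcode per column; must be
#'   unique.
#' @return An object of class `accessibility_matrix`.
#' @export
accessibility_matrix <- function(values, peak_ids, cell_barcodes) {
  values <- methods::as(methods::as(values, "CsparseMatrix"), "dMatrix")
  values <- Matrix::drop0(values)
  if (length(values@x)) values@x <- rep(1, length(values@x))
  if (nrow(values) != length(peak_ids)) stop_gda("peak_ids length != matrix rows")
  if (ncol(values) != length(cell_barcodes)) stop_gda("cell_barcodes length != matrix columns")
  if (anyDuplicated(peak_ids)) stop_gda("peak ids must be unique")
  if (anyDuplicated(cell_barcodes)) stop_gda("cell barcodes must be unique")
  structure(list(values = values, peak_ids = as.character(peak_ids),
                 cell_barcodes = as.character(cell_barcodes)),
            class = "accessibility_matrix")
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat("accessibility_matrix:", nrow(x$values), "peaks x", ncol(x$values), "cells;",
      format(Matrix::nnzero(x$values)), "accessible entries\n")
  invisible(x)
}

#' Write an accessibility matrix as MTX + BED + barcodes
#'
#' Inverse of [read_accessibility()]; a read/write/read round trip is the
#' identity on values, peak ids and barcodes.
#'
#' @param acc An `accessibility_matrix`.
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   row-aligned to `acc`. When `NULL`, a placeholder BED on contig `chrUn`
#'   is written so the sidecar stays structurally valid.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_accessibility <- function(acc, peaks = NULL, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(peaks)) {
    n <- length(acc$peak_ids)
    peaks <- data.frame(chrom = "chrUn", start = (seq_len(n) - 1L) * 1000L,
                        end = (seq_len(n) - 1L) * 1000L + 500L,
                        peak_id = acc$peak_ids)
  }
  stopifnot(nrow(peaks) == nrow(acc$values))
  paths <- c(matrix = file.path(dir, paste0(prefix, ".mtx")),
             peaks = file.path(dir, paste0(prefix, "_peaks.bed")),
             barcodes = file.path(dir, paste0(prefix, "_barcodes.tsv")))
  Matrix::writeMM(acc$values, paths[["matrix"]])
  write_peaks_bed(peaks, paths[["peaks"]])
  writeLines(acc$cell_barcodes, paths[["barcodes"]])
  invisible(paths)
}

#' Read peaks from a BED file
#'
#' @param path BED file, 0-based half-open coordinates, >= 3 columns.
#' @return Data frame with `chrom`, `start`, `end`, `peak_id` (column 4 when
#'   present, otherwise `chrom:start-end`).
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3) stop_gda("BED file ", path, " has fewer than 3 columns")
  out <- data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  out$peak_id <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    paste0(out$chrom, ":", out$start, "-", out$end)
  if (any(out$end <= out$start)) stop_gda("BED interval with end <= start in ", path)
  if (anyDuplicated(out$peak_id)) stop_gda("duplicate peak ids in ", path)
  out
}

#' Write peaks to a BED file
#' @param peaks Data frame with `chrom`, `start`, `end`, `peak_id`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract peak DNA sequences from a genome FASTA
#'
#' Slices the forward strand over `[start, end)` (BED semantics) and
#' upper-cases the result; scATAC peaks are unstranded so no
#' reverse-complementing is performed.
#'
#' @param peaks Data frame of peaks (`chrom`, `start`, `end`, `peak_id`).
#' @param genome_fasta_path FASTA file containing every referenced contig.
#' @return `peaks` with a `sequence` column added.
#' @export
extract_peak_sequences <- function(peaks, genome_fasta_path) {
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    stop_gda("contig(s) not found in ", genome_fasta_path, ": ",
             paste(missing, collapse = ", "))
  }
  widths <- stats::setNames(Biostrings::width(genome), names(genome))
  bad <- peaks$start < 0 | peaks$end > widths[peaks$chrom]
  if (any(bad)) {
    stop_gda("peak(s) out of contig bounds: ",
             paste(peaks$peak_id[bad], collapse = ", "))
  }
  peaks$sequence <- toupper(as.character(Biostrings::subseq(
    genome[peaks$chrom], start = peaks$start + 1L, end = peaks$end)))
  peaks
}

#' Write peak sequences as FASTA
#' @param peaks Data frame with `peak_id` and `sequence`.
#' @param path Output FASTA path.
#' @export
write_peak_fasta <- function(peaks, path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(peaks$sequence, peaks$peak_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read peak sequences from FASTA
#' @param path FASTA of peak sequences, names = peak ids.
#' @return Data frame with `peak_id` and `sequence`.
#' @export
read_peak_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(peak_id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read a cell-type label table
#'
#' @param path TSV with header columns `barcode` and `label`.
#' @return A `label_table`: data frame plus a `classes` attribute giving the
#'   class-index bijection (sorted unique class names, indices `0..C-1`).
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  label_table(tab$barcode, tab$label)
}

#' Construct a label table
#' @param barcodes Character vector of cell barcodes (unique).
#' @param labels Character vector of class names, same length.
#' @param classes Optional class ordering; defaults to sorted unique labels.
#' @return A `label_table` data frame with a `classes` attribute.
#' @export
label_table <- function(barcodes, labels, classes = NULL) {
  if (length(barcodes) != length(labels)) stop_gda("barcodes/labels length mismatch")
  if (anyDuplicated(barcodes)) stop_gda("a barcode appears in more than one label row")
  classes <- classes %||% sort(unique(as.character(labels)))
  if (length(classes) < 2) stop_gda("need at least 2 classes")
  if (!all(labels %in% classes)) stop_gda("label outside the declared class set")
  structure(data.frame(barcode = as.character(barcodes),
                       label = as.character(labels), stringsAsFactors = FALSE),
            classes = classes, class = c("label_table", "data.frame"))
}

#' Write a label table
#' @param lab A `label_table` (or data frame with `barcode`, `label`).
#' @param path Output TSV path.
#' @export
write_labels <- function(lab, path) {
  utils::write.table(as.data.frame(lab)[, c("barcode", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target-cell predictions
#'
#' One row per target cell: barcode, predicted label, then one posterior
#' column per class in class-index order. Ties in the posterior are broken
#' toward the lowest class index, so output is deterministic.
#'
#' @param barcodes Target cell barcodes.
#' @param predicted_classes Character vector of predicted class names.
#' @param posterior_rows Matrix, cells x classes, rows summing to 1 (1e-6).
#' @param classes Class names in index order (posterior column order).
#' @param out_path Output TSV path.
#' @export
write_predictions <- function(barcodes, predicted_classes, posterior_rows,
                              classes, out_path) {
  posterior_rows <- as.matrix(posterior_rows)
  if (length(barcodes) != length(predicted_classes) ||
      length(barcodes) != nrow(posterior_rows)) {
    stop_gda("barcodes, predictions and posterior rows must have equal length")
  }
  if (ncol(posterior_rows) != length(classes)) stop_gda("posterior columns != classes")
  if (nrow(posterior_rows) > 0 &&
      any(abs(rowSums(posterior_rows) - 1) > 1e-6)) {
    stop_gda("posterior rows must sum to 1")
  }
  df <- data.frame(barcode = barcodes, predicted_label = predicted_classes,
                   stringsAsFactors = FALSE)
  post <- as.data.frame(posterior_rows)
  names(post) <- paste0("p_", classes)
  utils::write.table(cbind(df, post), out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}

#' Write a cell or peak embedding matrix as TSV
#' @param emb Numeric matrix, one row per entity.
#' @param ids Row identifiers (barcodes or peak ids).
#' @param path Output TSV path.
#' @export
write_embedding_tsv <- function(emb, ids, path) {
  stopifnot(length(ids) == nrow(emb))
  df <- data.frame(id = ids, as.data.frame(emb), stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("e", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding_tsv()]
#' @param path TSV path.
#' @return List with `ids` and numeric matrix `values`.
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  list(ids = as.character(df$id),
       values = as.matrix(df[, -1, drop = FALSE]))
}
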