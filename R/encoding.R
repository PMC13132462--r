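#' Clean a raw peak DNA sequence
#'
#' Upper-cases the sequence and removes every non-canonical symbol (anything
#' outside A/C/G/T, including N). Removal rather than replacement keeps the
#' operation deterministic.
#'
#' @param raw Nonempty character scalar.
#' @return Cleaned sequence over `{A,C,G,T}`.
#' @export
clean_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || !nzchar(raw)) {
    stop_gda("raw sequence must be a nonempty string")
  }
  out <- gsub("[^ACGT]", "", toupper(raw))
  if (!nzchar(out)) {
    stop_gda("degenerate sequence: nothing left after removing non-ACGT symbols")
  }
  out
}

#' L1-normalised k-mer spectrum of a sequence
#'
#' Counts the `4^k` canonical k-mers in lexicographic order (A < C < G < T)
#' over all sliding windows and normalises to sum 1. This is the package's
#' built-in deterministic sequence encoder; an external DNA language model
#' can be plugged in through the [sequence_encoder()] contract instead.
#'
#' @param seq Clean sequence (see [clean_sequence()]).
#' @param k k-mer size, `1 <= k <= 6`; `nchar(seq) >= k`.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
kmer_encode <- function(seq, k = 4) {
  if (k < 1 || k > 6) stop_gda("k must be in 1..6")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ids <- match(chars, c("A", "C", "G", "T")) - 1L
  if (anyNA(ids)) stop_gda("sequence contains non-ACGT symbols; clean it first")
  n <- length(ids)
  if (n < k) stop_gda("sequence shorter than k")
  nwin <- n - k + 1L
  code <- integer(nwin)
  for (j in seq_len(k)) code <- code * 4L + ids[j:(j + nwin - 1L)]
  counts <- tabulate(code + 1L, nbins = 4L^k)
  stats::setNames(counts / sum(counts), all_kmers(k))
}

all_kmers <- function(k) {
  base <- c("A", "C", "G", "T")
  out <- base
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, base, paste0)))
    }
  }
  out
}

#' Sequence-encoder contract
#'
#' An encoder is a deterministic pure function from a clean sequence to a
#' fixed-length real vector, independent of sequence length.
#'
#' @param name Encoder name (recorded in embedding objects).
#' @param d Output dimension.
#' @param encode Function `character(1) -> numeric(d)`.
#' @return A `sequence_encoder` object.
#' @export
sequence_encoder <- function(name, d, encode) {
  stopifnot(is.function(encode), d >= 1)
  structure(list(name = name, d = as.integer(d), encode = encode),
            class = "sequence_encoder")
}

#' Built-in k-mer encoder
#' @param k k-mer size (default 4, giving dimension 256).
#' @return A `sequence_encoder`.
#' @export
kmer_encoder <- function(k = 4) {
  force(k)
  sequence_encoder(paste0("kmer", k), 4^k, function(s) kmer_encode(s, k))
}

#' Encode peak sequences into an embedding matrix
#'
#' Cleans each sequence and applies the encoder; row order follows the
#' input peak order, matching the accessibility matrix.
#'
#' @param peaks Data frame with `peak_id` and `sequence`.
#' @param encoder A [sequence_encoder()]; default k-mer encoder with k = 4.
#' @return A `peak_embedding` list: `values` (`N_p x d` matrix), `peak_ids`,
#'   `encoder_name`, `d`.
#' @export
encode_peaks <- function(peaks, encoder = kmer_encoder(4)) {
  stopifnot(inherits(encoder, "sequence_encoder"))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    v <- tryCatch(encoder$encode(clean_sequence(peaks$sequence[i])),
                  error = function(e) {
                    stop_gda("peak ", peaks$peak_id[i], ": ", conditionMessage(e))
                  })
    if (length(v) != encoder$d || any(!is.finite(v))) {
      stop_gda("peak ", peaks$peak_id[i], ": encoder returned an invalid vector")
    }
    v
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- NULL
  structure(list(values = values, peak_ids = peaks$peak_id,
                 encoder_name = encoder$name, d = encoder$d),
            class = "peak_embedding")
}

#' Tokenize a sequence for an external DNA language model
#'
#' Adapter entry point for a pretrained transformer encoder: segments a
#' clean sequence with a user-supplied subword vocabulary (greedy
#' longest-match against the vocabulary, the deterministic decoding of a
#' BPE/SentencePiece model's merged token set) and appends the start (CLS)
#' and end/separator (SEP) special ids the transformer expects. The
#' external model's weights are never bundled; when no vocabulary is
#' supplied the call fails with an actionable error rather than silently
#' falling back to the built-in encoder.
#'
#' @param seq Clean sequence.
#' @param vocab List with `tokens` (named integer vector: token string ->
#'   id), `cls_id`, `sep_id`, exported from the external tokenizer.
#' @param max_len Optional maximum total length including special tokens.
#' @return Integer vector of token ids, starting with `cls_id` and ending
#'   with `sep_id`.
#' @export
llm_adapter_tokenize <- function(seq, vocab = NULL, max_len = NULL) {
  if (is.null(vocab)) {
    stop_gda("external DNA language-model adapter is not configured: supply ",
             "`vocab` (list with `tokens`, `cls_id`, `sep_id`) exported from ",
             "the pretrained tokenizer; the built-in k-mer encoder is selected ",
             "with encoder type 'kmer' instead")
  }
  stopifnot(is.integer(vocab$tokens) || is.numeric(vocab$tokens),
            !is.null(names(vocab$tokens)))
  toks <- names(vocab$tokens)
  body <- integer(0)
  i <- 1L
  n <- nchar(seq)
  max_tok <- max(nchar(toks))
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(max_tok, n - i + 1L), 1L)) {
      cand <- substr(seq, i, i + len - 1L)
      if (cand %in% toks) {
        hit <- cand
        break
      }
    }
    if (is.null(hit)) stop_gda("no vocabulary token matches at position ", i)
    body <- c(body, as.integer(vocab$tokens[[hit]]))
    i <- i + nchar(hit)
  }
  if (!is.null(max_len)) body <- utils::head(body, max(0L, max_len - 2L))
  if (length(body) == 0) stop_gda("empty token body after truncation")
  c(as.integer(vocab$cls_id), body, as.integer(vocab$sep_id))
}
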