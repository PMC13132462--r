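# Internal numeric and RNG helpers shared across modules.

EPS_PROB <- 1e-7

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clamp_prob <- function(p, eps = EPS_PROB) pmin(pmax(p, eps), 1 - eps)

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Add a bias (row) vector to every row of a matrix.
add_bias <- function(M, b) {
  M + matrix(b, nrow = nrow(M), ncol = ncol(M), byrow = TRUE)
}

# Deterministic substream seed: mixes a base seed with a label so that
# independent random components (sequences, accessibility, init, ...) draw
# from distinct but reproducible streams. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 7919 + h + 1) %% 2147483647)
}

with_substream <- function(seed, label, code) {
  withr::with_seed(derive_seed(seed, label), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gda <- function(...) stop(..., call. = FALSE)
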