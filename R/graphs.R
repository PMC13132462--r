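# Cell-graph construction and the two propagation operators used by the
# dual-channel graph network: the self-loop-normalised adjacency (local
# channel) and the random-walk PPMI operator (global channel).

#' Build a k-nearest-neighbour cell graph
#'
#' Connects each cell to its `k` nearest neighbours (self excluded) under
#' the chosen metric and symmetrises the edge set by union. Ties are broken
#' toward the lower node index so construction is deterministic.
#'
#' @param emb A `cell_embedding` or a plain numeric matrix (cells x d).
#' @param k Neighbours per node, `1 <= k < n`. Default 6.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param domain Optional domain tag.
#' @return A `cell_graph`: `A` (binary symmetric adjacency, zero diagonal),
#'   `X` (features), `barcodes`, `k`, `metric`, `domain`.
#' @export
build_knn_graph <- function(emb, k = 6, metric = c("cosine", "euclidean"),
                            domain = NA_character_) {
  metric <- match.arg(metric)
  X <- if (inherits(emb, "cell_embedding")) emb$values else as.matrix(emb)
  barcodes <- if (inherits(emb, "cell_embedding")) emb$cell_barcodes else
    rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (k < 1 || k >= n) stop_gda("need 1 <= k < number of cells (k=", k, ", n=", n, ")")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) stop_gda("zero-norm embedding row under cosine metric")
    proximity <- tcrossprod(X / nrm)          # larger = closer
  } else {
    proximity <- -as.matrix(stats::dist(X))   # larger = closer
  }
  diag(proximity) <- -Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(-proximity[i, ], seq_len(n), method = "radix")
    A[i, ord[seq_len(k)]] <- 1
  }
  A <- pmax(A, t(A))  # symmetrise by union
  structure(list(A = A, X = X, barcodes = barcodes, k = k, metric = metric,
                 domain = domain),
            class = "cell_graph")
}

#' Self-loop-normalised adjacency
#'
#' `S = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of `A + I`;
#' the propagation operator of the local graph-convolution channel.
#' Self-loops guarantee positive degrees, so `S` is always defined.
#'
#' @param A Symmetric binary adjacency with zero diagonal (or a
#'   `cell_graph`).
#' @return Symmetric matrix with spectral radius at most 1.
#' @export
normalized_adjacency <- function(A) {
  if (inherits(A, "cell_graph")) A <- A$A
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  dinv * At * rep(dinv, each = nrow(At))
}

#' Random-walk co-occurrence counts
#'
#' Counts visits `C(u, v)` to every other node `v` during random walks of
#' length `L_walk` started at each node `u`. The start node's own visits are
#' not counted; repeat visits are. Two modes:
#' \describe{
#'   \item{closed_form}{deterministic expected counts
#'     `walks_per_node * sum_(t=1..L) (T^t)_(uv)` with `T` the
#'     row-normalised adjacency (the default, and the exact large-sample
#'     limit of the Monte-Carlo mode);}
#'   \item{monte_carlo}{seeded simulation of simple uniform-neighbour
#'     walks.}
#' }
#' Isolated nodes have no neighbours: their walks stay put and their count
#' row is zero.
#'
#' @param graph A `cell_graph` or adjacency matrix.
#' @param L_walk Walk length, `>= 1`. Default 3.
#' @param walks_per_node Walks started per node (default 1000).
#' @param mode `"closed_form"` (default) or `"monte_carlo"`.
#' @param seed Seed for the Monte-Carlo mode.
#' @return Nonnegative count matrix with zero diagonal.
#' @export
walk_cooccurrence <- function(graph, L_walk = 3, walks_per_node = 1000,
                              mode = c("closed_form", "monte_carlo"), seed = 0) {
  mode <- match.arg(mode)
  A <- if (inherits(graph, "cell_graph")) graph$A else as.matrix(graph)
  n <- nrow(A)
  if (L_walk < 1) stop_gda("L_walk must be >= 1")
  deg <- rowSums(A)
  if (mode == "closed_form") {
    Tm <- A / ifelse(deg > 0, deg, 1)
    Tm[deg == 0, ] <- 0
    C <- matrix(0, n, n)
    P <- diag(n)
    for (t in seq_len(L_walk)) {
      P <- P %*% Tm
      C <- C + P
    }
    C <- C * walks_per_node
  } else {
    neigh <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
    C <- matrix(0, n, n)
    withr::with_seed(as.integer(seed), {
      for (u in seq_len(n)) {
        if (deg[u] == 0) next
        cur <- rep.int(u, walks_per_node)
        for (t in seq_len(L_walk)) {
          nxt <- cur
          for (g in unique(cur)) {
            sel <- which(cur == g)
            nb <- neigh[[g]]
            if (length(nb) == 0) next  # walk stays put, nothing counted
            nxt[sel] <- nb[sample.int(length(nb), length(sel), replace = TRUE)]
          }
          cur <- nxt
          visits <- tabulate(cur, nbins = n)
          visits[u] <- 0
          C[u, ] <- C[u, ] + visits
        }
      }
    })
  }
  diag(C) <- 0
  C
}

#' PPMI matrix from walk co-occurrence counts
#'
#' From counts `C(u, v)`: conditional probabilities
#' `P(v|u) = C(u, v) / sum_v' C(u, v')` (all-zero rows stay zero), marginals
#' `P(v) = sum_u P(v|u)`, and
#' `PPMI(u, v) = max(0, log(P(v|u) / P(v) * |V| / L_walk))`, with `|V|/L`
#' acting as a scalar normalisation. Pairs with `P(v|u) = 0` or `P(v) = 0`
#' map to 0. In closed-form mode the result is invariant to
#' `walks_per_node`, whose scale cancels in `P(v|u)`.
#'
#' @param C Nonnegative count matrix with zero diagonal.
#' @param L_walk Walk length used to generate `C`.
#' @return A `ppmi_matrix`: nonnegative, zero diagonal, with `L_walk`
#'   attribute.
#' @export
ppmi_from_counts <- function(C, L_walk) {
  C <- as.matrix(C)
  if (any(C < 0)) stop_gda("negative counts")
  if (any(diag(C) != 0)) stop_gda("count diagonal must be zero")
  n <- nrow(C)
  rs <- rowSums(C)
  Pcond <- C / ifelse(rs > 0, rs, 1)
  Pcond[rs == 0, ] <- 0
  Pv <- colSums(Pcond)
  ratio <- Pcond / rep(ifelse(Pv > 0, Pv, 1), each = n)
  ratio[, Pv == 0] <- 0
  val <- matrix(0, n, n)
  pos <- ratio > 0
  val[pos] <- pmax(0, log(ratio[pos] * n / L_walk))
  structure(val, L_walk = L_walk, class = c("ppmi_matrix", class(val)))
}

#' Symmetrically normalised PPMI propagation operator
#'
#' Symmetrises the PPMI matrix as `(P + t(P)) / 2`, gives zero-degree rows a
#' unit self-weight so their rows stay defined (an isolated node propagates
#' only its own features), and normalises `D^{-1/2} P D^{-1/2}` with `D` the
#' degree (row-sum) matrix.
#'
#' @param P Nonnegative matrix (e.g. from [ppmi_from_counts()]).
#' @return Symmetric nonnegative propagation operator.
#' @export
normalize_ppmi <- function(P) {
  P <- (unclass(as.matrix(P)) + t(unclass(as.matrix(P)))) / 2
  zero <- rowSums(P) == 0
  if (any(zero)) diag(P)[zero] <- 1
  dinv <- 1 / sqrt(rowSums(P))
  dinv * P * rep(dinv, each = nrow(P))
}

#' Assemble a domain dataset for graph domain adaptation
#'
#' Convenience constructor: builds the kNN graph on the cell embeddings and
#' precomputes both propagation operators.
#'
#' @param emb `cell_embedding` (or matrix) for one domain.
#' @param labels Optional `label_table` for the source domain; matched to
#'   barcodes.
#' @param k,metric Graph construction parameters (see [build_knn_graph()]).
#' @param L_walk,walks_per_node,ppmi_mode,ppmi_seed PPMI parameters (see
#'   [walk_cooccurrence()]).
#' @param domain Domain tag ("source"/"target").
#' @return A `domain_dataset`: `X`, `S`, `Sp`, `A`, `barcodes`, `labels`
#'   (integer 0-based, or NULL), `classes`, `domain`.
#' @export
domain_dataset <- function(emb, labels = NULL, k = 6, metric = "cosine",
                           L_walk = 3, walks_per_node = 1000,
                           ppmi_mode = "closed_form", ppmi_seed = 0,
                           domain = NA_character_) {
  g <- build_knn_graph(emb, k = k, metric = metric, domain = domain)
  S <- normalized_adjacency(g$A)
  C <- walk_cooccurrence(g$A, L_walk = L_walk, walks_per_node = walks_per_node,
                         mode = ppmi_mode, seed = ppmi_seed)
  Sp <- normalize_ppmi(ppmi_from_counts(C, L_walk))
  y <- NULL
  classes <- NULL
  if (!is.null(labels)) {
    classes <- attr(labels, "classes")
    m <- match(g$barcodes, labels$barcode)
    if (anyNA(m)) stop_gda("labels missing for some barcodes")
    y <- match(labels$label[m], classes) - 1L
  }
  structure(list(X = g$X, S = S, Sp = Sp, A = g$A, barcodes = g$barcodes,
                 labels = y, classes = classes, domain = domain),
            class = "domain_dataset")
}
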