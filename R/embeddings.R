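#' Create a trainable token embedding table
#'
#' Dense vectors for a closed token vocabulary, initialized uniformly in
#' `[-init_range, init_range]`. Out-of-vocabulary tokens embed to the zero
#' vector.
#'
#' @param tokens Character vector of vocabulary tokens.
#' @param dim Embedding dimension (default 300, the text-channel default).
#' @param trainable Logical flag recorded on the table.
#' @param init_range Half-width of the uniform init interval (default 0.2).
#' @return An `embedding_table`: list with `vectors` (tokens x dim matrix,
#'   rownames = tokens), `dim`, `trainable`.
#' @export
embedding_table <- function(tokens, dim = 300, trainable = TRUE,
                            init_range = 0.2) {
  stopifnot(length(tokens) >= 1, dim >= 1, !anyDuplicated(tokens))
  m <- matrix(stats::runif(length(tokens) * dim, -init_range, init_range),
              nrow = length(tokens), ncol = dim,
              dimnames = list(tokens, NULL))
  structure(list(vectors = m, dim = as.integer(dim), trainable = trainable),
            class = "embedding_table")
}

#' Import pretrained word vectors
#'
#' Reads the standard whitespace-separated word-vector text format
#' (`token v1 v2 ... vd` per line) into an [embedding_table()].
#'
#' @param path File path.
#' @param trainable Whether the imported table should be marked trainable.
#' @return An `embedding_table`.
#' @export
read_word_vectors <- function(path, trainable = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1) stop("read_word_vectors: malformed first line")
  toks <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) {
    if (length(p) != d + 1L) stop("read_word_vectors: inconsistent dimension")
    as.numeric(p[-1])
  }, numeric(d)))
  rownames(vecs) <- toks
  structure(list(vectors = vecs, dim = d, trainable = trainable),
            class = "embedding_table")
}

#' Embed a token sequence with a table
#'
#' Row `i` of the result is the stored vector of token `i`;
#' out-of-vocabulary rows are zero. An empty token list yields a single zero
#' row (degenerate contract so downstream sequence code always sees at least
#' one position).
#'
#' @param tokens Character vector.
#' @param table An [embedding_table()].
#' @return Matrix `length(tokens) x dim` (or `1 x dim` when empty).
#' @export
embed_text <- function(tokens, table) {
  stopifnot(inherits(table, "embedding_table"))
  d <- table$dim
  if (length(tokens) == 0) return(matrix(0, 1, d))
  out <- matrix(0, length(tokens), d)
  idx <- match(tokens, rownames(table$vectors))
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Parameters of the character-level SMILES sequence encoder
#'
#' A character embedding table (ids 1..vocab_size; pad id 0 embeds to zero)
#' followed by a width-3 same-padded 1-D convolution over positions.
#'
#' @param vocab_size Number of real character tokens.
#' @param dim Channel width of the encoder (default 64, the model dimension
#'   of the one-dimensional SMILES learner).
#' @param init_range Uniform init half-width.
#' @return Parameter list with `table` (vocab_size x dim) and `conv`
#'   (width-3 convolution weights).
#' @export
smiles_encoder_params <- function(vocab_size, dim = 64, init_range = 0.2) {
  list(
    table = matrix(stats::runif(vocab_size * dim, -init_range, init_range),
                   vocab_size, dim),
    conv = conv1d_params(dim, dim, width = 3, init_range = init_range)
  )
}

#' Encode tokenized SMILES to a per-position embedding matrix
#'
#' Looks up character embeddings, applies the width-3 same-padded 1-D
#' convolution, and zeroes masked (pad) positions. The encoder respects the
#' mask: padding a sequence further does not change the rows of the real
#' positions.
#'
#' @param ts A [tokenize_smiles()] result.
#' @param params A [smiles_encoder_params()] list.
#' @return Matrix `length(ts$ids) x dim`; pad rows are zero.
#' @export
embed_smiles_sequence <- function(ts, params) {
  stopifnot(inherits(ts, "tokenized_smiles"))
  ids <- ts$ids
  if (any(ids > nrow(params$table) | ids < 0)) {
    stop("embed_smiles_sequence: id out of table range")
  }
  L <- length(ids)
  d <- ncol(params$table)
  X <- matrix(0, L, d)
  real <- ts$mask == 1L
  if (any(real)) X[real, ] <- params$table[ids[real], , drop = FALSE]
  # mask before and after the convolution so pad positions neither emit nor
  # receive signal
  X <- X * ts$mask
  Y <- conv1d_forward(array(X, c(1, L, d)), params$conv)$out
  matrix(Y, L, d) * ts$mask
}

# stable polynomial rolling hash of a string (31-adic mod 2^31-1),
# deterministic across sessions
.string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  h
}

#' Weisfeiler-Lehman hashed subtree fingerprint of a molecular graph
#'
#' Iteratively refines node labels by hashing each node's label together
#' with the sorted labels of its neighbors, then counts every (iteration,
#' label) occurrence into `dim` hashed buckets. Deterministic and invariant
#' to node permutation.
#'
#' @param mol_graph igraph with vertex attribute `label`
#'   (see [smiles_to_graph()]).
#' @param iterations Number of WL refinement rounds (>= 0).
#' @param dim Fingerprint length (>= 1).
#' @return Numeric vector of length `dim`; the zero vector for an empty
#'   graph.
#' @export
wl_graph_fingerprint <- function(mol_graph, iterations = 2, dim = 64) {
  stopifnot(iterations >= 0, dim >= 1)
  n <- igraph::vcount(mol_graph)
  fp <- numeric(dim)
  if (n == 0) return(fp)
  labs <- as.character(igraph::V(mol_graph)$label)
  if (length(labs) != n || anyNA(labs)) {
    stop("wl_graph_fingerprint: graph must carry a 'label' vertex attribute")
  }
  adj <- igraph::as_adj_list(mol_graph, mode = "all")
  add_counts <- function(fp, labs, round) {
    for (l in labs) {
      b <- (.string_hash(paste0(round, "|", l)) %% dim) + 1
      fp[b] <- fp[b] + 1
    }
    fp
  }
  fp <- add_counts(fp, labs, 0L)
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      labs <- vapply(seq_len(n), function(i) {
        nb <- sort(labs[as.integer(adj[[i]])])
        paste0(labs[i], "(", paste(nb, collapse = ","), ")")
      }, character(1))
      fp <- add_counts(fp, labs, it)
    }
  }
  fp
}

#' Parameters of the graph-channel encoder
#'
#' One graph-convolution layer, two graph-attention layers, two
#' fully-connected jump-connection layers and max pooling over nodes.
#' Biases (and weights) are initialized uniformly in
#' `[-init_range, init_range]`.
#'
#' @param d_in Node feature width (element one-hot + degree; see
#'   [graph_node_features()]).
#' @param d_hidden Hidden width (default 64).
#' @param d_out Output graph-vector width.
#' @param init_range Uniform init half-width (default 0.2).
#' @return Named parameter list.
#' @export
graph_encoder_params <- function(d_in, d_hidden = 64, d_out = 64,
                                 init_range = 0.2) {
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -init_range, init_range),
                               nr, nc)
  list(
    W_gcn = u(d_in, d_hidden), b_gcn = stats::runif(d_hidden, -init_range, init_range),
    W_gat1 = u(d_hidden, d_hidden), a_gat1 = stats::runif(2 * d_hidden, -init_range, init_range),
    W_gat2 = u(d_hidden, d_hidden), a_gat2 = stats::runif(2 * d_hidden, -init_range, init_range),
    W_fc1 = u(2 * d_hidden, d_hidden), b_fc1 = stats::runif(d_hidden, -init_range, init_range),
    W_fc2 = u(d_hidden, d_out), b_fc2 = stats::runif(d_out, -init_range, init_range)
  )
}

#' Node feature matrix for the graph encoder
#'
#' One-hot element encoding over the common organic elements (bucket
#' `other` for the rest) plus a normalized-degree column.
#'
#' @param mol_graph igraph with vertex `label` attributes.
#' @return Matrix `n_nodes x 11`.
#' @export
graph_node_features <- function(mol_graph) {
  elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  labs <- as.character(igraph::V(mol_graph)$label)
  n <- length(labs)
  X <- matrix(0, n, length(elements) + 2)
  idx <- match(labs, elements)
  idx[is.na(idx)] <- length(elements) + 1
  X[cbind(seq_len(n), idx)] <- 1
  X[, length(elements) + 2] <- igraph::degree(mol_graph) / 4
  X
}

#' Graph-channel encoder forward pass
#'
#' GCN layer (symmetric-normalized adjacency with self loops), two
#' single-head graph-attention layers, a two-layer fully-connected jump
#' connection on the concatenated first/last node representations, ReLU
#' activations throughout, and per-channel max pooling over nodes.
#' Deterministic given the parameters and invariant to node permutation.
#'
#' @param mol_graph igraph with vertex `label` attributes (non-empty).
#' @param params A [graph_encoder_params()] list.
#' @return Numeric vector of length `d_out`.
#' @export
graph_encoder <- function(mol_graph, params) {
  n <- igraph::vcount(mol_graph)
  if (n == 0) stop("graph_encoder: empty graph")
  X <- graph_node_features(mol_graph)
  A <- as.matrix(igraph::as_adjacency_matrix(mol_graph))
  A <- (A > 0) + 0
  Ahat <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat <- Ahat * outer(dinv, dinv)
  relu <- function(z) pmax(z, 0)
  H1 <- relu(Ahat %*% (X %*% params$W_gcn) +
               matrix(params$b_gcn, n, length(params$b_gcn), byrow = TRUE))
  gat <- function(H, W, a) {
    HW <- H %*% W
    d <- ncol(HW)
    src <- HW %*% a[seq_len(d)]
    dst <- HW %*% a[d + seq_len(d)]
    M <- Ahat > 0  # neighbors incl self
    out <- matrix(0, n, d)
    for (i in seq_len(n)) {
      nb <- which(M[i, ])
      e <- src[i] + dst[nb]
      e <- ifelse(e > 0, e, 0.2 * e)  # LeakyReLU(0.2)
      w <- exp(e - max(e)); w <- w / sum(w)
      out[i, ] <- colSums(HW[nb, , drop = FALSE] * w)
    }
    relu(out)
  }
  H2 <- gat(H1, params$W_gat1, params$a_gat1)
  H3 <- gat(H2, params$W_gat2, params$a_gat2)
  J <- relu(cbind(H1, H3) %*% params$W_fc1 +
              matrix(params$b_fc1, n, length(params$b_fc1), byrow = TRUE))
  J2 <- relu(J %*% params$W_fc2 +
               matrix(params$b_fc2, n, length(params$b_fc2), byrow = TRUE))
  apply(J2, 2, max)
}

#' Concatenate the per-drug channel embeddings
#'
#' Joins the four channels of one drug along the channel axis: the sentence
#' embedding matrix `Ew`, the description vector `Eq`, the graph vector
#' `Eg` (both tiled along positions) and the SMILES embedding matrix `Es`.
#' The two matrices are zero-padded to a common sequence length.
#'
#' @param Ew Sentence embedding matrix (`n x d_w`).
#' @param Eq Description vector (`d_q`).
#' @param Eg Graph vector (`d_g`).
#' @param Es SMILES embedding matrix (`L x d_s`).
#' @return Matrix `max(n, L) x (d_w + d_q + d_g + d_s)` with attribute
#'   `channel_dims`.
#' @export
concat_drug_embedding <- function(Ew, Eq, Eg, Es) {
  Ew <- as.matrix(Ew); Es <- as.matrix(Es)
  if (!all(is.finite(Ew)) || !all(is.finite(Eq)) ||
      !all(is.finite(Eg)) || !all(is.finite(Es))) {
    stop("concat_drug_embedding: non-finite input")
  }
  T_ <- max(nrow(Ew), nrow(Es))
  pad <- function(M) rbind(M, matrix(0, T_ - nrow(M), ncol(M)))
  out <- cbind(pad(Ew),
               matrix(Eq, T_, length(Eq), byrow = TRUE),
               matrix(Eg, T_, length(Eg), byrow = TRUE),
               pad(Es))
  attr(out, "channel_dims") <- c(d_w = ncol(Ew), d_q = length(Eq),
                                 d_g = length(Eg), d_s = ncol(Es))
  out
}

#' Split a concatenated drug embedding back into its channels
#'
#' Exact inverse of [concat_drug_embedding()] on the channel axis.
#'
#' @param E_d Concatenated matrix with a `channel_dims` attribute (or
#'   explicit `dims`).
#' @param dims Optional named channel widths `c(d_w, d_q, d_g, d_s)`.
#' @return List with matrices `Ew`, `Eq_tiled`, `Eg_tiled`, `Es`.
#' @export
split_drug_embedding <- function(E_d, dims = attr(E_d, "channel_dims")) {
  stopifnot(!is.null(dims), sum(dims) == ncol(E_d))
  ends <- cumsum(dims)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- lapply(seq_along(dims), function(i) {
    E_d[, starts[i]:ends[i], drop = FALSE]
  })
  names(out) <- c("Ew", "Eq_tiled", "Eg_tiled", "Es")
  out
}
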