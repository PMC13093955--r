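# Pairwise fusion layer: partial cross-attention between the two drugs'
# feature sequences followed by a Mamba block and a residual connection.
# "Partial" means the attention reads and rewrites only the first half of
# the channel dimension; the second half passes through bit-identically,
# which halves the projection cost relative to full cross-attention and
# preserves the original features.

#' Split a feature sequence into two channel halves
#'
#' @param Dr Matrix `T x d` with `d` even.
#' @return List with `first` (`T x d/2`) and `second` (`T x d/2`);
#'   column-binding them inverts the split exactly.
#' @export
split_channels <- function(Dr) {
  Dr <- as.matrix(Dr)
  d <- ncol(Dr)
  if (d %% 2 != 0) {
    stop("split_channels: channel width ", d,
         " is odd; configure an even channel width")
  }
  h <- d / 2
  list(first = Dr[, seq_len(h), drop = FALSE],
       second = Dr[, h + seq_len(h), drop = FALSE])
}

#' Merge two channel halves
#'
#' Inverse of [split_channels()].
#'
#' @param first,second Matrices with equal row counts.
#' @return Column-bound matrix.
#' @export
merge_channels <- function(first, second) cbind(first, second)

#' Parameters of the partial cross-attention module
#'
#' Learnable query/key/value projections acting on the attended
#' half-channel; the key dimension `dk` (used in the `1/sqrt(dk)` scaling)
#' defaults to the half-channel width.
#'
#' @param d_half Width of the attended half-channel.
#' @param dk Key dimension (default `d_half`).
#' @param init_range Uniform init half-width.
#' @return An `attention_params` list with `W_Q`, `W_K`, `W_V`, `dk`.
#' @export
attention_params <- function(d_half, dk = d_half, init_range = 0.2) {
  stopifnot(d_half >= 1, dk >= 1)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -init_range, init_range),
                               nr, nc)
  structure(list(W_Q = u(d_half, dk), W_K = u(d_half, dk),
                 W_V = u(d_half, d_half), dk = as.integer(dk)),
            class = "attention_params")
}

#' Partial cross-attention between two drugs' feature sequences
#'
#' Each drug's features are split into two channel halves. The first halves
#' attend across the pair (`softmax(Q K^T / sqrt(dk)) V`, drug-a queries
#' over drug-b keys/values and symmetrically); the second halves pass
#' through unchanged and are column-bound back on.
#'
#' @param Dr_a,Dr_b Feature sequences (`T_a x d`, `T_b x d`), equal even
#'   channel width.
#' @param params An [attention_params()] list (shared by both directions).
#' @return List with `F_a`, `F_b` (fused sequences, same shapes as the
#'   inputs), `Z_a`, `Z_b` (interaction-enhanced halves) and the attention
#'   weight matrices `weights_ab` (`T_a x T_b`, rows sum to 1) and
#'   `weights_ba`.
#' @export
partial_cross_attention <- function(Dr_a, Dr_b, params) {
  Dr_a <- as.matrix(Dr_a); Dr_b <- as.matrix(Dr_b)
  if (ncol(Dr_a) != ncol(Dr_b)) {
    stop("partial_cross_attention: channel widths differ (",
         ncol(Dr_a), " vs ", ncol(Dr_b), ")")
  }
  sa <- split_channels(Dr_a)
  sb <- split_channels(Dr_b)
  ab <- attn_core_forward(sa$first %*% params$W_Q, sb$first %*% params$W_K,
                          sb$first %*% params$W_V)
  ba <- attn_core_forward(sb$first %*% params$W_Q, sa$first %*% params$W_K,
                          sa$first %*% params$W_V)
  list(F_a = merge_channels(ab$out, sa$second),
       F_b = merge_channels(ba$out, sb$second),
       Z_a = ab$out, Z_b = ba$out,
       weights_ab = ab$A, weights_ba = ba$A)
}

#' Parameters of the cross-Mamba fusion layer
#'
#' @param d_model Channel width of the drug feature sequences (even).
#' @param ... Passed to [mamba_params()].
#' @param init_range Uniform init half-width.
#' @return List with `attn` ([attention_params()]) and `mamba`
#'   ([mamba_params()]).
#' @export
cross_mamba_params <- function(d_model, ..., init_range = 0.2) {
  stopifnot(d_model %% 2 == 0)
  list(attn = attention_params(d_model / 2, init_range = init_range),
       mamba = mamba_params(d_model, ..., init_range = init_range))
}

#' Cross-Mamba fusion layer
#'
#' Partial cross-attention across the pair, a Mamba block on each fused
#' sequence, and an elementwise residual back onto the block input:
#' `Er' = Mamba(PartialCrossAttention(Dr)) + Dr`.
#'
#' @param Dr_a,Dr_b Drug feature sequences of equal channel width.
#' @param params A [cross_mamba_params()] list.
#' @param training Dropout flag for the Mamba block.
#' @return List with `Er_a`, `Er_b` (post-residual outputs, input shapes
#'   preserved) and the attention weights of the fusion step.
#' @export
cross_mamba_layer <- function(Dr_a, Dr_b, params, training = FALSE) {
  pc <- partial_cross_attention(Dr_a, Dr_b, params$attn)
  Er_a <- mamba_block(pc$F_a, params$mamba, training) + as.matrix(Dr_a)
  Er_b <- mamba_block(pc$F_b, params$mamba, training) + as.matrix(Dr_b)
  list(Er_a = Er_a, Er_b = Er_b,
       weights_ab = pc$weights_ab, weights_ba = pc$weights_ba)
}

#' Parameters of the convolutional refinement stage
#'
#' @param d_model Channel width (even).
#' @param init_range Uniform init half-width.
#' @return List with `conv` (width-3 same-padded convolution) and `attn`
#'   (partial cross-attention parameters for the refined features).
#' @export
conv_refine_params <- function(d_model, init_range = 0.2) {
  stopifnot(d_model %% 2 == 0)
  list(conv = conv1d_params(d_model, d_model, width = 3,
                            init_range = init_range),
       attn = attention_params(d_model / 2, init_range = init_range))
}

#' Convolutional refinement with partial cross-attention
#'
#' Applies a width-3 same-padded 1-D convolution and an elementwise ReLU to
#' each drug's fused sequence, then a second partial cross-attention in
#' which each drug's refined features attend over the partner's refined
#' features.
#'
#' @param F_a,F_b Fused feature sequences (`T x d`, finite).
#' @param params A [conv_refine_params()] list.
#' @return List with `EF_a`, `EF_b` and the refinement attention weights.
#' @export
conv_refine <- function(F_a, F_b, params) {
  F_a <- as.matrix(F_a); F_b <- as.matrix(F_b)
  if (!all(is.finite(F_a)) || !all(is.finite(F_b))) {
    stop("conv_refine: non-finite input")
  }
  ref <- function(F_) {
    Y <- conv1d_forward(array(F_, c(1, nrow(F_), ncol(F_))), params$conv)$out
    pmax(matrix(Y, nrow(F_), ncol(F_)), 0)
  }
  G_a <- ref(F_a); G_b <- ref(F_b)
  pc <- partial_cross_attention(G_a, G_b, params$attn)
  list(EF_a = pc$F_a, EF_b = pc$F_b,
       weights_ab = pc$weights_ab, weights_ba = pc$weights_ba)
}

#' Pool two refined sequences and join them into the pair vector
#'
#' Collapses the time axis of each drug's refined sequence (per-channel
#' maximum, or learned attention pooling with softmax weights over
#' positions) and concatenates the two pooled vectors.
#'
#' @param EF_a,EF_b Refined sequences (`T x d`, non-empty).
#' @param mode `"max"` (default) or `"attention"`.
#' @param pool_w Score vector of length `d` for attention pooling.
#' @return Numeric vector of length `2 d`.
#' @export
pool_join <- function(EF_a, EF_b, mode = c("max", "attention"),
                      pool_w = NULL) {
  mode <- match.arg(mode)
  EF_a <- as.matrix(EF_a); EF_b <- as.matrix(EF_b)
  if (nrow(EF_a) == 0 || nrow(EF_b) == 0) {
    stop("pool_join: empty sequence")
  }
  pool <- function(M) {
    if (mode == "max") return(apply(M, 2, max))
    w <- if (is.null(pool_w)) rep(0, ncol(M)) else pool_w
    s <- drop(M %*% w)
    a <- exp(s - max(s)); a <- a / sum(a)
    colSums(M * a)
  }
  c(pool(EF_a), pool(EF_b))
}

#' Export attention weights as a flat table
#'
#' Flattens one or more attention-weight matrices into a long table
#' suitable for heat-map plotting of cross-modal interaction patterns.
#' Row sums (per query position) are preserved.
#'
#' @param weights Attention matrix (rows = query positions, sum to 1), or a
#'   named list of such matrices (names become the `pair` column).
#' @param pattern_labels Optional labels for the key positions (columns).
#' @return `data.frame` with columns `pair`, `query`, `pattern`, `weight`.
#' @export
export_attention_weights <- function(weights, pattern_labels = NULL) {
  if (is.matrix(weights)) weights <- list(pair_1 = weights)
  out <- do.call(rbind, lapply(names(weights), function(nm) {
    W <- weights[[nm]]
    labs <- if (is.null(pattern_labels)) {
      paste0("pattern_", seq_len(ncol(W)))
    } else {
      pattern_labels
    }
    data.frame(pair = nm,
               query = rep(seq_len(nrow(W)), times = ncol(W)),
               pattern = rep(labs, each = nrow(W)),
               weight = as.vector(W),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
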