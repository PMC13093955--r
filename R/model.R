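# End-to-end model assembly: per-drug channel embeddings -> PCA -> Mamba
# encoder -> cross-Mamba fusion -> convolutional refinement -> pooled join
# -> sigmoid heads. Gradients are hand-written per stage (reverse mode with
# explicit caches); training is Adam with a loss-plateau learning-rate
# decay, inverse-frequency class weights and SMOTE oversampling of the
# rarest positive class in PCA feature space.

#' Model configuration
#'
#' All tunable hyperparameters with their documented defaults: channel
#' widths (text 300, SMILES/graph/model 64), SMILES dictionary 66, one
#' attention head, feedforward width 128, positional capacity 100 for the
#' SMILES encoder and 512 for text, PCA target 150, dropout 0.2 inside
#' encoder blocks and 0.5 before the head, bias/weight init uniform in
#' [-0.2, 0.2], batch size 64, learning rate 0.001, 3000 optimizer steps.
#' Ablation toggles switch off the fusion layer, the refinement
#' convolution or PCA, swap the Mamba blocks for a transformer encoder
#' block, or select attention pooling.
#'
#' @param d_w,d_q,d_g,d_s Channel widths: sentence words, description,
#'   molecular graph, SMILES sequence.
#' @param d_model Sequence-model channel width (even).
#' @param d_state SSM state width.
#' @param expand Mamba inner expansion factor.
#' @param conv_width Mamba depthwise causal convolution width.
#' @param dropout_block Dropout inside encoder blocks.
#' @param dropout_head Dropout before the classification head.
#' @param init_range Uniform initialization half-width.
#' @param smiles_vocab_size Expected SMILES dictionary size.
#' @param attention_heads Number of attention heads (single-head model).
#' @param d_ff Feedforward width of the transformer ablation block.
#' @param smiles_max_len Positional capacity of the SMILES encoder.
#' @param text_max_len Maximum sentence token count.
#' @param pca_dim PCA target dimension.
#' @param use_pca Enable the PCA reduction between concatenation and the
#'   sequence model.
#' @param batch_size,learning_rate,iterations Optimizer settings
#'   (iterations = optimizer steps).
#' @param pooling `"max"` or `"attention"`.
#' @param graph_channel `"wl"` (hashed Weisfeiler-Lehman fingerprint) or
#'   `"encoder"` (GCN/GAT graph encoder with fixed random parameters).
#' @param head `"sigmoid"` (one-vs-rest heads with per-type binary
#'   cross-entropy) or `"softmax"` (categorical cross-entropy).
#' @param use_smote,use_class_weights Imbalance-handling toggles.
#' @param smote_k Nearest-neighbor count for SMOTE interpolation.
#' @param no_fusion,no_conv,transformer_for_mamba Ablation toggles.
#' @param wl_iterations WL refinement rounds for the graph fingerprint.
#' @param seed Master seed for initialization, batching and dropout.
#' @return A validated `model_config` list.
#' @export
model_config <- function(d_w = 300, d_q = 300, d_g = 64, d_s = 64,
                         d_model = 64, d_state = 16, expand = 2,
                         conv_width = 4, dropout_block = 0.2,
                         dropout_head = 0.5, init_range = 0.2,
                         smiles_vocab_size = 66, attention_heads = 1,
                         d_ff = 128, smiles_max_len = 100,
                         text_max_len = 512, pca_dim = 150, use_pca = TRUE,
                         batch_size = 64, learning_rate = 0.001,
                         iterations = 3000,
                         pooling = c("max", "attention"),
                         graph_channel = c("wl", "encoder"),
                         head = c("sigmoid", "softmax"),
                         use_smote = TRUE, use_class_weights = TRUE,
                         smote_k = 5, no_fusion = FALSE, no_conv = FALSE,
                         transformer_for_mamba = FALSE, wl_iterations = 2,
                         seed = 1) {
  cfg <- list(d_w = d_w, d_q = d_q, d_g = d_g, d_s = d_s,
              d_model = d_model, d_state = d_state, expand = expand,
              conv_width = conv_width, dropout_block = dropout_block,
              dropout_head = dropout_head, init_range = init_range,
              smiles_vocab_size = smiles_vocab_size,
              attention_heads = attention_heads, d_ff = d_ff,
              smiles_max_len = smiles_max_len, text_max_len = text_max_len,
              pca_dim = pca_dim, use_pca = use_pca,
              batch_size = batch_size, learning_rate = learning_rate,
              iterations = iterations, pooling = match.arg(pooling),
              graph_channel = match.arg(graph_channel),
              head = match.arg(head), use_smote = use_smote,
              use_class_weights = use_class_weights, smote_k = smote_k,
              no_fusion = no_fusion, no_conv = no_conv,
              transformer_for_mamba = transformer_for_mamba,
              wl_iterations = wl_iterations, seed = seed)
  dims <- c(d_w, d_q, d_g, d_s, d_model, d_state, expand, conv_width,
            d_ff, smiles_max_len, text_max_len, pca_dim, batch_size,
            iterations + 1, smote_k)
  if (any(dims <= 0)) stop("model_config: all dimensions must be positive")
  if (dropout_block < 0 || dropout_block >= 1 ||
      dropout_head < 0 || dropout_head >= 1) {
    stop("model_config: dropout rates must lie in [0, 1)")
  }
  if (d_model %% 2 != 0) stop("model_config: d_model must be even")
  structure(cfg, class = "model_config")
}

#' Inverse-frequency class weights
#'
#' Weight per type proportional to the inverse of its training count,
#' normalized so the mean weight is 1.
#'
#' @param counts Named positive counts per type.
#' @return Named weights, mean 1.
#' @export
#' @examples
#' inverse_frequency_weights(c(a = 1, b = 3))  # 1.5, 0.5
inverse_frequency_weights <- function(counts) {
  if (any(counts <= 0)) {
    stop("inverse_frequency_weights: zero count; oversample (SMOTE) the ",
         "class or remove it before weighting")
  }
  w <- 1 / counts
  w / mean(w)
}

#' Weighted binary cross-entropy over one-vs-rest heads
#'
#' Mean over batch and types of
#' `-(w_t * y * log(p) + (1 - y) * log(1 - p))`, with probabilities clamped
#' at `1e-7` for log stability. `w_t` weights the positive term of type `t`
#' (inverse-frequency weighting of minority classes).
#'
#' @param P Probability matrix (batch x types), entries in (0, 1).
#' @param labels One-hot matrix of the same shape.
#' @param class_weights Positive weight per type (default all 1).
#' @return Non-negative scalar; 0 iff predictions match labels exactly
#'   (after clamping).
#' @export
bce_loss <- function(P, labels, class_weights = rep(1, ncol(P))) {
  P <- as.matrix(P); labels <- as.matrix(labels)
  if (!all(dim(P) == dim(labels))) stop("bce_loss: shape mismatch")
  if (length(class_weights) != ncol(P)) stop("bce_loss: weight length")
  Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  W <- matrix(class_weights, nrow(P), ncol(P), byrow = TRUE)
  -mean(W * labels * log(Pc) + (1 - labels) * log(1 - Pc))
}

## ---- PCA ----

#' Fit a PCA reduction
#'
#' Principal directions of the row vectors of `X`; components are returned
#' as orthonormal rows sorted by decreasing explained variance. When `k`
#' exceeds the rank of the centered data, trailing components are
#' zero-padded with a warning.
#'
#' @param X Feature matrix (`n x d`, `n >= 2`).
#' @param k Target dimension (`k <= min(n, d)`).
#' @return A `pca_state` list: `components` (`k x d`), `means`,
#'   `explained_variance`, `k`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 2, k >= 1, k <= min(n, d))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  r <- ncol(pc$rotation)
  comp <- t(pc$rotation)
  if (k > r || any(ev[seq_len(min(k, r))] < 1e-12)) {
    eff <- min(k, sum(ev > 1e-12))
    if (eff < k) {
      warning("pca_fit: requested k = ", k, " exceeds data rank ", eff,
              "; trailing components zero-padded")
      comp <- rbind(comp[seq_len(eff), , drop = FALSE],
                    matrix(0, k - eff, d))
      ev <- c(ev[seq_len(eff)], rep(0, k - eff))
    }
  }
  comp <- comp[seq_len(k), , drop = FALSE]
  dimnames(comp) <- NULL
  structure(list(components = comp,
                 means = unname(colMeans(X)),
                 explained_variance = unname(ev[seq_len(k)]),
                 k = as.integer(k)),
            class = "pca_state")
}

#' Project data onto fitted principal components
#'
#' @param state A [pca_fit()] result.
#' @param X Matrix with the same column count as the fitting data.
#' @return Matrix `n x k`.
#' @export
pca_transform <- function(state, X) {
  X <- as.matrix(X)
  stopifnot(inherits(state, "pca_state"),
            ncol(X) == length(state$means))
  sweep(X, 2, state$means) %*% t(state$components)
}

#' Reconstruct data from PCA scores
#'
#' @param state A [pca_fit()] result.
#' @param S Score matrix (`n x k`).
#' @return Matrix in the original feature space.
#' @export
pca_inverse <- function(state, S) {
  sweep(as.matrix(S) %*% state$components, 2, state$means, `+`)
}

## ---- SMOTE ----

#' Oversampling targets under the second-rarest-class rule
#'
#' Raises the count of the rarest positive class to the count of the
#' second-rarest positive class; other classes (including `Negative`, if
#' present) are unchanged.
#'
#' @param counts Named counts per type.
#' @return Named target counts.
#' @export
#' @examples
#' smote_target_counts(ddi_corpus_counts()["train", ])["Int"]  # 824
smote_target_counts <- function(counts) {
  stopifnot(!is.null(names(counts)))
  pos <- setdiff(names(counts), "Negative")
  tgt <- counts
  if (length(pos) >= 2) {
    o <- order(counts[pos])
    rarest <- pos[o[1]]
    second <- pos[o[2]]
    tgt[rarest] <- max(counts[rarest], counts[second])
  }
  tgt
}

#' SMOTE oversampling of minority feature vectors
#'
#' Generates synthetic samples `x_i + lambda * (x_nn - x_i)` with `lambda`
#' uniform in \[0, 1\] and `x_nn` one of the `k_neighbors` nearest same-class
#' neighbors of `x_i`, until each class reaches its target count.
#'
#' @param features Numeric feature matrix (rows = samples).
#' @param labels Class label per row.
#' @param target_rule `"second_rarest"` (raise the rarest positive class to
#'   the second-rarest positive count) or a named vector of explicit target
#'   counts.
#' @param k_neighbors Neighborhood size (default 5).
#' @param seed RNG seed.
#' @return List with augmented `features`, `labels`, and `synthetic`
#'   (logical flag per row).
#' @export
smote_oversample <- function(features, labels, target_rule = "second_rarest",
                             k_neighbors = 5, seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  targets <- if (is.character(target_rule) &&
                 identical(target_rule, "second_rarest")) {
    cn <- as.vector(counts); names(cn) <- names(counts)
    smote_target_counts(cn)
  } else {
    target_rule
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  newF <- list(); newL <- character(0)
  for (cl in names(targets)) {
    have <- sum(labels == cl)
    need <- targets[[cl]] - have
    if (need <= 0) next
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      stop("smote_oversample: class ", sQuote(cl),
           " has fewer than 2 members; cannot interpolate")
    }
    Xc <- features[idx, , drop = FALSE]
    Dm <- as.matrix(stats::dist(Xc))
    diag(Dm) <- Inf
    k <- min(k_neighbors, length(idx) - 1)
    for (j in seq_len(need)) {
      i <- sample.int(length(idx), 1)
      nn <- order(Dm[i, ])[seq_len(k)]
      pick <- nn[sample.int(k, 1)]
      lam <- stats::runif(1)
      newF[[length(newF) + 1]] <- Xc[i, ] + lam * (Xc[pick, ] - Xc[i, ])
      newL <- c(newL, cl)
    }
  }
  if (length(newF)) {
    features <- rbind(features, do.call(rbind, newF))
  }
  list(features = features, labels = c(labels, newL),
       synthetic = c(rep(FALSE, length(labels)), rep(TRUE, length(newL))))
}

## ---- model construction ----

#' Initialize a model from training samples
#'
#' Builds the word/description vocabulary from the samples, the SMILES
#' character vocabulary over the 66-character alphabet, and all trainable
#' parameters (uniform init in `[-init_range, init_range]`). PCA is fitted
#' later, by [train_model()], on training data only.
#'
#' @param samples List of `pair_sample` objects (training data).
#' @param config A [model_config()].
#' @return A `ddi_model` list with `config`, vocabularies, `params` and an
#'   (empty) graph-fingerprint cache.
#' @export
init_model <- function(samples, config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  words <- sort(unique(unlist(lapply(samples, function(s) {
    c(s$sentence_tokens, s$drug_a$description_tokens,
      s$drug_b$description_tokens)
  }))))
  if (length(words) == 0) words <- "."
  svocab <- build_smiles_vocab(smiles_alphabet66())
  cfg <- config
  C_tot <- cfg$d_w + cfg$d_q + cfg$d_g + cfg$d_s
  k_in <- if (cfg$use_pca) min(cfg$pca_dim, C_tot) else C_tot
  ir <- cfg$init_range
  mk_block <- function() {
    if (cfg$transformer_for_mamba) {
      transformer_params(cfg$d_model, cfg$d_ff, cfg$dropout_block, ir)
    } else {
      mamba_params(cfg$d_model, cfg$d_state, cfg$expand, cfg$conv_width,
                   cfg$dropout_block, ir)
    }
  }
  params <- list(
    word_table = matrix(stats::runif(length(words) * cfg$d_w, -ir, ir),
                        length(words), cfg$d_w),
    desc_table = matrix(stats::runif(length(words) * cfg$d_q, -ir, ir),
                        length(words), cfg$d_q),
    smiles = smiles_encoder_params(length(svocab$token_to_id), cfg$d_s, ir),
    adapter = linear_params(k_in, cfg$d_model, ir),
    m1 = mk_block(),
    head = linear_params(2 * cfg$d_model, length(ddi_labels()), ir)
  )
  if (!cfg$no_fusion) {
    params$attn1 <- attention_params(cfg$d_model / 2, init_range = ir)
    params$m2 <- mk_block()
  }
  if (!cfg$no_conv) {
    params$convr <- conv1d_params(cfg$d_model, cfg$d_model, 3, ir)
  }
  params$attn2 <- attention_params(cfg$d_model / 2, init_range = ir)
  if (cfg$pooling == "attention") {
    params$pool_w <- stats::runif(cfg$d_model, -ir, ir)
  }
  genc <- if (cfg$graph_channel == "encoder") {
    graph_encoder_params(11, 64, cfg$d_g, ir)
  }
  structure(list(config = cfg, word_vocab = words, svocab = svocab,
                 params = params, pca = NULL, class_weights = NULL,
                 graph_params = genc, graph_cache = new.env(parent = emptyenv())),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("DDI cross-modal model\n")
  cat("  words:", length(x$word_vocab),
      "| smiles tokens:", length(x$svocab$token_to_id),
      "| d_model:", x$config$d_model, "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  cat("  PCA:", if (is.null(x$pca)) "not fitted" else
    paste0("fitted (k = ", x$pca$k, ")"), "\n")
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' Excludes frozen quantities (the SSM spectrum `A`, structural scalars).
#'
#' @param model A `ddi_model` (or a raw parameter list).
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "ddi_model")) model$params else model
  frozen <- c("A", "width", "dk", "dropout", "d_model", "d_inner",
              "d_state", "d_ff")
  walk <- function(p) {
    if (is.list(p)) {
      nms <- names(p)
      tot <- 0
      for (i in seq_along(p)) {
        if (!is.null(nms) && nms[i] %in% frozen) next
        tot <- tot + walk(p[[i]])
      }
      tot
    } else if (is.numeric(p)) length(p) else 0
  }
  walk(params)
}

# fingerprint (or fixed graph-encoder) vector for one SMILES, cached
graph_vector <- function(model, smiles) {
  key <- smiles
  cache <- model$graph_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  g <- smiles_to_graph(smiles)
  v <- if (model$config$graph_channel == "encoder") {
    graph_encoder(g, model$graph_params)
  } else {
    wl_graph_fingerprint(g, model$config$wl_iterations, model$config$d_g)
  }
  nv <- sqrt(sum(v^2))
  if (nv > 0) v <- v / nv
  cache[[key]] <- v
  v
}

#' Encode pair samples into integer/tensor form
#'
#' Maps tokens to vocabulary indices (out-of-vocabulary words to 0, which
#' embeds to the zero vector), tokenizes SMILES over the model's character
#' vocabulary, computes the (cached) graph vectors, and records the label
#' index.
#'
#' @param model A `ddi_model`.
#' @param samples List of `pair_sample` objects.
#' @return List of encoded samples.
#' @export
encode_samples <- function(model, samples) {
  cfg <- model$config
  labels <- ddi_labels()
  lapply(samples, function(s) {
    wid <- match(s$sentence_tokens, model$word_vocab)
    wid[is.na(wid)] <- 0L
    wid <- utils::head(wid, cfg$text_max_len)
    if (length(wid) == 0) wid <- 0L
    enc_side <- function(d) {
      did <- match(d$description_tokens, model$word_vocab)
      did <- did[!is.na(did)]
      n <- min(nchar(d$smiles), cfg$smiles_max_len)
      ts <- tokenize_smiles(d$smiles, model$svocab, max_len = max(n, 1))
      list(desc = did, sm_ids = ts$ids[ts$mask == 1L],
           g = graph_vector(model, d$smiles))
    }
    list(wid = as.integer(wid), a = enc_side(s$drug_a),
         b = enc_side(s$drug_b),
         y = match(s$label, labels))
  })
}

#' Fit the model's PCA reduction on training samples
#'
#' Computes the concatenated channel features of the samples and fits the
#' principal-component reduction that [forward()] applies per position.
#' [train_model()] calls this automatically; it is exposed so an untrained
#' model can run forward passes.
#'
#' @param model A `ddi_model` with `config$use_pca = TRUE`.
#' @param samples Training `pair_sample` list (or encoded samples).
#' @return The model with `model$pca` fitted.
#' @export
fit_pca <- function(model, samples) {
  stopifnot(inherits(model, "ddi_model"))
  if (!model$config$use_pca) return(model)
  enc <- if (length(samples) && inherits(samples[[1]], "pair_sample")) {
    encode_samples(model, samples)
  } else {
    samples
  }
  n <- length(enc)
  rows <- list()
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 256))) {
    st <- stage1_forward(model, enc[chunk])
    for (side in c("Xa", "Xb")) {
      len <- if (side == "Xa") st$lena else st$lenb
      rows[[length(rows) + 1]] <- do.call(rbind, lapply(
        seq_along(chunk), function(b) {
          matrix(st[[side]][b, seq_len(len[b]), ], len[b],
                 dim(st[[side]])[3])
        }))
    }
  }
  feat <- do.call(rbind, rows)
  k <- min(model$config$pca_dim, ncol(feat), nrow(feat))
  model$pca <- pca_fit(feat, k)
  model
}

## ---- stage 1: channel embeddings -> concatenation -> PCA ----

# enc: list of encoded samples (the compute set). Returns per-drug
# position-wise feature arrays in the (possibly PCA-reduced) channel space,
# plus prefix lengths and caches for the backward pass.
stage1_forward <- function(model, enc) {
  cfg <- model$config
  p <- model$params
  B <- length(enc)
  nlen <- vapply(enc, function(e) length(e$wid), integer(1))
  salen <- vapply(enc, function(e) max(length(e$a$sm_ids), 1L), integer(1))
  sblen <- vapply(enc, function(e) max(length(e$b$sm_ids), 1L), integer(1))
  T_ <- max(nlen, salen, sblen)
  lena <- pmax(nlen, salen)
  lenb <- pmax(nlen, sblen)
  Wids <- matrix(0L, B, T_)
  SA <- matrix(0L, B, T_); SB <- matrix(0L, B, T_)
  Ga <- matrix(0, B, cfg$d_g); Gb <- matrix(0, B, cfg$d_g)
  Eqa <- matrix(0, B, cfg$d_q); Eqb <- matrix(0, B, cfg$d_q)
  for (b in seq_len(B)) {
    e <- enc[[b]]
    if (nlen[b] > 0) Wids[b, seq_len(nlen[b])] <- e$wid
    if (length(e$a$sm_ids)) SA[b, seq_along(e$a$sm_ids)] <- e$a$sm_ids
    if (length(e$b$sm_ids)) SB[b, seq_along(e$b$sm_ids)] <- e$b$sm_ids
    Ga[b, ] <- e$a$g; Gb[b, ] <- e$b$g
    if (length(e$a$desc)) {
      Eqa[b, ] <- colMeans(p$desc_table[e$a$desc, , drop = FALSE])
    }
    if (length(e$b$desc)) {
      Eqb[b, ] <- colMeans(p$desc_table[e$b$desc, , drop = FALSE])
    }
  }
  maska <- outer(seq_len(B), seq_len(T_),
                 function(b, t) as.numeric(t <= lena[b]))
  maskb <- outer(seq_len(B), seq_len(T_),
                 function(b, t) as.numeric(t <= lenb[b]))
  # shared sentence channel
  lookup <- function(table, ids) {
    M <- matrix(0, B * T_, ncol(table))
    pos <- which(c(ids) > 0)
    if (length(pos)) M[pos, ] <- table[c(ids)[pos], , drop = FALSE]
    from_bt(M, B, T_)
  }
  Ew <- lookup(p$word_table, Wids)
  smi_side <- function(ids) {
    X <- lookup(p$smiles$table, ids)
    cv <- conv1d_forward(X, p$smiles$conv)
    sm_mask <- (ids > 0) + 0
    list(out = cv$out * c(sm_mask), cv = cv, sm_mask = sm_mask)
  }
  Esa <- smi_side(SA); Esb <- smi_side(SB)
  brow <- rep(seq_len(B), T_)   # (b, t) row index -> sample b
  assemble <- function(Es, Eq, G, mask) {
    mv <- c(mask)
    M <- cbind(as_bt(Ew) * mv,
               Eq[brow, , drop = FALSE] * mv,
               G[brow, , drop = FALSE] * mv,
               as_bt(Es$out))
    from_bt(M, B, T_)
  }
  Ea <- assemble(Esa, Eqa, Ga, maska)
  Eb <- assemble(Esb, Eqb, Gb, maskb)
  project <- function(E, mask) {
    if (cfg$use_pca && !is.null(model$pca)) {
      M <- sweep(as_bt(E), 2, model$pca$means) %*% t(model$pca$components)
      from_bt(M, B, T_) * c(mask)
    } else {
      E
    }
  }
  list(Xa = project(Ea, maska), Xb = project(Eb, maskb),
       lena = lena, lenb = lenb, T_ = T_,
       cache = list(Wids = Wids, SA = SA, SB = SB, enc = enc,
                    Esa = Esa, Esb = Esb, maska = maska, maskb = maskb,
                    B = B))
}

stage1_backward <- function(model, st1, dXa, dXb) {
  cfg <- model$config
  p <- model$params
  cc <- st1$cache
  B <- cc$B; T_ <- st1$T_
  unproject <- function(dX, mask) {
    if (cfg$use_pca && !is.null(model$pca)) {
      from_bt(as_bt(dX * c(mask)) %*% model$pca$components, B, T_)
    } else {
      dX
    }
  }
  dEa <- unproject(dXa, cc$maska)
  dEb <- unproject(dXb, cc$maskb)
  i1 <- seq_len(cfg$d_w)
  i2 <- cfg$d_w + seq_len(cfg$d_q)
  i4 <- cfg$d_w + cfg$d_q + cfg$d_g + seq_len(cfg$d_s)
  gW <- matrix(0, nrow(p$word_table), ncol(p$word_table))
  gD <- matrix(0, nrow(p$desc_table), ncol(p$desc_table))
  scatter_words <- function(dEw, mask) {
    dM <- as_bt(dEw * c(mask))
    pos <- which(c(cc$Wids) > 0)
    if (length(pos)) {
      agg <- rowsum(dM[pos, , drop = FALSE], c(cc$Wids)[pos])
      ids <- as.integer(rownames(agg))
      gW[ids, ] <<- gW[ids, ] + agg
    }
  }
  scatter_words(dEa[, , i1, drop = FALSE], cc$maska)
  scatter_words(dEb[, , i1, drop = FALSE], cc$maskb)
  # description means
  for (b in seq_len(B)) {
    e <- cc$enc[[b]]
    for (side in c("a", "b")) {
      ids <- e[[side]]$desc
      if (!length(ids)) next
      dE <- if (side == "a") dEa else dEb
      mask <- if (side == "a") cc$maska else cc$maskb
      g <- colSums(matrix(dE[b, , i2], T_, cfg$d_q) * mask[b, ]) / length(ids)
      for (id in ids) gD[id, ] <- gD[id, ] + g
    }
  }
  # SMILES conv + table
  gS_table <- matrix(0, nrow(p$smiles$table), ncol(p$smiles$table))
  gS_conv <- NULL
  smi_back <- function(dEs, side, ids) {
    dY <- dEs * c(side$sm_mask)
    cb <- conv1d_backward(p$smiles$conv, side$cv, dY)
    gS_conv <<- if (is.null(gS_conv)) cb$grads else tree_add(gS_conv, cb$grads)
    dM <- as_bt(cb$dX)
    pos <- which(c(ids) > 0)
    if (length(pos)) {
      agg <- rowsum(dM[pos, , drop = FALSE], c(ids)[pos])
      ridx <- as.integer(rownames(agg))
      gS_table[ridx, ] <<- gS_table[ridx, ] + agg
    }
  }
  smi_back(dEa[, , i4, drop = FALSE], cc$Esa, cc$SA)
  smi_back(dEb[, , i4, drop = FALSE], cc$Esb, cc$SB)
  list(word_table = gW, desc_table = gD,
       smiles = list(table = gS_table, conv = gS_conv))
}

## ---- transformer encoder block (Mamba ablation) ----

#' Parameters of the transformer encoder block used by the
#' `transformer_for_mamba` ablation
#'
#' Single-head self-attention plus a two-layer feedforward (ReLU), both
#' with residual connections and output dropout.
#'
#' @param d_model Channel width.
#' @param d_ff Feedforward width (default 128).
#' @param dropout Output dropout rate.
#' @param init_range Uniform init half-width.
#' @return A `transformer_params` list.
#' @export
transformer_params <- function(d_model, d_ff = 128, dropout = 0.2,
                               init_range = 0.2) {
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -init_range, init_range),
                               nr, nc)
  structure(list(W_Q = u(d_model, d_model), W_K = u(d_model, d_model),
                 W_V = u(d_model, d_model), W_O = u(d_model, d_model),
                 ff1 = linear_params(d_model, d_ff, init_range),
                 ff2 = linear_params(d_ff, d_model, init_range),
                 dropout = dropout, d_model = as.integer(d_model),
                 d_ff = as.integer(d_ff)),
            class = "transformer_params")
}

transformer_forward_batch <- function(X, p, training = FALSE, len = NULL) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  if (is.null(len)) len <- rep(T_, B)
  H <- X
  attns <- vector("list", B)
  for (b in seq_len(B)) {
    L <- len[b]
    Xb <- matrix(X[b, seq_len(L), ], L, d[3])
    ac <- attn_core_forward(Xb %*% p$W_Q, Xb %*% p$W_K, Xb %*% p$W_V)
    attns[[b]] <- c(ac, list(Xb = Xb))
    H[b, seq_len(L), ] <- Xb + ac$out %*% p$W_O
  }
  ff <- linear_forward(H, p$ff1)
  rl <- relu_forward(ff$out)
  f2 <- linear_forward(rl$out, p$ff2)
  dr <- dropout_forward(f2$out, p$dropout, training)
  list(out = H + dr$out,
       cache = list(attns = attns, ff = ff, rl = rl, f2 = f2, dr = dr,
                    len = len, dims = d))
}

transformer_backward_batch <- function(p, cache, dOut) {
  d <- cache$dims; B <- d[1]
  dF <- dropout_backward(cache$dr, dOut)
  lb2 <- linear_backward(p$ff2, cache$f2, dF)
  dRl <- relu_backward(cache$rl, lb2$dX)
  lb1 <- linear_backward(p$ff1, cache$ff, dRl)
  dH <- dOut + lb1$dX
  dX <- array(0, d)
  gQ <- 0; gK <- 0; gV <- 0; gO <- 0
  for (b in seq_len(B)) {
    L <- cache$len[b]
    ac <- cache$attns[[b]]
    dHb <- matrix(dH[b, seq_len(L), ], L, d[3])
    dZ <- dHb %*% t(p$W_O)
    gO <- gO + crossprod(ac$out, dHb)
    ab <- attn_core_backward(ac, dZ)
    gQ <- gQ + crossprod(ac$Xb, ab$dQ)
    gK <- gK + crossprod(ac$Xb, ab$dK)
    gV <- gV + crossprod(ac$Xb, ab$dV)
    dXb <- dHb + ab$dQ %*% t(p$W_Q) + ab$dK %*% t(p$W_K) +
      ab$dV %*% t(p$W_V)
    dX[b, seq_len(L), ] <- dXb
    if (L < d[2]) dX[b, (L + 1):d[2], ] <- dH[b, (L + 1):d[2], ]
  }
  list(dX = dX,
       grads = list(W_Q = gQ, W_K = gK, W_V = gV, W_O = gO,
                    ff1 = lb1$grads, ff2 = lb2$grads))
}

seq_block_forward <- function(X, p, training, len) {
  if (inherits(p, "transformer_params")) {
    transformer_forward_batch(X, p, training, len)
  } else {
    mamba_forward_batch(X, p, training)
  }
}

seq_block_backward <- function(p, cache, dOut) {
  if (inherits(p, "transformer_params")) {
    transformer_backward_batch(p, cache, dOut)
  } else {
    mamba_backward_batch(p, cache, dOut)
  }
}

## ---- stage 2: adapter -> encoder -> fusion -> refinement -> head ----

# batched partial cross-attention over padded sequences with prefix masks
batch_pcattn_forward <- function(Xa, Xb, lena, lenb, prm) {
  d <- dim(Xa); B <- d[1]; T_ <- d[2]; h <- d[3] / 2
  ia <- seq_len(h); ib <- h + seq_len(h)
  Fa <- Xa; Fb <- Xb
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    A1 <- matrix(Xa[b, , ia], T_, h)
    A2 <- matrix(Xb[b, , ia], T_, h)
    ca <- attn_core_forward(A1 %*% prm$W_Q, A2 %*% prm$W_K, A2 %*% prm$W_V,
                            key_len = lenb[b])
    cb <- attn_core_forward(A2 %*% prm$W_Q, A1 %*% prm$W_K, A1 %*% prm$W_V,
                            key_len = lena[b])
    Fa[b, , ia] <- ca$out
    Fb[b, , ia] <- cb$out
    caches[[b]] <- list(ca = ca, cb = cb, A1 = A1, A2 = A2)
  }
  list(Fa = Fa, Fb = Fb, caches = caches, dims = d)
}

batch_pcattn_backward <- function(cache, prm, dFa, dFb) {
  d <- cache$dims; B <- d[1]; T_ <- d[2]; h <- d[3] / 2
  ia <- seq_len(h); ib <- h + seq_len(h)
  dXa <- dFa; dXb <- dFb   # retained halves pass straight through
  gQ <- 0; gK <- 0; gV <- 0
  for (b in seq_len(B)) {
    cc <- cache$caches[[b]]
    dZa <- matrix(dFa[b, , ia], T_, h)
    dZb <- matrix(dFb[b, , ia], T_, h)
    ba <- attn_core_backward(cc$ca, dZa)
    bb <- attn_core_backward(cc$cb, dZb)
    gQ <- gQ + crossprod(cc$A1, ba$dQ) + crossprod(cc$A2, bb$dQ)
    gK <- gK + crossprod(cc$A2, ba$dK) + crossprod(cc$A1, bb$dK)
    gV <- gV + crossprod(cc$A2, ba$dV) + crossprod(cc$A1, bb$dV)
    dXa[b, , ia] <- ba$dQ %*% t(prm$W_Q) + bb$dK %*% t(prm$W_K) +
      bb$dV %*% t(prm$W_V)
    dXb[b, , ia] <- bb$dQ %*% t(prm$W_Q) + ba$dK %*% t(prm$W_K) +
      ba$dV %*% t(prm$W_V)
  }
  list(dXa = dXa, dXb = dXb,
       grads = list(W_Q = gQ, W_K = gK, W_V = gV))
}

stage2_forward <- function(model, Xa, Xb, lena, lenb, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (dim(Xa)[3] != nrow(p$adapter$W)) {
    stop("feature width ", dim(Xa)[3], " does not match the adapter (",
         nrow(p$adapter$W), "); with use_pca = TRUE fit the reduction ",
         "first (train_model() or fit_pca())")
  }
  B <- dim(Xa)[1]; T_ <- dim(Xa)[2]
  ma <- outer(seq_len(B), seq_len(T_), function(b, t) as.numeric(t <= lena[b]))
  mb <- outer(seq_len(B), seq_len(T_), function(b, t) as.numeric(t <= lenb[b]))
  ad_a <- linear_forward(Xa, p$adapter)
  ad_b <- linear_forward(Xb, p$adapter)
  H0a <- ad_a$out * c(ma); H0b <- ad_b$out * c(mb)
  m1a <- seq_block_forward(H0a, p$m1, training, lena)
  m1b <- seq_block_forward(H0b, p$m1, training, lenb)
  Dra <- m1a$out * c(ma); Drb <- m1b$out * c(mb)
  if (!cfg$no_fusion) {
    pc1 <- batch_pcattn_forward(Dra, Drb, lena, lenb, p$attn1)
    Fa <- pc1$Fa * c(ma); Fb <- pc1$Fb * c(mb)
    m2a <- seq_block_forward(Fa, p$m2, training, lena)
    m2b <- seq_block_forward(Fb, p$m2, training, lenb)
    Epa <- (m2a$out + Dra) * c(ma)
    Epb <- (m2b$out + Drb) * c(mb)
  } else {
    pc1 <- NULL; m2a <- NULL; m2b <- NULL
    Epa <- Dra; Epb <- Drb
  }
  if (!cfg$no_conv) {
    cva <- conv1d_forward(Epa, p$convr)
    cvb <- conv1d_forward(Epb, p$convr)
    rla <- relu_forward(cva$out)
    rlb <- relu_forward(cvb$out)
    Gra <- rla$out * c(ma); Grb <- rlb$out * c(mb)
  } else {
    cva <- NULL; cvb <- NULL; rla <- NULL; rlb <- NULL
    Gra <- Epa; Grb <- Epb
  }
  pc2 <- batch_pcattn_forward(Gra, Grb, lena, lenb, p$attn2)
  EFa <- pc2$Fa * c(ma); EFb <- pc2$Fb * c(mb)
  if (cfg$pooling == "max") {
    pa <- maxpool_forward(EFa, lena)
    pb <- maxpool_forward(EFb, lenb)
  } else {
    pa <- attnpool_forward(EFa, p$pool_w, lena)
    pb <- attnpool_forward(EFb, p$pool_w, lenb)
  }
  V <- cbind(pa$out, pb$out)
  dr <- dropout_forward(V, cfg$dropout_head, training)
  logits <- dr$out %*% p$head$W + rep(p$head$b, each = B)
  P <- if (cfg$head == "sigmoid") {
    sigmoid(logits)
  } else {
    E <- exp(logits - apply(logits, 1, max)); E / rowSums(E)
  }
  list(P = P, logits = logits, V = V,
       attn_weights = list(
         fusion_ab = if (!is.null(pc1)) lapply(pc1$caches, function(x) x$ca$A),
         refine_ab = lapply(pc2$caches, function(x) x$ca$A)),
       cache = list(ma = ma, mb = mb, ad_a = ad_a, ad_b = ad_b,
                    m1a = m1a, m1b = m1b, Dra = Dra, Drb = Drb,
                    pc1 = pc1, m2a = m2a, m2b = m2b,
                    cva = cva, cvb = cvb, rla = rla, rlb = rlb,
                    pc2 = pc2, pa = pa, pb = pb, dr = dr,
                    lena = lena, lenb = lenb, B = B, T_ = T_))
}

stage2_backward <- function(model, fw, dLogits) {
  cfg <- model$config
  p <- model$params
  cc <- fw$cache
  B <- cc$B
  d <- cfg$d_model
  grads <- list()
  Vd <- cc$dr$out
  grads$head <- list(W = crossprod(Vd, dLogits), b = colSums(dLogits))
  dVd <- dLogits %*% t(p$head$W)
  dV <- dropout_backward(cc$dr, dVd)
  dpa <- dV[, seq_len(d), drop = FALSE]
  dpb <- dV[, d + seq_len(d), drop = FALSE]
  if (cfg$pooling == "max") {
    dEFa <- maxpool_backward(cc$pa, dpa)
    dEFb <- maxpool_backward(cc$pb, dpb)
  } else {
    ba <- attnpool_backward(cc$pa, dpa)
    bb <- attnpool_backward(cc$pb, dpb)
    dEFa <- ba$dX; dEFb <- bb$dX
    grads$pool_w <- ba$dw + bb$dw
  }
  dEFa <- dEFa * c(cc$ma); dEFb <- dEFb * c(cc$mb)
  pb2 <- batch_pcattn_backward(cc$pc2, p$attn2, dEFa, dEFb)
  grads$attn2 <- pb2$grads
  dGra <- pb2$dXa; dGrb <- pb2$dXb
  if (!cfg$no_conv) {
    dRa <- relu_backward(cc$rla, dGra * c(cc$ma))
    dRb <- relu_backward(cc$rlb, dGrb * c(cc$mb))
    cba <- conv1d_backward(p$convr, cc$cva, dRa)
    cbb <- conv1d_backward(p$convr, cc$cvb, dRb)
    grads$convr <- tree_add(cba$grads, cbb$grads)
    dEpa <- cba$dX; dEpb <- cbb$dX
  } else {
    dEpa <- dGra; dEpb <- dGrb
  }
  dEpa <- dEpa * c(cc$ma); dEpb <- dEpb * c(cc$mb)
  if (!cfg$no_fusion) {
    mb2a <- seq_block_backward(p$m2, cc$m2a$cache, dEpa)
    mb2b <- seq_block_backward(p$m2, cc$m2b$cache, dEpb)
    grads$m2 <- tree_add(mb2a$grads, mb2b$grads)
    dFa <- mb2a$dX * c(cc$ma); dFb <- mb2b$dX * c(cc$mb)
    pb1 <- batch_pcattn_backward(cc$pc1, p$attn1, dFa, dFb)
    grads$attn1 <- pb1$grads
    dDra <- pb1$dXa + dEpa   # residual Er' = m2(F) + Dr
    dDrb <- pb1$dXb + dEpb
  } else {
    dDra <- dEpa; dDrb <- dEpb
  }
  dDra <- dDra * c(cc$ma); dDrb <- dDrb * c(cc$mb)
  mb1a <- seq_block_backward(p$m1, cc$m1a$cache, dDra)
  mb1b <- seq_block_backward(p$m1, cc$m1b$cache, dDrb)
  grads$m1 <- tree_add(mb1a$grads, mb1b$grads)
  dH0a <- mb1a$dX * c(cc$ma)
  dH0b <- mb1b$dX * c(cc$mb)
  aba <- linear_backward(p$adapter, cc$ad_a, dH0a)
  abb <- linear_backward(p$adapter, cc$ad_b, dH0b)
  grads$adapter <- tree_add(aba$grads, abb$grads)
  list(dXa = aba$dX, dXb = abb$dX, grads = grads)
}

## ---- full forward (public) ----

#' Forward pass: per-type interaction probabilities for a batch
#'
#' Runs the full pipeline (channel embeddings, concatenation, PCA if
#' fitted, Mamba encoding, cross-Mamba fusion, convolutional refinement,
#' pooled join, classification head) in evaluation mode (dropout off).
#'
#' @param model A `ddi_model` (typically from [train_model()]).
#' @param samples List of `pair_sample` objects, or pre-encoded samples
#'   from [encode_samples()].
#' @return Matrix `length(samples) x 5` of probabilities, columns named by
#'   [ddi_labels()], with the refinement attention weights of the batch
#'   attached as attribute `attn_weights`.
#' @export
forward <- function(model, samples) {
  enc <- if (length(samples) && inherits(samples[[1]], "pair_sample")) {
    encode_samples(model, samples)
  } else {
    samples
  }
  st1 <- stage1_forward(model, enc)
  fw <- stage2_forward(model, st1$Xa, st1$Xb, st1$lena, st1$lenb,
                       training = FALSE)
  P <- fw$P
  colnames(P) <- ddi_labels()
  attr(P, "attn_weights") <- fw$attn_weights
  P
}

## ---- optimizer ----

adam_init <- function() list(m = NULL, v = NULL, t = 0)

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  if (is.null(state$m)) {
    state$m <- tree_zeros(grads)
    state$v <- tree_zeros(grads)
  }
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      for (nm in names(g)) {
        if (is.null(g[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      # unnamed lists (conv kernel weight lists)
      if (is.null(names(g))) {
        for (i in seq_along(g)) {
          r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
          p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
        }
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

## ---- training ----

loss_and_dlogits <- function(logits, P, Y, class_weights, head) {
  B <- nrow(P); K <- ncol(P)
  W <- matrix(class_weights, B, K, byrow = TRUE)
  if (head == "sigmoid") {
    loss <- bce_loss(P, Y, class_weights)
    dlog <- (W * Y * (P - 1) + (1 - Y) * P) / (B * K)
  } else {
    Pc <- pmax(P, 1e-12)
    wrow <- rowSums(W * Y)
    loss <- -sum(wrow * log(rowSums(Pc * Y))) / B
    dlog <- wrow * (P - Y) / B
  }
  list(loss = loss, dlogits = dlog)
}

#' Train the cross-modal DDI model
#'
#' Initializes the model from the training samples, fits PCA on the
#' training features, builds inverse-frequency class weights and a SMOTE
#' oversampling plan (rarest positive class raised to the second-rarest
#' count, interpolated in PCA feature space), then runs
#' `config$iterations` Adam steps at `config$batch_size` with a
#' loss-plateau learning-rate decay (factor 0.5, patience 100 steps).
#' Fully deterministic given `config$seed`.
#'
#' @param samples Training `pair_sample` list (no test data; oversampling
#'   and PCA see only these samples).
#' @param config A [model_config()].
#' @param verbose Print progress every 100 steps.
#' @return A trained `ddi_model` with a `log` data.frame
#'   (`step`, `loss`, `lr`) attached as `model$log`.
#' @export
train_model <- function(samples, config, verbose = FALSE) {
  set.seed(config$seed)
  model <- init_model(samples, config)
  enc <- encode_samples(model, samples)
  n <- length(enc)
  labels <- ddi_labels()
  y <- vapply(enc, `[[`, integer(1), "y")
  # PCA fit on all valid positions of the training features
  model <- fit_pca(model, enc)
  # SMOTE plan: parents and interpolation weights fixed up front; the
  # interpolation itself happens in the current PCA feature space each step
  smote_plan <- list()
  if (config$use_smote) {
    cnt <- table(factor(labels[y], levels = labels))
    pos <- setdiff(labels, "Negative")
    present <- pos[cnt[pos] > 0]
    if (length(present) >= 2) {
      o <- order(cnt[present])
      rarest <- present[o[1]]
      need <- as.integer(cnt[present][o[2]] - cnt[present][o[1]])
      ridx <- which(labels[y] == rarest)
      if (need > 0 && length(ridx) >= 2) {
        pooled <- matrix(0, length(ridx), if (config$use_pca) model$pca$k
                         else config$d_w + config$d_q + config$d_g + config$d_s)
        for (chunk in split(seq_along(ridx),
                            ceiling(seq_along(ridx) / 256))) {
          st <- stage1_forward(model, enc[ridx[chunk]])
          for (b in seq_along(chunk)) {
            pooled[chunk[b], ] <- colMeans(
              matrix(st$Xa[b, seq_len(st$lena[b]), ], st$lena[b],
                     dim(st$Xa)[3]))
          }
        }
        Dm <- as.matrix(stats::dist(pooled)); diag(Dm) <- Inf
        kk <- min(config$smote_k, length(ridx) - 1)
        for (j in seq_len(need)) {
          i <- sample.int(length(ridx), 1)
          nn <- order(Dm[i, ])[seq_len(kk)]
          pick <- nn[sample.int(kk, 1)]
          smote_plan[[j]] <- list(p1 = ridx[i], p2 = ridx[pick],
                                  lambda = stats::runif(1),
                                  y = match(rarest, labels))
        }
      }
    }
  }
  # class weights on the effective (post-oversampling) training counts
  class_weights <- rep(1, length(labels))
  if (config$use_class_weights) {
    eff <- table(factor(labels[y], levels = labels))
    if (length(smote_plan)) {
      cl <- labels[smote_plan[[1]]$y]
      eff[cl] <- eff[cl] + length(smote_plan)
    }
    if (any(eff == 0)) {
      stop("train_model: class(es) absent from training data: ",
           paste(names(eff)[eff == 0], collapse = ", "))
    }
    class_weights <- inverse_frequency_weights(as.vector(eff))
  }
  model$class_weights <- class_weights
  # training pool: real indices (positive ints) and SMOTE entries
  pool <- c(seq_len(n), if (length(smote_plan)) -seq_along(smote_plan))
  opt <- adam_init()
  lr <- config$learning_rate
  best <- Inf; stall <- 0L
  log_step <- integer(0); log_loss <- numeric(0); log_lr <- numeric(0)
  steps <- config$iterations
  for (step in seq_len(steps)) {
    take <- if (length(pool) >= config$batch_size) {
      sample(pool, config$batch_size)
    } else {
      sample(pool, config$batch_size, replace = TRUE)
    }
    real <- unique(c(take[take > 0],
                     unlist(lapply(take[take < 0], function(s) {
                       e <- smote_plan[[-s]]; c(e$p1, e$p2)
                     }))))
    st1 <- stage1_forward(model, enc[real])
    # assemble training rows (real rows index the compute set; SMOTE rows
    # interpolate two parents)
    B <- length(take)
    T_ <- st1$T_
    kdim <- dim(st1$Xa)[3]
    Xa <- array(0, c(B, T_, kdim)); Xb <- array(0, c(B, T_, kdim))
    lena <- integer(B); lenb <- integer(B)
    ymat <- matrix(0, B, length(labels))
    row_of <- match(seq_len(n), real)
    mixes <- vector("list", B)
    for (bb in seq_len(B)) {
      s <- take[bb]
      if (s > 0) {
        r <- row_of[s]
        Xa[bb, , ] <- st1$Xa[r, , ]; Xb[bb, , ] <- st1$Xb[r, , ]
        lena[bb] <- st1$lena[r]; lenb[bb] <- st1$lenb[r]
        ymat[bb, y[s]] <- 1
        mixes[[bb]] <- list(r1 = r, w1 = 1)
      } else {
        e <- smote_plan[[-s]]
        r1 <- row_of[e$p1]; r2 <- row_of[e$p2]
        w1 <- 1 - e$lambda; w2 <- e$lambda
        Xa[bb, , ] <- w1 * st1$Xa[r1, , ] + w2 * st1$Xa[r2, , ]
        Xb[bb, , ] <- w1 * st1$Xb[r1, , ] + w2 * st1$Xb[r2, , ]
        lena[bb] <- max(st1$lena[r1], st1$lena[r2])
        lenb[bb] <- max(st1$lenb[r1], st1$lenb[r2])
        ymat[bb, e$y] <- 1
        mixes[[bb]] <- list(r1 = r1, w1 = w1, r2 = r2, w2 = w2)
      }
    }
    fw <- stage2_forward(model, Xa, Xb, lena, lenb, training = TRUE)
    ld <- loss_and_dlogits(fw$logits, fw$P, ymat, class_weights,
                           config$head)
    if (!is.finite(ld$loss)) {
      stop("train_model: non-finite loss at step ", step,
           " (learning rate ", lr, ")")
    }
    bw <- stage2_backward(model, fw, ld$dlogits)
    # route batch-row gradients back to compute-set rows
    nr <- length(real)
    dXa <- array(0, c(nr, T_, kdim)); dXb <- array(0, c(nr, T_, kdim))
    for (bb in seq_len(B)) {
      mx <- mixes[[bb]]
      dXa[mx$r1, , ] <- dXa[mx$r1, , ] + mx$w1 * bw$dXa[bb, , ]
      dXb[mx$r1, , ] <- dXb[mx$r1, , ] + mx$w1 * bw$dXb[bb, , ]
      if (!is.null(mx$r2)) {
        dXa[mx$r2, , ] <- dXa[mx$r2, , ] + mx$w2 * bw$dXa[bb, , ]
        dXb[mx$r2, , ] <- dXb[mx$r2, , ] + mx$w2 * bw$dXb[bb, , ]
      }
    }
    g1 <- stage1_backward(model, st1, dXa, dXb)
    grads <- c(bw$grads, g1)
    up <- adam_update(model$params, grads, opt, lr)
    model$params <- up$params
    opt <- up$state
    # loss-plateau learning-rate decay
    if (ld$loss < best - 1e-6) { best <- ld$loss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= 100L) { lr <- max(lr * 0.5, 1e-5); stall <- 0L }
    log_step <- c(log_step, step)
    log_loss <- c(log_loss, ld$loss)
    log_lr <- c(log_lr, lr)
    if (verbose && step %% 100 == 0) {
      message("step ", step, " loss ", signif(ld$loss, 4), " lr ", lr)
    }
  }
  model$log <- data.frame(step = log_step, loss = log_loss, lr = log_lr)
  model
}

#' Predict interaction types for samples
#'
#' @param model Trained `ddi_model`.
#' @param samples List of `pair_sample` objects.
#' @param chunk Batch size for evaluation.
#' @return List with `prob` (matrix, columns = [ddi_labels()]) and `label`
#'   (argmax type per sample).
#' @export
predict_model <- function(model, samples, chunk = 64) {
  enc <- encode_samples(model, samples)
  n <- length(enc)
  out <- matrix(0, n, length(ddi_labels()),
                dimnames = list(NULL, ddi_labels()))
  for (ix in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    out[ix, ] <- unclass(forward(model, enc[ix]))[, , drop = FALSE]
  }
  list(prob = out, label = ddi_labels()[max.col(out, ties.method = "first")])
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a serialized parameter container with the
#' configuration, vocabularies, PCA state and class weights embedded;
#' loading restores a model whose predictions are identical to the saved
#' one.
#'
#' @param model A `ddi_model`.
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `ddi_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ddi_model"))
  obj <- unclass(model)
  obj$graph_cache <- as.list(model$graph_cache)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$graph_cache <- list2env(obj$graph_cache, parent = emptyenv())
  structure(obj, class = "ddi_model")
}
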