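test_that("channel split and merge are exact inverses", {
  set.seed(41)
  for (k in 1:100) {
    T_ <- sample(1:6, 1); d <- 2 * sample(1:4, 1)
    Dr <- matrix(rnorm(T_ * d), T_, d)
    sp <- split_channels(Dr)
    expect_identical(ncol(sp$first), as.integer(d / 2))
    expect_identical(merge_channels(sp$first, sp$second), Dr)
    # concat then split is also the identity
    re <- split_channels(merge_channels(sp$first, sp$second))
    expect_identical(re$first, sp$first)
    expect_identical(re$second, sp$second)
  }
  expect_error(split_channels(matrix(0, 3, 5)), "even")
  z <- split_channels(matrix(0, 4, 6))
  expect_true(all(z$first == 0) && all(z$second == 0))
})

test_that("partial cross-attention matches its closed forms", {
  set.seed(42)
  d <- 8; h <- 4
  prm <- attention_params(h)
  # single key: softmax over one position is 1, so every query row gets
  # the single value projection
  Dr_a <- matrix(rnorm(3 * d), 3, d)
  Dr_b <- matrix(rnorm(1 * d), 1, d)
  out <- partial_cross_attention(Dr_a, Dr_b, prm)
  v <- drop(Dr_b[, 1:h] %*% prm$W_V)
  for (i in 1:3) expect_equal(unname(out$Z_a[i, ]), unname(v),
                              tolerance = 1e-12)
  expect_equal(out$weights_ab, matrix(1, 3, 1), ignore_attr = TRUE)
  # identical keys give the uniform softmax -> mean of value rows
  prm_id <- attention_params(h)
  prm_id$W_Q <- diag(h); prm_id$W_K <- diag(h); prm_id$W_V <- diag(h)
  key <- rnorm(h)
  out2 <- partial_cross_attention(Dr_a, cbind(rbind(key, key),
                                              matrix(rnorm(2 * h), 2)), prm_id)
  expect_equal(out2$weights_ab, matrix(0.5, 3, 2), ignore_attr = TRUE)
  for (i in 1:3) {
    expect_equal(unname(out2$Z_a[i, ]), unname(c(key)), tolerance = 1e-12)
  }
})

test_that("partial cross-attention equals the brute-force loop oracle", {
  set.seed(43)
  for (k in 1:100) {
    d <- 2 * sample(2:4, 1); h <- d / 2
    Ta <- sample(1:5, 1); Tb <- sample(1:5, 1)
    prm <- attention_params(h)
    Dr_a <- matrix(rnorm(Ta * d), Ta, d)
    Dr_b <- matrix(rnorm(Tb * d), Tb, d)
    got <- partial_cross_attention(Dr_a, Dr_b, prm)
    oa <- oracle_cross_attention(Dr_a[, 1:h, drop = FALSE],
                                 Dr_b[, 1:h, drop = FALSE],
                                 prm$W_Q, prm$W_K, prm$W_V)
    ob <- oracle_cross_attention(Dr_b[, 1:h, drop = FALSE],
                                 Dr_a[, 1:h, drop = FALSE],
                                 prm$W_Q, prm$W_K, prm$W_V)
    expect_equal(got$Z_a, oa$Z, tolerance = 1e-6)
    expect_equal(got$Z_b, ob$Z, tolerance = 1e-6)
    expect_equal(got$weights_ab, oa$A, tolerance = 1e-6)
    # retained halves pass through bit-identically
    expect_identical(got$F_a[, (h + 1):d, drop = FALSE],
                     Dr_a[, (h + 1):d, drop = FALSE])
    # every attention row sums to one
    expect_equal(rowSums(got$weights_ab), rep(1, Ta), tolerance = 1e-12)
    expect_equal(rowSums(got$weights_ba), rep(1, Tb), tolerance = 1e-12)
  }
  expect_error(partial_cross_attention(matrix(0, 2, 4), matrix(0, 2, 6),
                                       attention_params(2)), "width")
})

test_that("attention reads only the partner's first half-channels", {
  set.seed(44)
  d <- 8; h <- 4
  prm <- attention_params(h)
  Dr_a <- matrix(rnorm(3 * d), 3, d)
  Dr_b <- matrix(rnorm(4 * d), 4, d)
  base <- partial_cross_attention(Dr_a, Dr_b, prm)
  Dr_b2 <- Dr_b
  Dr_b2[, (h + 1):d] <- rnorm(4 * h) * 10   # perturb retained half only
  pert <- partial_cross_attention(Dr_a, Dr_b2, prm)
  expect_identical(pert$Z_a, base$Z_a)
  expect_identical(pert$weights_ab, base$weights_ab)
  # permutation equivariance over key positions
  perm <- c(3, 1, 4, 2)
  permd <- partial_cross_attention(Dr_a, Dr_b[perm, ], prm)
  expect_equal(permd$weights_ab, base$weights_ab[, perm],
               tolerance = 1e-12)
  expect_equal(permd$Z_a, base$Z_a, tolerance = 1e-12)
})

test_that("partial attention needs strictly fewer parameters than full", {
  d <- 16
  partial <- attention_params(d / 2)
  n_partial <- length(partial$W_Q) + length(partial$W_K) +
    length(partial$W_V)
  full <- attention_params(d)
  n_full <- length(full$W_Q) + length(full$W_K) + length(full$W_V)
  expect_lt(n_partial, n_full)
})

test_that("cross-Mamba layer keeps shapes and satisfies reductions", {
  set.seed(45)
  d <- 8
  prm <- cross_mamba_params(d, d_state = 4, dropout = 0)
  Dr_a <- matrix(rnorm(5 * d), 5, d)
  Dr_b <- matrix(rnorm(3 * d), 3, d)
  out <- cross_mamba_layer(Dr_a, Dr_b, prm)
  expect_identical(dim(out$Er_a), dim(Dr_a))
  expect_identical(dim(out$Er_b), dim(Dr_b))
  # zero inputs with zero-initialized parameters give a zero residual
  zp <- rapply(prm, function(x) x * 0, how = "replace", classes = "numeric")
  zp$mamba$dropout <- 0
  z <- cross_mamba_layer(matrix(0, 4, d), matrix(0, 4, d), zp)
  expect_equal(z$Er_a, matrix(0, 4, d))
  # perturbing the partner's retained half leaves this drug's attended
  # half input unchanged (partiality carried through the layer)
  Dr_b2 <- Dr_b
  Dr_b2[, (d / 2 + 1):d] <- 9
  out2 <- cross_mamba_layer(Dr_a, Dr_b2, prm)
  expect_equal(out2$Er_a, out$Er_a, tolerance = 1e-12)
})

test_that("conv refinement follows conv -> ReLU -> partial attention", {
  set.seed(46)
  d <- 6
  prm <- conv_refine_params(d)
  F_a <- matrix(rnorm(4 * d), 4, d)
  F_b <- matrix(rnorm(5 * d), 5, d)
  # brute-force sliding-window conv + ReLU + attention oracle
  G_a <- pmax(oracle_conv3(F_a, prm$conv$W, prm$conv$b), 0)
  G_b <- pmax(oracle_conv3(F_b, prm$conv$W, prm$conv$b), 0)
  h <- d / 2
  oa <- oracle_cross_attention(G_a[, 1:h], G_b[, 1:h],
                               prm$attn$W_Q, prm$attn$W_K, prm$attn$W_V)
  got <- conv_refine(F_a, F_b, prm)
  expect_equal(got$EF_a[, 1:h], oa$Z, tolerance = 1e-6)
  expect_equal(got$EF_a[, (h + 1):d], G_a[, (h + 1):d], tolerance = 1e-10)
  # all-negative conv output: ReLU zeroes it and the attended half becomes
  # the value projection of a zero sequence
  prm0 <- prm
  for (j in 1:3) prm0$conv$W[[j]][] <- 0
  prm0$conv$b[] <- -5
  gz <- conv_refine(F_a, F_b, prm0)
  expect_true(all(gz$EF_a == 0))
  # identity kernel on non-negative input reduces to partial attention
  prm_id <- prm
  for (j in c(1, 3)) prm_id$conv$W[[j]][] <- 0
  prm_id$conv$W[[2]] <- diag(d); prm_id$conv$b[] <- 0
  Fp <- abs(F_a); Fq <- abs(F_b)
  red <- conv_refine(Fp, Fq, prm_id)
  direct <- partial_cross_attention(Fp, Fq, prm_id$attn)
  expect_equal(red$EF_a, direct$F_a, tolerance = 1e-10)
  expect_error(conv_refine(F_a * NA, F_b, prm), "non-finite")
})

test_that("pooled join collapses time and concatenates the pair", {
  set.seed(47)
  EF_a <- matrix(rnorm(6 * 4), 6, 4)
  EF_b <- matrix(rnorm(3 * 4), 3, 4)
  V <- pool_join(EF_a, EF_b, mode = "max")
  expect_length(V, 8)
  # loop oracle for the per-channel maximum
  for (c_ in 1:4) {
    m <- -Inf
    for (t in 1:6) m <- max(m, EF_a[t, c_])
    expect_equal(V[c_], m)
  }
  # constant sequence pools to the constant
  const <- matrix(rep(1:4, each = 5), 5, 4)
  expect_equal(pool_join(const, const, mode = "max"),
               rep(1:4, 2), ignore_attr = TRUE)
  # a single row is returned as-is in either mode
  one <- matrix(rnorm(4), 1, 4)
  expect_equal(pool_join(one, one, "max"), c(one, one), ignore_attr = TRUE)
  expect_equal(pool_join(one, one, "attention", pool_w = rnorm(4)),
               c(one, one), ignore_attr = TRUE)
  # attention pooling weights sum to one (weighted mean stays in hull)
  w <- rnorm(4)
  Vp <- pool_join(EF_a, EF_b, "attention", pool_w = w)
  expect_true(all(Vp[1:4] <= apply(EF_a, 2, max) + 1e-12))
  expect_true(all(Vp[1:4] >= apply(EF_a, 2, min) - 1e-12))
  expect_error(pool_join(EF_a[0, , drop = FALSE], EF_b), "empty")
})

test_that("attention-weight export preserves row normalization", {
  W1 <- matrix(1, 1, 1)
  t1 <- export_attention_weights(W1)
  expect_identical(nrow(t1), 1L)
  expect_equal(t1$weight, 1)
  W2 <- matrix(0.25, 2, 2) * 2
  t2 <- export_attention_weights(matrix(c(0.25, 0.75, 0.5, 0.5), 2, 2,
                                        byrow = TRUE),
                                 pattern_labels = c("text", "smiles"))
  expect_identical(nrow(t2), 4L)
  expect_setequal(unique(t2$pattern), c("text", "smiles"))
  set.seed(48)
  for (k in 1:20) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    W <- matrix(rexp(n * m), n, m)
    W <- W / rowSums(W)
    tab <- export_attention_weights(W)
    sums <- as.vector(tapply(tab$weight, tab$query, sum))
    expect_equal(sums, rep(1, n), tolerance = 1e-9)
  }
})
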