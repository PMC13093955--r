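test_that("PCA reduction recovers exact subspaces and stays orthonormal", {
  set.seed(51)
  # data in a 3-dimensional affine subspace of R^8
  basis <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
  S <- matrix(rnorm(40 * 3), 40, 3)
  X <- S %*% t(basis) + matrix(rep(rnorm(8), each = 40), 40, 8)
  st <- pca_fit(X, 3)
  expect_equal(pca_inverse(st, pca_transform(st, X)), X, tolerance = 1e-8)
  expect_equal(st$components %*% t(st$components), diag(3),
               tolerance = 1e-8)
  # isotropic unit-variance data: total explained variance ~ d
  Z <- matrix(rnorm(4000 * 5), 4000, 5)
  stz <- pca_fit(Z, 5)
  expect_equal(sum(stz$explained_variance), 5, tolerance = 0.2)
  expect_true(all(diff(stz$explained_variance) <= 1e-12))
  # rank-deficient data zero-pads trailing components with a warning
  Xlow <- cbind(rnorm(20), rnorm(20)) %*% matrix(rnorm(2 * 6), 2, 6)
  expect_warning(stl <- pca_fit(Xlow, 5), "rank")
  expect_true(all(stl$components[4:5, ] == 0))
})

test_that("weighted BCE matches closed forms and a double-loop oracle", {
  expect_lt(bce_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 1e-5)
  expect_equal(bce_loss(matrix(0.5, 1, 1), matrix(1, 1, 1)), log(2),
               tolerance = 1e-10)
  set.seed(52)
  P <- matrix(runif(8 * 5, 0.05, 0.95), 8, 5)
  Y <- matrix(0, 8, 5); Y[cbind(1:8, sample(1:5, 8, TRUE))] <- 1
  w <- runif(5, 0.5, 2)
  acc <- 0
  for (i in 1:8) for (j in 1:5) {
    acc <- acc - (w[j] * Y[i, j] * log(P[i, j]) +
                    (1 - Y[i, j]) * log(1 - P[i, j]))
  }
  expect_equal(bce_loss(P, Y, w), acc / 40, tolerance = 1e-12)
  expect_error(bce_loss(P, Y[, 1:4]), "shape")
})

test_that("inverse-frequency weights normalize to mean one", {
  expect_equal(unname(inverse_frequency_weights(c(5, 5, 5))), rep(1, 3))
  expect_equal(unname(inverse_frequency_weights(c(1, 3))), c(1.5, 0.5))
  w <- inverse_frequency_weights(ddi_corpus_counts()["train", ])
  expect_equal(unname(w["Int"] / w["Effect"]), 1675 / 188,
               tolerance = 1e-12)
  expect_equal(mean(w), 1)
  expect_error(inverse_frequency_weights(c(a = 0, b = 2)), "SMOTE")
})

test_that("SMOTE interpolates within the minority hull to the target", {
  # 1-D minority at {0, 10}: synthetics stay inside [0, 10]
  X <- matrix(c(0, 10, rep(5, 8)), ncol = 1)
  lab <- c("Int", "Int", rep("Advice", 8))
  out <- smote_oversample(X, lab, k_neighbors = 1, seed = 3)
  synth <- out$features[out$synthetic, , drop = FALSE]
  expect_identical(sum(out$labels == "Int"), 8L)
  expect_true(all(synth >= 0 & synth <= 10))
  # originals preserved untouched
  expect_equal(out$features[1:10, , drop = FALSE], X, ignore_attr = TRUE)
  expect_true(all(out$labels[out$synthetic] == "Int"))
  # singleton minority cannot interpolate
  expect_error(smote_oversample(matrix(rnorm(5), 5, 1),
                                c("Int", rep("Advice", 4)), seed = 1),
               "fewer than 2")
  # determinism
  out2 <- smote_oversample(X, lab, k_neighbors = 1, seed = 3)
  expect_identical(out, out2)
})

test_that("the second-rarest-class rule reproduces the corpus bookkeeping", {
  tgt <- smote_target_counts(ddi_corpus_counts()["train", ])
  expect_identical(unname(tgt["Int"]), 824L)
  expect_identical(tgt[c("Advice", "Mechanism", "Effect", "Negative")],
                   ddi_corpus_counts()["train",
                                       c("Advice", "Mechanism",
                                         "Effect", "Negative")])
})

test_that("forward probabilities behave as logistic heads", {
  sc <- synth_config(n_samples = 8, seed = 61, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  cfg <- tiny_model_config()
  m <- fit_pca(init_model(ds, cfg), ds)
  # zero head: logistic(0) = 0.5 everywhere
  m$params$head$W[] <- 0; m$params$head$b[] <- 0
  P <- forward(m, ds)
  expect_true(all(abs(P - 0.5) < 1e-12))
  # duplicated sample gives identical probability rows (eval mode)
  m2 <- fit_pca(init_model(ds, cfg), ds)
  P2 <- forward(m2, c(ds[1], ds[1], ds[2]))
  expect_equal(P2[1, ], P2[2, ], tolerance = 1e-12)
  expect_true(all(P2 > 0 & P2 < 1))
})

test_that("batching does not leak across samples", {
  sc <- synth_config(n_samples = 6, seed = 62, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  m <- fit_pca(init_model(ds, tiny_model_config()), ds)
  P_batch <- unclass(forward(m, ds[1:2]))
  P_1 <- unclass(forward(m, ds[1]))
  P_2 <- unclass(forward(m, ds[2]))
  expect_equal(P_batch[1, ], P_1[1, ], tolerance = 1e-6)
  expect_equal(P_batch[2, ], P_2[1, ], tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(63)
  sc <- synth_config(n_samples = 5, seed = 64, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  cfg <- tiny_model_config()
  model <- init_model(ds, cfg)
  enc <- encode_samples(model, ds)
  st <- ddimamba:::stage1_forward(model, enc)
  rows <- do.call(rbind, lapply(seq_along(enc), function(b) {
    matrix(st$Xa[b, , ], dim(st$Xa)[2])
  }))
  model$pca <- pca_fit(rows, cfg$pca_dim)
  w <- c(1.2, 0.8, 1, 1.1, 0.9)
  yv <- vapply(enc, `[[`, integer(1), "y")
  Y <- matrix(0, length(enc), 5); Y[cbind(seq_along(yv), yv)] <- 1
  loss_of <- function(mm) {
    s1 <- ddimamba:::stage1_forward(mm, enc)
    fw <- ddimamba:::stage2_forward(mm, s1$Xa, s1$Xb, s1$lena, s1$lenb,
                                    FALSE)
    ddimamba:::loss_and_dlogits(fw$logits, fw$P, Y, w, "sigmoid")$loss
  }
  s1 <- ddimamba:::stage1_forward(model, enc)
  fw <- ddimamba:::stage2_forward(model, s1$Xa, s1$Xb, s1$lena, s1$lenb,
                                  FALSE)
  ld <- ddimamba:::loss_and_dlogits(fw$logits, fw$P, Y, w, "sigmoid")
  bw <- ddimamba:::stage2_backward(model, fw, ld$dlogits)
  g1 <- ddimamba:::stage1_backward(model, s1, bw$dXa, bw$dXb)
  g <- c(bw$grads, g1)
  get_leaf <- function(l, path) { for (p in path) l <- l[[p]]; l }
  set_leaf <- function(l, path, v) {
    if (length(path) == 1) { l[[path[[1]]]] <- v; return(l) }
    l[[path[[1]]]] <- set_leaf(l[[path[[1]]]], path[-1], v)
    l
  }
  paths <- list(list("head", "W"), list("adapter", "W"),
                list("attn1", "W_Q"), list("attn2", "W_V"),
                list("convr", "W", 1),
                list("m1", "in_proj", "W"), list("m1", "conv", "w"),
                list("m1", "dt", "W"), list("m1", "W_B"), list("m1", "D"),
                list("m2", "out_proj", "W"),
                list("word_table"), list("desc_table"),
                list("smiles", "table"), list("smiles", "conv", "W", 2))
  eps <- 1e-5
  for (pth in paths) {
    leaf <- get_leaf(model$params, pth)
    gleaf <- get_leaf(g, pth)
    for (i in sample(length(leaf), min(3, length(leaf)))) {
      v <- leaf; v[i] <- leaf[i] + eps
      mp <- model; mp$params <- set_leaf(mp$params, pth, v)
      lp <- loss_of(mp)
      v[i] <- leaf[i] - eps
      mp$params <- set_leaf(mp$params, pth, v)
      lm <- loss_of(mp)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - gleaf[i]),
                1e-6 + 1e-3 * (abs(num) + abs(gleaf[i])))
    }
  }
})

test_that("training is deterministic, logged, and reduces the loss", {
  sc <- synth_config(n_samples = 16, seed = 65, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  cfg <- tiny_model_config(batch_size = 16)
  # zero iterations leave the parameters at their initialization
  m0 <- train_model(ds, cfg)
  ref <- init_model(ds, cfg)
  if (cfg$use_pca) {
    expect_equal(m0$params$head$W, ref$params$head$W)
    expect_equal(m0$params$m1$in_proj$W, ref$params$m1$in_proj$W)
  }
  expect_identical(nrow(m0$log), 0L)
  # identical seeds give bitwise-identical loss curves
  cfg5 <- tiny_model_config(batch_size = 16, iterations = 5)
  mA <- train_model(ds, cfg5)
  mB <- train_model(ds, cfg5)
  expect_identical(mA$log$loss, mB$log$loss)
  # loss trends down over the first 50 steps on the separable fixture
  cfg50 <- tiny_model_config(batch_size = 16, iterations = 50)
  m50 <- train_model(ds, cfg50)
  expect_lt(mean(tail(m50$log$loss, 10)), mean(head(m50$log$loss, 10)))
  expect_lt(min(m50$log$loss), m50$log$loss[1])
})

test_that("checkpoints restore identical predictions", {
  sc <- synth_config(n_samples = 10, seed = 66, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  m <- train_model(ds, tiny_model_config(batch_size = 8, iterations = 3))
  before <- predict_model(m, ds)$prob
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  after <- predict_model(m2, ds)$prob
  expect_equal(after, before, tolerance = 1e-7)
})

test_that("ablation toggles change parameter counts as expected", {
  sc <- synth_config(n_samples = 8, seed = 67, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  full <- count_parameters(init_model(ds, tiny_model_config()))
  no_cm <- count_parameters(init_model(ds,
                                       tiny_model_config(no_fusion = TRUE)))
  no_cv <- count_parameters(init_model(ds,
                                       tiny_model_config(no_conv = TRUE)))
  tr <- count_parameters(init_model(ds,
                                    tiny_model_config(transformer_for_mamba = TRUE)))
  ap <- count_parameters(init_model(ds,
                                    tiny_model_config(pooling = "attention")))
  expect_lt(no_cm, full)
  expect_lt(no_cv, full)
  expect_false(tr == full)
  expect_identical(ap, full + tiny_model_config()$d_model)
})

test_that("softmax head trains through the categorical loss", {
  sc <- synth_config(n_samples = 25, seed = 68, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  cfg <- tiny_model_config(batch_size = 16, iterations = 10,
                           head = "softmax")
  m <- train_model(ds, cfg)
  P <- forward(m, ds)
  expect_equal(rowSums(P), rep(1, length(ds)), tolerance = 1e-9)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
})

test_that("forward exposes normalized attention weights for export", {
  sc <- synth_config(n_samples = 4, seed = 70, signal_strength = 1,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  m <- fit_pca(init_model(ds, tiny_model_config()), ds)
  P <- forward(m, ds)
  aw <- attr(P, "attn_weights")
  expect_length(aw$refine_ab, 4)
  names(aw$refine_ab) <- vapply(ds, `[[`, character(1), "id")
  tab <- export_attention_weights(aw$refine_ab)
  expect_setequal(unique(tab$pair), vapply(ds, `[[`, character(1), "id"))
  sums <- tapply(tab$weight, list(tab$pair, tab$query), sum)
  expect_true(all(abs(sums - 1) < 1e-9, na.rm = TRUE))
})
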