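test_that("confusion counts tabulate true versus predicted labels", {
  labs <- ddi_labels()
  perfect <- confusion_counts(labs, labs)
  expect_true(all(perfect[upper.tri(perfect)] == 0))
  expect_true(all(diag(perfect) == 1))
  single <- confusion_counts("Effect", "Int")
  expect_identical(sum(single), 1L)
  expect_identical(unname(single["Int", "Effect"]), 1L)
  set.seed(71)
  true <- sample(labs, 100, replace = TRUE)
  pred <- sample(labs, 100, replace = TRUE)
  cm <- confusion_counts(pred, true)
  expect_identical(sum(cm), 100L)
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(factor(true, levels = labs)))))
  expect_error(confusion_counts(c("Advice"), c("Wat")), "unknown")
  expect_error(confusion_counts("Advice", c("Advice", "Int")), "length")
})

test_that("per-class precision and recall follow the counting formulas", {
  # one class predicted 10 times with 7 hits out of 8 true instances
  cm <- matrix(0, 5, 5, dimnames = list(ddi_labels(), ddi_labels()))
  cm["Effect", "Effect"] <- 7
  cm["Effect", "Negative"] <- 1      # missed true Effect
  cm["Advice", "Effect"] <- 3        # false Effect predictions
  cm["Advice", "Advice"] <- 10
  pr <- precision_recall_per_class(cm)
  eff <- pr[pr$class == "Effect", ]
  expect_equal(eff$precision, 0.7)
  expect_equal(eff$recall, 0.875)
  # perfect classifier
  prp <- precision_recall_per_class(diag(4))
  expect_true(all(prp$precision == 1) && all(prp$recall == 1))
  # zero-denominator cases return 0 with a flag
  cm0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm0[1, 1] <- 5
  pr0 <- precision_recall_per_class(cm0)
  expect_true(all(pr0$precision[2:3] == 0))
  expect_true(all(pr0$precision_undefined[2:3]))
  # random tables match the direct formula
  set.seed(72)
  for (k in 1:20) {
    cm <- matrix(rpois(25, 4), 5, 5,
                 dimnames = list(ddi_labels(), ddi_labels()))
    pr <- precision_recall_per_class(cm)
    for (i in 1:5) {
      pexp <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
      rexp <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
      expect_equal(pr$precision[i], pexp)
      expect_equal(pr$recall[i], rexp)
    }
  }
})

test_that("F1 is the harmonic mean with the degenerate case at zero", {
  expect_equal(f1_harmonic(0.5, 0.5), 0.5)
  expect_equal(f1_harmonic(0, 0), 0)
  expect_equal(round(f1_harmonic(94.6, 93.9), 1), 94.2)
  expect_equal(round(f1_harmonic(82.97, 80.13), 1), 81.5)
  set.seed(73)
  p <- runif(10); r <- runif(10)
  expect_equal(f1_harmonic(p, r), 2 * p * r / (p + r))
})

test_that("macro averaging is the unweighted class mean", {
  mm <- macro_metrics(rep(1, 5), rep(1, 5))
  expect_equal(mm$macro_precision, 1)
  expect_equal(mm$f1, 1)
  expect_equal(macro_metrics(c(1, 0, 0, 0, 0), rep(1, 5))$macro_precision,
               0.2)
  set.seed(74)
  P <- runif(5); R <- runif(5)
  mm <- macro_metrics(P, R)
  expect_equal(mm$macro_precision, sum(P) / 5)
  expect_equal(mm$f1, 2 * mean(P) * mean(R) / (mean(P) + mean(R)))
})

test_that("rank AUC matches the double loop and handles ties", {
  expect_equal(auc_rank(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc_rank(rep(1, 4), rep(1, 6)), 0.5)
  expect_error(auc_rank(numeric(0), 1), "empty")
  set.seed(75)
  for (k in 1:200) {
    pos <- sample(0:10, sample(1:12, 1), replace = TRUE) / 10
    neg <- sample(0:10, sample(1:12, 1), replace = TRUE) / 10
    expect_equal(auc_rank(pos, neg), oracle_auc_double_loop(pos, neg),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  pos <- rnorm(30); neg <- rnorm(40)
  expect_equal(auc_rank(exp(pos), exp(neg)), auc_rank(pos, neg),
               tolerance = 1e-12)
})

test_that("stratified folds are disjoint, covering and proportionate", {
  labs <- rep(c("A", "B"), each = 50)
  f <- stratified_kfold(labs, k = 5, seed = 2)
  expect_length(unlist(f), 100)
  expect_identical(sort(unlist(f)), 1:100)
  for (j in 1:5) {
    expect_identical(as.vector(table(labs[f[[j]]])), c(10L, 10L))
  }
  expect_identical(stratified_kfold(labs, 5, 2), f)
  expect_false(identical(stratified_kfold(labs, 5, 3), f))
  expect_error(stratified_kfold(c(rep("A", 10), "B"), k = 5), "B")
  # corpus-proportioned audit at the combined dataset size
  cnt <- colSums(ddi_corpus_counts())
  big <- rep(names(cnt), cnt)
  expect_identical(length(big), 16009L)
  fb <- stratified_kfold(big, k = 5, seed = 4)
  sizes <- lengths(fb)
  expect_true(all(abs(sizes - 16009 / 5) <= 1))
  for (j in 1:5) {
    tab <- table(factor(big[fb[[j]]], levels = names(cnt)))
    expect_true(all(abs(tab - cnt / 5) <= 1))
  }
})

test_that("cross-validation guards and the majority baseline close form", {
  sc <- synth_config(n_samples = 60, seed = 81, signal_strength = 0,
                     class_probabilities = rep(0.2, 5))
  ds <- gen_pair_dataset(sc)
  expect_error(cross_validate(ds, tiny_model_config(), k = 1), "at least 2")
  cv <- cross_validate(ds, tiny_model_config(), k = 2, seed = 5,
                       classifier = "majority")
  labs <- vapply(ds, `[[`, character(1), "label")
  maj <- names(which.max(table(labs)))
  for (j in 1:2) {
    rep_ <- cv$folds[[j]]
    pc <- rep_$per_class
    expect_equal(pc$recall[pc$class == maj], 1)
    other <- setdiff(ddi_labels(), maj)
    present <- other[other %in% labs[stratified_kfold(labs, 2, 5)[[j]]]]
    expect_true(all(pc$recall[pc$class %in% present] == 0))
  }
  # the mean is the unweighted average of the per-fold metrics
  expect_equal(cv$mean$macro_recall,
               mean(vapply(cv$folds, `[[`, numeric(1), "macro_recall")))
})

test_that("excluding the negative class changes only the averaging set", {
  labs <- ddi_labels()
  set.seed(82)
  true <- sample(labs, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.6, true, sample(labs, 200, replace = TRUE))
  full <- metrics_report(pred, true)
  nf <- metrics_report(pred, true, exclude_negative = TRUE)
  pos <- setdiff(labs, "Negative")
  expect_equal(nf$per_class[nf$per_class$class %in% pos, c("precision",
                                                           "recall", "f1")],
               full$per_class[full$per_class$class %in% pos,
                              c("precision", "recall", "f1")])
  sel <- full$per_class$class %in% pos
  expect_equal(nf$macro_precision, mean(full$per_class$precision[sel]))
})
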