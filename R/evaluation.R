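# Relation-classification evaluation: per-class and macro precision /
# recall / F1 from the confusion table, rank AUC with tie handling, and
# stratified k-fold cross-validation bookkeeping.

#' Confusion counts for a label set
#'
#' @param predicted,true Character vectors of equal length with values in
#'   `labels`.
#' @param labels Label universe (default [ddi_labels()]).
#' @return Integer matrix: entry `(i, j)` counts samples of true class `i`
#'   predicted as class `j`.
#' @export
confusion_counts <- function(predicted, true, labels = ddi_labels()) {
  if (length(predicted) != length(true)) {
    stop("confusion_counts: length mismatch")
  }
  bad <- setdiff(unique(c(predicted, true)), labels)
  if (length(bad)) {
    stop("confusion_counts: unknown label(s): ", paste(bad, collapse = ", "))
  }
  table(factor(true, levels = labels), factor(predicted, levels = labels))
}

#' Per-class precision and recall from a confusion table
#'
#' `P_l` = correct predictions of class `l` over all predictions of `l`
#' (column sum); `R_l` = over all true instances of `l` (row sum).
#' Zero-denominator cases return 0, flagged in the `undefined` columns.
#'
#' @param confusion Square confusion matrix (rows = true).
#' @return `data.frame` with `class`, `precision`, `recall`,
#'   `precision_undefined`, `recall_undefined`.
#' @export
precision_recall_per_class <- function(confusion) {
  confusion <- as.matrix(unclass(confusion))
  stopifnot(nrow(confusion) == ncol(confusion))
  dg <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum_ <- rowSums(confusion)
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  data.frame(class = cls,
             precision = ifelse(colsum > 0, dg / colsum, 0),
             recall = ifelse(rowsum_ > 0, dg / rowsum_, 0),
             precision_undefined = colsum == 0,
             recall_undefined = rowsum_ == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Harmonic-mean F1
#'
#' `F1 = 2 P R / (P + R)`, defined as 0 when both are 0. Accepts values on
#' the \[0, 1\] or percentage scale (the scale is preserved).
#'
#' @param P,R Precision and recall (vectors recycle).
#' @return F1 on the same scale as the inputs.
#' @export
#' @examples
#' f1_harmonic(94.6, 93.9)  # 94.2 at one decimal
f1_harmonic <- function(P, R) {
  ifelse(P + R == 0, 0, 2 * P * R / (P + R))
}

#' Macro-averaged metrics over the label set
#'
#' Macro precision and recall are unweighted class means; the overall F1
#' is the harmonic mean of macro precision and macro recall.
#'
#' @param P_l,R_l Per-class precision and recall (same length and order).
#' @return List with `macro_precision`, `macro_recall`, `f1`.
#' @export
macro_metrics <- function(P_l, R_l) {
  stopifnot(length(P_l) == length(R_l))
  P <- mean(P_l); R <- mean(R_l)
  list(macro_precision = P, macro_recall = R, f1 = f1_harmonic(P, R))
}

#' Rank AUC with tie handling
#'
#' Probability that a positive score exceeds a negative score, ties
#' counted 0.5 (the normalized Mann-Whitney U statistic); invariant under
#' strictly monotone transforms of all scores.
#'
#' @param pos,neg Numeric score vectors (both non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(pos, neg) {
  P <- length(pos); N <- length(neg)
  if (P < 1 || N < 1) stop("auc_rank: empty score class")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(P)]) - P * (P + 1) / 2) / (P * N)
}

# macro one-vs-rest AUC over the label set; classes absent from `true`
# are skipped
macro_ovr_auc <- function(prob, true, labels = ddi_labels()) {
  aucs <- vapply(labels, function(l) {
    is_pos <- true == l
    if (!any(is_pos) || all(is_pos)) return(NA_real_)
    auc_rank(prob[is_pos, l], prob[!is_pos, l])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Full metrics report for a prediction set
#'
#' Per-class precision/recall/F1, macro averages, one-vs-rest AUC (when
#' probability scores are supplied) and the confusion table. With
#' `exclude_negative`, the `Negative` class is removed from the averaging
#' set only; per-class values of the positive classes are unchanged.
#'
#' @param predicted,true Label vectors.
#' @param prob Optional probability matrix (columns named by labels).
#' @param exclude_negative Average over the four positive classes only.
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(predicted, true, prob = NULL,
                           exclude_negative = FALSE) {
  labels <- ddi_labels()
  cm <- confusion_counts(predicted, true, labels)
  pr <- precision_recall_per_class(cm)
  pr$f1 <- f1_harmonic(pr$precision, pr$recall)
  avg_set <- if (exclude_negative) setdiff(labels, "Negative") else labels
  sel <- pr$class %in% avg_set
  mm <- macro_metrics(pr$precision[sel], pr$recall[sel])
  auc <- if (!is.null(prob)) macro_ovr_auc(prob, true, avg_set) else NA_real_
  structure(list(per_class = pr, confusion = cm,
                 macro_precision = mm$macro_precision,
                 macro_recall = mm$macro_recall, f1 = mm$f1,
                 macro_f1 = mean(pr$f1[sel]),
                 auc = auc, n = length(true),
                 excluded_negative = exclude_negative),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", x$n, "samples",
      if (x$excluded_negative) "(Negative excluded from averaging)", "\n")
  df <- x$per_class
  df$precision <- round(100 * df$precision, 1)
  df$recall <- round(100 * df$recall, 1)
  df$f1 <- round(100 * df$f1, 1)
  print(df[, c("class", "precision", "recall", "f1")])
  cat(sprintf("macro P %.1f%%  macro R %.1f%%  F1 %.1f%%  macro-F1 %.1f%%",
              100 * x$macro_precision, 100 * x$macro_recall, 100 * x$f1,
              100 * x$macro_f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.1f%%", 100 * x$auc))
  cat("\n")
  invisible(x)
}

#' Evaluate a trained model on labeled samples
#'
#' @param model Trained `ddi_model`.
#' @param samples Labeled `pair_sample` list.
#' @param exclude_negative Average positive classes only.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, samples, exclude_negative = FALSE) {
  pred <- predict_model(model, samples)
  true <- vapply(samples, `[[`, character(1), "label")
  metrics_report(pred$label, true, pred$prob, exclude_negative)
}

#' Stratified k-fold split
#'
#' Shuffles each class independently (seeded) and deals its members
#' round-robin over the folds, so per-fold class counts differ from the
#' proportional share by at most one sample.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return A `fold_split`: list of disjoint index vectors covering
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < k]
  if (length(small)) {
    stop("stratified_kfold: class(es) smaller than k = ", k, ": ",
         paste(small, collapse = ", "))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  folds <- vector("list", k)
  start <- 0L
  for (cl in names(cnt)) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so overall fold sizes also
    # stay within one sample of each other
    f <- ((seq_along(idx) - 1L + start) %% k) + 1L
    start <- (start + length(idx)) %% k
    for (j in seq_len(k)) {
      folds[[j]] <- c(folds[[j]], idx[f == j])
    }
  }
  structure(lapply(folds, sort), class = "fold_split",
            labels = labels, k = k, seed = seed)
}

#' Stratified cross-validation of the full pipeline
#'
#' Trains on k-1 folds and evaluates on the held-out fold, k times;
#' oversampling and class weighting happen inside each training fold only.
#' Per-fold seeds are derived from the master seed.
#'
#' @param samples Labeled `pair_sample` list.
#' @param config A [model_config()]; `config$classifier = "majority"`
#'   selects the dummy majority-class baseline instead of the full model.
#' @param k Number of folds (>= 2).
#' @param seed Master seed for fold assignment and per-fold training.
#' @param classifier `"model"` (default) or `"majority"` (dummy baseline
#'   predicting the most frequent training class, scores = class
#'   frequencies).
#' @param exclude_negative Average positive classes only.
#' @return List with `folds` (per-fold [metrics_report()]s) and `mean`
#'   (unweighted means of the macro metrics across folds).
#' @export
cross_validate <- function(samples, config, k = 5, seed = 1,
                           classifier = c("model", "majority"),
                           exclude_negative = FALSE) {
  if (k < 2) stop("cross_validate: k must be at least 2")
  classifier <- match.arg(classifier)
  labels_all <- vapply(samples, `[[`, character(1), "label")
  folds <- stratified_kfold(labels_all, k, seed)
  reports <- vector("list", k)
  for (j in seq_len(k)) {
    test_idx <- folds[[j]]
    train_idx <- setdiff(seq_along(samples), test_idx)
    true <- labels_all[test_idx]
    if (classifier == "majority") {
      tr <- table(labels_all[train_idx])
      maj <- names(tr)[which.max(tr)]
      pred <- rep(maj, length(test_idx))
      freq <- as.vector(tr[ddi_labels()]) / sum(tr)
      freq[is.na(freq)] <- 0
      prob <- matrix(freq, length(test_idx), length(ddi_labels()),
                     byrow = TRUE, dimnames = list(NULL, ddi_labels()))
      reports[[j]] <- metrics_report(pred, true, prob, exclude_negative)
    } else {
      cfg <- config
      cfg$seed <- config$seed + j
      fit <- train_model(samples[train_idx], cfg)
      reports[[j]] <- evaluate_model(fit, samples[test_idx],
                                     exclude_negative)
    }
  }
  pick <- function(f) vapply(reports, `[[`, numeric(1), f)
  list(folds = reports,
       mean = list(macro_precision = mean(pick("macro_precision")),
                   macro_recall = mean(pick("macro_recall")),
                   f1 = mean(pick("f1")),
                   macro_f1 = mean(pick("macro_f1")),
                   auc = mean(pick("auc"))))
}
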