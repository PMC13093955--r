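# Seeded generator of schema-conformant drug-pair corpora. Class imbalance
# follows the filtered DDIExtraction2013 training distribution by default;
# a planted, learnable class signal is placed in two modalities (a
# class-specific sentence token and a class-specific SMILES fragment on one
# drug of the pair) with configurable incidence, so channel ablations
# measurably degrade synthetic performance. SMILES are built from a closed
# template grammar (heteroatom-sparse carbon chains, optional aromatic
# ring) that guarantees chemical validity without an external database.

# filler lexicon for sentences and descriptions (no stop words, no class
# motifs)
synth_lexicon <- function() {
  c("patients", "dose", "plasma", "concentration", "therapy", "clinical",
    "oral", "daily", "study", "treatment", "levels", "observed",
    "reported", "administration", "serum", "renal", "hepatic", "effects",
    "response", "exposure", "trial", "combination", "groups",
    "significant", "subjects", "healthy", "single", "repeated",
    "pharmacokinetics", "absorption", "metabolism", "clearance",
    "receptor", "enzyme", "protein", "binding", "tablet", "infusion",
    "steady", "state")
}

#' Class motifs planted by the synthetic generator
#'
#' One sentence token and one SMILES fragment per relation type. SMILES
#' fragments are short heteroatom runs whose character trigrams do not
#' occur in the background chains (which never place two heteroatoms
#' adjacently); fragments degrade gracefully when the configured alphabet
#' lacks heteroatoms.
#'
#' @param alphabet SMILES alphabet in use.
#' @return List with `token` and `smiles` named character vectors (one
#'   entry per label).
#' @export
synth_motifs <- function(alphabet = c("C", "N", "O", "c", "1", "(", ")", "=")) {
  labels <- ddi_labels()
  tokens <- c(Advice = "recommended", Mechanism = "inhibits",
              Effect = "potentiates", Int = "interacts",
              Negative = "unchanged")
  het <- intersect(c("N", "O"), alphabet)
  smi <- if (length(het) >= 2) {
    c(Advice = "NNN", Mechanism = "OOO", Effect = "NNO",
      Int = "ONN", Negative = "NOO")
  } else if (length(het) == 1) {
    stats::setNames(vapply(seq_along(labels), function(i) {
      paste(rep(het, i + 1), collapse = "")
    }, character(1)), labels)
  } else {
    stats::setNames(vapply(seq_along(labels), function(i) {
      paste(rep("C", i + 4), collapse = "")
    }, labels), labels)
  }
  list(token = tokens, smiles = smi[labels])
}

#' Synthetic-corpus configuration
#'
#' @param n_samples Number of drug-pair samples.
#' @param seed RNG seed (mandatory; the generator is fully deterministic
#'   given the seed).
#' @param class_probabilities Named probabilities over [ddi_labels()];
#'   default proportional to the filtered DDIExtraction2013 training
#'   counts (824 / 1675 / 1309 / 188 / 8987).
#' @param signal_strength Probability in \[0, 1\] that a sample carries its
#'   class motif (sentence token + SMILES fragment); at 0 the labels are
#'   independent of content.
#' @param smiles_alphabet Characters the generated SMILES may use (subset
#'   of [smiles_alphabet66()]).
#' @param n_drugs Size of the base drug pool.
#' @param sentence_len,desc_len,smiles_len Length ranges (2-vectors).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_samples, seed,
                         class_probabilities = NULL,
                         signal_strength = 0.9,
                         smiles_alphabet = c("C", "N", "O", "c", "1",
                                             "(", ")", "="),
                         n_drugs = max(20L, ceiling(n_samples / 25)),
                         sentence_len = c(6, 14), desc_len = c(3, 8),
                         smiles_len = c(4, 12)) {
  if (missing(seed)) stop("synth_config: seed is mandatory")
  labels <- ddi_labels()
  if (is.null(class_probabilities)) {
    cnt <- ddi_corpus_counts()["train", ]
    class_probabilities <- cnt / sum(cnt)
  }
  stopifnot(length(class_probabilities) == length(labels),
            abs(sum(class_probabilities) - 1) < 1e-8,
            signal_strength >= 0, signal_strength <= 1,
            all(smiles_alphabet %in% smiles_alphabet66()),
            n_samples >= 1)
  if (is.null(names(class_probabilities))) {
    names(class_probabilities) <- labels
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 class_probabilities = class_probabilities[labels],
                 signal_strength = signal_strength,
                 smiles_alphabet = smiles_alphabet,
                 n_drugs = as.integer(n_drugs),
                 sentence_len = sentence_len, desc_len = desc_len,
                 smiles_len = smiles_len),
            class = "synth_config")
}

# one template SMILES: carbon chain with isolated heteroatoms, optional
# aromatic ring when the alphabet allows it
gen_smiles_chain <- function(config) {
  alpha <- config$smiles_alphabet
  atoms <- intersect(c("C", "N", "O"), alpha)
  if (length(atoms) == 0) atoms <- alpha[1]
  het <- setdiff(atoms, "C")
  L <- sample(config$smiles_len[1]:config$smiles_len[2], 1)
  chars <- character(L)
  prev_het <- TRUE  # never start with a heteroatom either
  for (i in seq_len(L)) {
    if (!prev_het && length(het) && stats::runif(1) < 0.2) {
      chars[i] <- sample(het, 1)
      prev_het <- TRUE
    } else {
      chars[i] <- if ("C" %in% atoms) "C" else atoms[1]
      prev_het <- FALSE
    }
  }
  s <- paste(chars, collapse = "")
  if (all(c("c", "1") %in% alpha) && stats::runif(1) < 0.3) {
    s <- paste0(s, "c1ccccc1")
  }
  s
}

#' Generate synthetic drug records
#'
#' SMILES come from the closed template grammar (guaranteed parseable and
#' canonicalizable); descriptions are token sequences from a fixed
#' synthetic lexicon. Deterministic per `config$seed`.
#'
#' @param n Number of records.
#' @param config A [synth_config()].
#' @return List of [drug_record()] objects.
#' @export
gen_drug_records <- function(n, config) {
  stopifnot(n >= 1, inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lex <- synth_lexicon()
  lapply(seq_len(n), function(i) {
    nd <- sample(config$desc_len[1]:config$desc_len[2], 1)
    drug_record(sprintf("drug_%04d", i),
                gen_smiles_chain(config),
                paste(sample(lex, nd, replace = TRUE), collapse = " "))
  })
}

#' Generate a synthetic drug-pair corpus
#'
#' Labels are drawn from `class_probabilities`. With probability
#' `signal_strength` a sample carries its class motif: the class sentence
#' token inserted at a random sentence position and the class SMILES
#' fragment appended to one randomly chosen drug of the pair. At
#' `signal_strength = 0` content is independent of the label.
#'
#' @param config A [synth_config()].
#' @return List of `pair_sample` objects of length `config$n_samples`.
#' @export
gen_pair_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lex <- synth_lexicon()
  labels <- ddi_labels()
  motifs <- synth_motifs(config$smiles_alphabet)
  # base drug pool (drawn inside the same stream for full determinism)
  pool <- lapply(seq_len(config$n_drugs), function(i) {
    nd <- sample(config$desc_len[1]:config$desc_len[2], 1)
    drug_record(sprintf("drug_%04d", i),
                gen_smiles_chain(config),
                paste(sample(lex, nd, replace = TRUE), collapse = " "))
  })
  lapply(seq_len(config$n_samples), function(i) {
    lab <- sample(labels, 1, prob = config$class_probabilities)
    da <- pool[[sample.int(config$n_drugs, 1)]]
    db <- pool[[sample.int(config$n_drugs, 1)]]
    ns <- sample(config$sentence_len[1]:config$sentence_len[2], 1)
    toks <- sample(lex, ns, replace = TRUE)
    if (stats::runif(1) < config$signal_strength) {
      pos <- sample.int(ns + 1, 1) - 1
      toks <- append(toks, motifs$token[[lab]], after = pos)
      if (stats::runif(1) < 0.5) {
        da$smiles <- paste0(da$smiles, motifs$smiles[[lab]])
      } else {
        db$smiles <- paste0(db$smiles, motifs$smiles[[lab]])
      }
    }
    pair_sample(toks, da, db, lab, id = sprintf("s%05d", i))
  })
}

#' Planted-signal incidence per class
#'
#' Reports, for each relation type, the fraction of its samples whose
#' sentence carries the class motif token; equals the generator's
#' `signal_strength` up to binomial error.
#'
#' @param dataset Output of [gen_pair_dataset()].
#' @param alphabet SMILES alphabet used at generation (for the motif
#'   table).
#' @return `data.frame` with `class`, `n`, `incidence`.
#' @export
planted_signal_report <- function(dataset,
                                  alphabet = c("C", "N", "O", "c", "1",
                                               "(", ")", "=")) {
  motifs <- synth_motifs(alphabet)
  labs <- vapply(dataset, `[[`, character(1), "label")
  has <- vapply(dataset, function(s) {
    motifs$token[[s$label]] %in% s$sentence_tokens
  }, logical(1))
  out <- do.call(rbind, lapply(ddi_labels(), function(l) {
    sel <- labs == l
    data.frame(class = l, n = sum(sel),
               incidence = if (any(sel)) mean(has[sel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
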