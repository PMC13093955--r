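#' DDI relation label set
#'
#' The five relation types of the DDIExtraction2013 task, in canonical order:
#' `Advice`, `Mechanism`, `Effect`, `Int` and `Negative` (no interaction).
#'
#' @param include_negative If `FALSE`, return only the four positive types
#'   (the negative-filtered evaluation mode).
#' @return Character vector of labels.
#' @export
ddi_labels <- function(include_negative = TRUE) {
  labs <- c("Advice", "Mechanism", "Effect", "Int", "Negative")
  if (include_negative) labs else labs[1:4]
}

#' DDIExtraction2013 class distribution after filtering
#'
#' Per-class instance counts of the filtered DDIExtraction2013 corpus
#' (SemEval-2013 Task 9.2) under its standard train/test split. These printed
#' counts are used as the imbalance template of the synthetic generator and
#' for oversampling/manifest bookkeeping; the corpus itself is never read.
#'
#' @return Integer matrix with rows `train`/`test` and one column per label.
#' @export
#' @examples
#' ddi_corpus_counts()["train", ]
ddi_corpus_counts <- function() {
  m <- rbind(
    train = c(Advice = 824L, Mechanism = 1309L, Effect = 1675L,
              Int = 188L, Negative = 8987L),
    test = c(Advice = 221L, Mechanism = 301L, Effect = 359L,
             Int = 96L, Negative = 2049L)
  )
  m[, ddi_labels()]
}

#' English stop-word list
#'
#' The standard English stop-word list (frozen copy shipped with the package
#' for determinism).
#'
#' @return Character vector of lowercase stop words.
#' @export
english_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "ddimamba")
  readLines(path, encoding = "UTF-8")
}

#' Clean and tokenize free text
#'
#' Lowercases, removes non-alphanumeric characters and extra whitespace,
#' splits on whitespace and removes stop words, preserving token order.
#'
#' @param raw Character scalar (any printable characters).
#' @param stopwords Character vector of words to drop (already lowercase).
#' @return Character vector of clean tokens; empty input yields `character(0)`.
#' @export
#' @examples
#' clean_text("Aspirin, taken WITH warfarin!")
clean_text <- function(raw, stopwords = english_stopwords()) {
  stopifnot(is.character(raw), length(raw) == 1)
  if (is.na(raw) || !nzchar(raw)) return(character(0))
  x <- tolower(raw)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!(toks %in% stopwords)]
}

#' The 66-character SMILES alphabet
#'
#' A fixed 66-token character alphabet covering the organic-subset atoms,
#' aromatic atoms, bracket-atom symbols, bonds, branches, ring-bond digits
#' and charges used by canonical SMILES. Building a vocabulary over this
#' alphabet gives the default dictionary size of 66.
#'
#' @return Character vector of 66 distinct single characters.
#' @export
smiles_alphabet66 <- function() {
  chars <- c(
    as.character(0:9),                              # ring bonds / charges
    "#", "%", "(", ")", "+", "-", "=", "@", "[", "]",
    "/", "\\", ".",                                 # bonds, branches, dots
    "B", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "O", "P", "R", "S", "T", "V", "W", "Z", # element letters
    "a", "b", "c", "e", "g", "i", "l", "n", "o", "p",
    "r", "s", "t", "u",                             # aromatic / 2nd letters
    "*", ":", "~", "$", "d", "f", "h", "m", "y"     # wildcards, rare letters
  )
  stopifnot(length(chars) == 66, !anyDuplicated(chars))
  chars
}

#' Build a SMILES character vocabulary
#'
#' Every character occurring in the corpus is assigned a unique integer id
#' starting at 1; id 0 is reserved for padding. Characters are sorted
#' lexicographically (C locale) before id assignment so the vocabulary is
#' deterministic for a given character set.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @return A `smiles_vocab`: list with `token_to_id` (named integer vector)
#'   and `pad_id = 0`.
#' @export
#' @examples
#' v <- build_smiles_vocab(c("CCO"))
#' v$token_to_id
build_smiles_vocab <- function(corpus) {
  stopifnot(is.character(corpus), length(corpus) >= 1)
  chars <- unique(unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE))
  prev <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  chars <- sort(chars)
  ids <- seq_along(chars)
  names(ids) <- chars
  structure(list(token_to_id = ids, pad_id = 0L), class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES character vocabulary:", length(x$token_to_id),
      "tokens (+ pad id 0)\n")
  invisible(x)
}

#' Tokenize a SMILES string to fixed-length id and mask lists
#'
#' Looks up the id of each character in the vocabulary to produce the id
#' list, then pads (with `pad_id`) or head-truncates to `max_len`; the mask
#' is 1 at real-token positions and 0 at padding.
#'
#' @param smiles SMILES string; every character must be in `vocab`.
#' @param vocab A [build_smiles_vocab()] vocabulary.
#' @param max_len Positive integer target length.
#' @return A `tokenized_smiles`: list with integer `ids` and `mask`, both of
#'   length `max_len`.
#' @export
tokenize_smiles <- function(smiles, vocab, max_len) {
  stopifnot(inherits(vocab, "smiles_vocab"), max_len >= 1)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  ids <- unname(vocab$token_to_id[chars])
  if (length(chars) && anyNA(ids)) {
    bad <- unique(chars[is.na(ids)])
    stop("tokenize_smiles: character(s) not in vocabulary: ",
         paste(sQuote(bad), collapse = ", "))
  }
  n <- min(length(ids), max_len)
  out_ids <- rep(vocab$pad_id, max_len)
  out_mask <- integer(max_len)
  if (n > 0) {
    out_ids[seq_len(n)] <- ids[seq_len(n)]
    out_mask[seq_len(n)] <- 1L
  }
  structure(list(ids = as.integer(out_ids), mask = out_mask),
            class = "tokenized_smiles")
}

#' Recover the character string from tokenized SMILES
#'
#' Inverse of [tokenize_smiles()] on the unpadded prefix.
#'
#' @param ts A `tokenized_smiles`.
#' @param vocab The vocabulary used to tokenize.
#' @return Character scalar (possibly truncated relative to the original).
#' @export
detokenize_smiles <- function(ts, vocab) {
  stopifnot(inherits(ts, "tokenized_smiles"), inherits(vocab, "smiles_vocab"))
  ids <- ts$ids[ts$mask == 1L]
  id_to_tok <- names(vocab$token_to_id)[order(vocab$token_to_id)]
  paste(id_to_tok[ids], collapse = "")
}

# Syntactic well-formedness of a SMILES string: balanced parentheses and
# brackets, paired ring-bond digits, no dangling bond symbol, characters
# from the known SMILES character set. This complements the chemistry
# toolkit, which repairs (rather than rejects) some of these defects.
smiles_is_wellformed <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    return(FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9),
               "#", "%", "(", ")", "+", "-", "=", "@", "[", "]", "/", "\\",
               ".", "*", ":", "~", "$")
  if (!all(chars %in% allowed)) return(FALSE)
  depth_p <- 0L; depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    if (ch == ")") { depth_p <- depth_p - 1L; if (depth_p < 0L) return(FALSE) }
    if (ch == "[") { depth_b <- depth_b + 1L; if (depth_b > 1L) return(FALSE) }
    if (ch == "]") { depth_b <- depth_b - 1L; if (depth_b < 0L) return(FALSE) }
  }
  if (depth_p != 0L || depth_b != 0L) return(FALSE)
  # ring-bond digits must pair up; ignore digits inside bracket atoms and
  # treat %nn two-digit closures as units
  stripped <- gsub("\\[[^]]*\\]", "", smiles)
  pct <- regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]]
  if (length(pct) && any(table(pct) %% 2 != 0)) return(FALSE)
  if (grepl("%([0-9]?$|[^0-9])", stripped)) return(FALSE)
  rest <- gsub("%[0-9]{2}", "", stripped)
  digs <- regmatches(rest, gregexpr("[0-9]", rest))[[1]]
  if (length(digs) && any(table(digs) %% 2 != 0)) return(FALSE)
  # a bond symbol must not dangle at either end or before a closing paren
  if (grepl("[=#/\\\\~-]$", smiles)) return(FALSE)
  if (grepl("^[=#~-]", smiles)) return(FALSE)
  if (grepl("[=#/\\\\~-][)]", smiles)) return(FALSE)
  TRUE
}

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to its canonical form via the Open Babel
#' chemistry toolkit. The routine is idempotent (canonical input maps to
#' itself) and returns `NA` for strings that are syntactically malformed or
#' rejected by the toolkit.
#'
#' @param smiles Character scalar.
#' @return Canonical SMILES string, or `NA_character_` if invalid.
#' @export
smiles_canonicalize <- function(smiles) {
  if (!smiles_is_wellformed(smiles)) return(NA_character_)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) ""
  )
  out <- trimws(gsub("[\t\n].*$", "", out))
  if (!nzchar(out)) return(NA_character_)
  out
}

#' Construct a drug record
#'
#' @param drug_id Opaque identifier string.
#' @param smiles SMILES string for the drug's molecular structure.
#' @param description Free-text drug description; tokenized with
#'   [clean_text()] (lowercase, alphanumeric, stop-word-free).
#' @param stopwords Stop-word list used for cleaning.
#' @return A `drug_record` list with `drug_id`, `smiles`,
#'   `description_tokens`.
#' @export
drug_record <- function(drug_id, smiles, description = "",
                        stopwords = english_stopwords()) {
  stopifnot(is.character(drug_id), length(drug_id) == 1,
            is.character(smiles), length(smiles) == 1)
  structure(list(drug_id = drug_id, smiles = smiles,
                 description_tokens = clean_text(description, stopwords)),
            class = "drug_record")
}

#' Construct a drug-pair sample
#'
#' One sentence-level instance: the mention sentence, the two drug records
#' and the DDI relation label.
#'
#' @param sentence Raw sentence text (tokenized with [clean_text()]) or an
#'   already-clean character vector of tokens.
#' @param drug_a,drug_b [drug_record()] objects.
#' @param label One of [ddi_labels()].
#' @param id Optional sample identifier.
#' @param stopwords Stop-word list used when `sentence` is raw text.
#' @return A `pair_sample` list.
#' @export
pair_sample <- function(sentence, drug_a, drug_b, label, id = NULL,
                        stopwords = english_stopwords()) {
  toks <- if (length(sentence) == 1 && grepl("\\s|[A-Z,.!?]", sentence)) {
    clean_text(sentence, stopwords)
  } else {
    as.character(sentence)
  }
  x <- structure(list(id = if (is.null(id)) NA_character_ else id,
                      sentence_tokens = toks,
                      drug_a = drug_a, drug_b = drug_b, label = label),
                 class = "pair_sample")
  validate_pair_sample(x)
  x
}

#' Validate a pair sample
#'
#' Checks the `pair_sample` invariants: known label, at least one sentence
#' token, both drug records structurally valid.
#'
#' @param x A `pair_sample`.
#' @param where Optional context string used in error messages
#'   (e.g. a file line number).
#' @return `x`, invisibly; errors on violation.
#' @export
validate_pair_sample <- function(x, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  if (!is.character(x$label) || length(x$label) != 1 ||
      !(x$label %in% ddi_labels())) {
    stop("invalid label ", sQuote(as.character(x$label)[1]),
         "; expected one of ", paste(ddi_labels(), collapse = ", "), ctx)
  }
  if (length(x$sentence_tokens) < 1) {
    stop("pair sample needs at least one sentence token", ctx)
  }
  for (side in c("drug_a", "drug_b")) {
    d <- x[[side]]
    if (!inherits(d, "drug_record") || !nzchar(d$smiles)) {
      stop(side, " is not a valid drug record (non-empty SMILES required)",
           ctx)
    }
  }
  invisible(x)
}

#' Filter drug records by SMILES validity and length
#'
#' Drops records whose SMILES exceed `max_smiles_len` characters or fail the
#' validity/canonicalization contract; kept records carry the canonical form
#' of their SMILES. Removals are reported, not raised.
#'
#' @param records List of [drug_record()] objects.
#' @param max_smiles_len Maximum SMILES length (default 250).
#' @return List with `kept` (records, canonical SMILES) and `dropped`
#'   (list of `list(record, reason)` with reason `"length"` or `"invalid"`).
#' @export
filter_records <- function(records, max_smiles_len = 250) {
  kept <- list(); dropped <- list()
  for (rec in records) {
    if (nchar(rec$smiles) > max_smiles_len) {
      dropped[[length(dropped) + 1]] <- list(record = rec, reason = "length")
      next
    }
    can <- smiles_canonicalize(rec$smiles)
    if (is.na(can) || nchar(can) > max_smiles_len) {
      reason <- if (is.na(can)) "invalid" else "length"
      dropped[[length(dropped) + 1]] <- list(record = rec, reason = reason)
      next
    }
    rec$smiles <- can
    kept[[length(kept) + 1]] <- rec
  }
  list(kept = kept, dropped = dropped)
}

#' Read drug-pair samples from a JSONL file
#'
#' One JSON object per line with fields `id`, `sentence`,
#' `drug_a`/`drug_b` (each `id`, `smiles`, `description`) and `label`.
#'
#' @param path File path.
#' @param stopwords Stop-word list for text cleaning.
#' @return List of validated `pair_sample` objects.
#' @export
read_pair_samples <- function(path, stopwords = english_stopwords()) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop("parse error at line ", i, ": ",
                           conditionMessage(e))
                    })
    for (f in c("sentence", "drug_a", "drug_b", "label")) {
      if (is.null(obj[[f]])) stop("line ", i, ": missing field ", sQuote(f))
    }
    mk <- function(d) drug_record(as.character(d$id), as.character(d$smiles),
                                  as.character(d$description), stopwords)
    s <- structure(list(
      id = if (is.null(obj$id)) NA_character_ else as.character(obj$id),
      sentence_tokens = clean_text(as.character(obj$sentence), stopwords),
      drug_a = mk(obj$drug_a), drug_b = mk(obj$drug_b),
      label = as.character(obj$label)), class = "pair_sample")
    validate_pair_sample(s, where = paste0("line ", i))
    out[[i]] <- s
  }
  out
}

#' Write drug-pair samples to a JSONL file
#'
#' Inverse of [read_pair_samples()]: one JSON object per line; token lists
#' are rendered as whitespace-joined text (reading the file back recovers
#' the same tokens because cleaning is idempotent on clean text).
#'
#' @param samples List of `pair_sample` objects.
#' @param path Output path.
#' @return Number of records written, invisibly.
#' @export
write_pair_samples <- function(samples, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in samples) {
    validate_pair_sample(s)
    obj <- list(
      id = if (is.na(s$id)) "" else s$id,
      sentence = paste(s$sentence_tokens, collapse = " "),
      drug_a = list(id = s$drug_a$drug_id, smiles = s$drug_a$smiles,
                    description = paste(s$drug_a$description_tokens,
                                        collapse = " ")),
      drug_b = list(id = s$drug_b$drug_id, smiles = s$drug_b$smiles,
                    description = paste(s$drug_b$description_tokens,
                                        collapse = " ")),
      label = s$label
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(length(samples))
}
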