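#' Construct a comparable corpus
#'
#' A comparable corpus is an ordered collection of document pairs with
#' comparable (topic-aligned) content: document `i` on the source side is
#' topically aligned with document `i` on the target side. Documents are
#' either raw character scalars (before [preprocess_corpus()]) or token
#' vectors (after).
#'
#' @param source,target lists of documents (character vectors).
#' @param languages length-2 character vector of language identifiers.
#' @param tokenized logical; whether documents are already token vectors.
#' @return an object of class `comparable_corpus`.
#' @export
comparable_corpus <- function(source, target, languages = c("source", "target"),
                              tokenized = FALSE) {
  if (length(source) != length(target)) {
    stop("alignment error: ", length(source), " source documents vs ",
         length(target), " target documents")
  }
  structure(list(source = source, target = target,
                 languages = as.character(languages), tokenized = tokenized),
            class = "comparable_corpus")
}

#' @export
print.comparable_corpus <- function(x, ...) {
  cat("<comparable_corpus> ", length(x$source), " aligned document pairs (",
      x$languages[1], "-", x$languages[2], "), ",
      if (x$tokenized) "tokenized" else "raw", "\n", sep = "")
  invisible(x)
}

#' @export
length.comparable_corpus <- function(x) length(x$source)

read_doc_paths <- function(path) {
  if (dir.exists(path)) {
    sort_c(list.files(path, full.names = TRUE))
  } else if (file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    stop("I/O error: cannot read '", path, "'")
  }
}

#' Read a comparable corpus from disk
#'
#' Each argument is either a directory of UTF-8 plain-text files (taken in
#' sorted filename order) or a manifest file listing one document path per
#' line. Source and target must supply equally many documents; pairs are
#' aligned by position.
#'
#' @param source_path,target_path directory or manifest path per language.
#' @param languages language identifiers.
#' @return a raw (untokenized) [comparable_corpus()].
#' @export
read_corpus <- function(source_path, target_path,
                        languages = c("source", "target")) {
  fs <- read_doc_paths(source_path)
  ft <- read_doc_paths(target_path)
  if (length(fs) != length(ft)) {
    stop("alignment error: ", length(fs), " source files vs ",
         length(ft), " target files")
  }
  if (length(fs) == 0) {
    warning("empty corpus: no documents found")
  }
  read_one <- function(f) {
    if (!file.exists(f)) stop("I/O error: cannot read '", f, "'")
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
  }
  comparable_corpus(lapply(fs, read_one), lapply(ft, read_one), languages)
}

#' Tokenize and lowercase a document
#'
#' Splits on whitespace, lowercases, and strips leading/trailing
#' non-alphanumeric characters from each token; hyphens and apostrophes
#' inside a token are kept. Empty tokens are dropped, so the rule is
#' idempotent.
#'
#' @param x character vector (a raw document or an existing token vector).
#' @return character vector of tokens.
#' @export
tokenize <- function(x) {
  toks <- unlist(strsplit(tolower(x), "[[:space:]]+"), use.names = FALSE)
  toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Preprocess a comparable corpus
#'
#' Applies [tokenize()] to every document on both sides, preserving document
#' order. Documents that become empty are kept (with a message), so alignment
#' is never broken.
#'
#' @param corpus a [comparable_corpus()].
#' @return the corpus with `tokenized = TRUE`.
#' @export
preprocess_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "comparable_corpus"))
  src <- lapply(corpus$source, tokenize)
  tgt <- lapply(corpus$target, tokenize)
  n_empty <- sum(lengths(src) == 0) + sum(lengths(tgt) == 0)
  if (n_empty > 0) {
    message(n_empty, " document(s) empty after preprocessing")
  }
  comparable_corpus(src, tgt, corpus$languages, tokenized = TRUE)
}

#' Construct a translation lexicon
#'
#' A lexicon is a set of (source term, target term) pairs. Terms may contain
#' single internal spaces separating the words of a multi-word phrase. A
#' source term may appear with several targets (multiple translations);
#' duplicate pairs are collapsed.
#'
#' @param source,target character vectors of equal length.
#' @return a `lexicon` data frame with columns `source` and `target`.
#' @export
lexicon <- function(source = character(), target = character()) {
  stopifnot(length(source) == length(target))
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_key(df$source, df$target)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("lexicon", "data.frame")
  df
}

#' Read a seed lexicon from a two-column TSV file
#'
#' UTF-8, no header, tab-separated: source term, target term. Entries are
#' lowercased to match corpus preprocessing and duplicates collapsed.
#'
#' @param path file path.
#' @return a [lexicon()].
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop("parse error in '", path, "': line ", bad[1], " has ",
         lengths(parts)[bad[1]], " column(s), expected 2")
  }
  m <- do.call(rbind, parts)
  lexicon(tolower(m[, 1]), tolower(m[, 2]))
}

#' Write a lexicon as two-column TSV
#' @param lex a [lexicon()].
#' @param path output file.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(lex$source, lex$target, sep = "\t"), path, useBytes = TRUE)
}

#' Filter a lexicon against the corpus vocabularies
#'
#' Retains exactly the entries whose source term is in the source vocabulary
#' and whose target term is in the target vocabulary, mirroring the common
#' practice of evaluating only pairs observable in the corpus.
#'
#' @param lex a [lexicon()].
#' @param vocab_s,vocab_t [vocabulary()] objects (or character vectors of
#'   terms).
#' @return the filtered [lexicon()].
#' @export
filter_lexicon <- function(lex, vocab_s, vocab_t) {
  ts <- if (is.character(vocab_s)) vocab_s else names(vocab_s)
  tt <- if (is.character(vocab_t)) vocab_t else names(vocab_t)
  keep <- lex$source %in% ts & lex$target %in% tt
  out <- lex[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lexicon", "data.frame")
  out
}

#' Split a lexicon into train / validation / test sets
#'
#' Performs an 80/20 random split into a training portion and a test set,
#' then an 80/20 split of the training portion into train and validation.
#' The split is by lexicon entry, so two translations of the same source may
#' land in different parts. Reproducible for a fixed seed.
#'
#' @param lex a [lexicon()] with at least 5 entries.
#' @param seed integer seed.
#' @return a `split_lexicon` list with elements `train`, `validation`,
#'   `test`, and `seed`.
#' @export
split_lexicon <- function(lex, seed = 1) {
  n <- nrow(lex)
  if (n < 5) stop("lexicon too small to split (", n, " entries, need >= 5)")
  idx <- local_seed(seed, sample.int(n))
  n_test <- round(0.2 * n)
  n_val <- round(0.2 * (n - n_test))
  test_i <- idx[seq_len(n_test)]
  val_i <- idx[n_test + seq_len(n_val)]
  train_i <- idx[-seq_len(n_test + n_val)]
  as_lex <- function(i) {
    out <- lex[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("lexicon", "data.frame")
    out
  }
  structure(list(train = as_lex(train_i), validation = as_lex(val_i),
                 test = as_lex(test_i), seed = seed),
            class = "split_lexicon")
}

#' @export
print.split_lexicon <- function(x, ...) {
  cat("<split_lexicon> train ", nrow(x$train), " / validation ",
      nrow(x$validation), " / test ", nrow(x$test),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Descriptive statistics for a translation lexicon
#'
#' Reports the composition of a lexicon with respect to the corpus
#' vocabularies: the share of phrase-phrase, word-phrase and word-word pairs,
#' the share of source terms with more than one translation, mean corpus
#' frequency of lexicon terms per language, and (when the unfiltered lexicon
#' is supplied) the retention percentage after vocabulary filtering.
#'
#' @param lex the (filtered) [lexicon()].
#' @param vocab_s,vocab_t optional [vocabulary()] objects for frequency
#'   statistics.
#' @param original optional unfiltered [lexicon()] for the retention rate.
#' @return a list of class `lexicon_stats`.
#' @export
lexicon_stats <- function(lex, vocab_s = NULL, vocab_t = NULL,
                          original = NULL) {
  n <- nrow(lex)
  s_phr <- grepl(" ", lex$source, fixed = TRUE)
  t_phr <- grepl(" ", lex$target, fixed = TRUE)
  tab <- table(lex$source)
  mean_freq <- function(vocab, terms) {
    if (is.null(vocab)) return(NA_real_)
    f <- vocab[match(unique(terms), names(vocab))]
    mean(f, na.rm = TRUE)
  }
  out <- list(
    n_entries = n,
    retention_pct = if (is.null(original)) NA_real_ else 100 * n / nrow(original),
    phrase_phrase_pct = 100 * mean(s_phr & t_phr),
    word_phrase_pct = 100 * mean(xor(s_phr, t_phr)),
    word_word_pct = 100 * mean(!s_phr & !t_phr),
    multi_translation_pct = 100 * mean(tab > 1),
    mean_source_freq = mean_freq(vocab_s, lex$source),
    mean_target_freq = mean_freq(vocab_t, lex$target)
  )
  class(out) <- "lexicon_stats"
  out
}

#' @export
print.lexicon_stats <- function(x, ...) {
  cat("<lexicon_stats>\n")
  cat(sprintf("  entries:            %d\n", x$n_entries))
  if (!is.na(x$retention_pct))
    cat(sprintf("  retention:          %.2f%%\n", x$retention_pct))
  cat(sprintf("  phrase-phrase:      %.2f%%\n", x$phrase_phrase_pct))
  cat(sprintf("  word-phrase:        %.2f%%\n", x$word_phrase_pct))
  cat(sprintf("  word-word:          %.2f%%\n", x$word_word_pct))
  cat(sprintf("  multi-translation:  %.2f%%\n", x$multi_translation_pct))
  if (!is.na(x$mean_source_freq))
    cat(sprintf("  mean source freq:   %.1f\n", x$mean_source_freq))
  if (!is.na(x$mean_target_freq))
    cat(sprintf("  mean target freq:   %.1f\n", x$mean_target_freq))
  invisible(x)
}
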