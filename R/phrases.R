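#' Phrase extraction configuration
#'
#' @param threshold positive real; bigrams scoring above it are merged.
#' @param delta discount subtracted from the bigram count, preventing phrases
#'   made of very infrequent words.
#' @param iterations number of merge passes; pass `k` can produce phrases of
#'   up to `k + 1` words (4 iterations yield n-grams up to length 5).
#' @return a `phrase_config` list.
#' @export
phrase_config <- function(threshold = 6, delta = 5, iterations = 4) {
  stopifnot(threshold > 0, iterations >= 1)
  structure(list(threshold = threshold, delta = delta,
                 iterations = as.integer(iterations)),
            class = "phrase_config")
}

#' Collocation score of a bigram
#'
#' `score = (count_ij - delta) / (count_i * count_j) * v_size`, where
#' `v_size` is the number of distinct token types in the current corpus.
#' High-scoring bigrams co-occur far more often than their unigram
#' frequencies predict.
#'
#' @param count_ij bigram count.
#' @param count_i,count_j unigram counts (must be positive).
#' @param delta discount.
#' @param v_size vocabulary (type) count.
#' @return numeric score, vectorized over its arguments.
#' @export
bigram_score <- function(count_ij, count_i, count_j, delta, v_size) {
  if (any(count_i <= 0) || any(count_j <= 0)) {
    stop("unigram counts must be positive")
  }
  (count_ij - delta) / (count_i * count_j) * v_size
}

# greedy left-to-right non-overlapping merge of flagged adjacent positions
merge_doc <- function(tokens, mergeable) {
  n <- length(tokens)
  keep <- rep(TRUE, n)
  out <- tokens
  i <- 1L
  while (i < n) {
    if (mergeable[i]) {
      out[i] <- paste(out[i], tokens[i + 1L])
      keep[i + 1L] <- FALSE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out[keep]
}

#' Iterative collocation-based phrase extraction
#'
#' Runs `iterations` merge passes over the token sequences. In each pass,
#' every adjacent token bigram is scored with [bigram_score()] (with the
#' type count of the current pass as `|V|`); bigrams scoring above the
#' threshold are merged greedily left to right into a single phrase token
#' (component words joined by single spaces), provided the merged phrase
#' does not exceed `pass + 1` words. Merged tokens are treated as ordinary
#' tokens in later passes.
#'
#' @param docs list of token vectors (one language side, preprocessed).
#' @param config a [phrase_config()].
#' @return list with `docs` (retokenized token vectors) and `phrases`
#'   (character vector of extracted phrase tokens).
#' @export
extract_phrases <- function(docs, config = phrase_config()) {
  stopifnot(inherits(config, "phrase_config"))
  for (iter in seq_len(config$iterations)) {
    uni <- table(unlist(docs, use.names = FALSE))
    v_size <- length(uni)
    if (v_size < 2) break
    max_words <- iter + 1L
    wn <- lengths(strsplit(names(uni), " ", fixed = TRUE))
    names(wn) <- names(uni)
    # corpus-wide bigram counts for this pass
    big <- table(unlist(lapply(docs, function(x) {
      if (length(x) < 2) return(character())
      paste(x[-length(x)], x[-1])
    }), use.names = FALSE))
    any_merge <- FALSE
    docs <- lapply(docs, function(x) {
      n <- length(x)
      if (n < 2) return(x)
      left <- x[-n]
      right <- x[-1]
      cij <- big[paste(left, right)]
      sc <- bigram_score(as.numeric(cij), as.numeric(uni[left]),
                         as.numeric(uni[right]), config$delta, v_size)
      ok <- sc > config$threshold & (wn[left] + wn[right]) <= max_words
      if (any(ok)) any_merge <<- TRUE
      merge_doc(x, ok)
    })
    if (!any_merge) break
  }
  all_tokens <- unique(unlist(docs, use.names = FALSE))
  list(docs = docs,
       phrases = sort_c(all_tokens[grepl(" ", all_tokens, fixed = TRUE)]))
}

#' Expand phrase tokens back into their component words
#'
#' Inverse of the merging performed by [extract_phrases()]; round-trips the
#' original token sequences exactly.
#'
#' @param docs list of token vectors possibly containing phrase tokens.
#' @return list of token vectors with every phrase split on spaces.
#' @export
expand_phrases <- function(docs) {
  lapply(docs, function(x) unlist(strsplit(x, " ", fixed = TRUE),
                                  use.names = FALSE))
}

#' Tune the phrase-extraction threshold and discount
#'
#' Grid search maximizing the recall of the multi-word terms of the training
#' lexicon in the extracted vocabulary (single-word term recall is
#' unaffected by extraction settings at a fixed `min_count`). Ties are
#' broken towards the higher threshold (fewer phrases), then the higher
#' discount.
#'
#' @param docs list of token vectors for one language side.
#' @param terms character vector of that language's training-lexicon terms
#'   (only multi-word terms matter; single words are ignored).
#' @param delta_grid,threshold_grid candidate values.
#' @param iterations merge passes, see [phrase_config()].
#' @param min_count vocabulary threshold for single words, see
#'   [build_vocabulary()].
#' @return the selected [phrase_config()], with the achieved recall in
#'   attribute `"recall"`.
#' @export
tune_extraction <- function(docs, terms, delta_grid = c(1, 2, 5, 10),
                            threshold_grid = c(2, 4, 6, 8, 16, 32),
                            iterations = 4, min_count = 5) {
  if (length(delta_grid) == 0 || length(threshold_grid) == 0) {
    stop("empty tuning grid")
  }
  phr_terms <- terms[grepl(" ", terms, fixed = TRUE)]
  if (length(phr_terms) == 0) {
    stop("training lexicon contains no multi-word term to tune on")
  }
  grid <- expand.grid(delta = delta_grid, threshold = threshold_grid)
  recall <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- phrase_config(grid$threshold[i], grid$delta[i], iterations)
    ext <- extract_phrases(docs, cfg)
    vocab <- build_vocabulary(ext$docs, min_count = min_count)
    mean(phr_terms %in% names(vocab))
  }, numeric(1))
  ord <- order(-recall, -grid$threshold, -grid$delta)
  best <- ord[1]
  if (max(recall) == 0) {
    warning("no grid setting recovered any training phrase")
  }
  out <- phrase_config(grid$threshold[best], grid$delta[best], iterations)
  attr(out, "recall") <- recall[best]
  out
}

#' Build a vocabulary from retokenized documents
#'
#' Counts tokens after phrase extraction, so a word that the corpus only
#' ever uses inside an extracted phrase is excluded (no separate
#' representation would be learned for it), while the phrase itself is
#' included. Single words must reach `min_count`; phrases are exempt by
#' default (`phrase_min_count = 1`) since extraction already applies a
#' frequency-sensitive score.
#'
#' @param docs list of token vectors.
#' @param min_count minimum corpus frequency for single-word terms.
#' @param phrase_min_count minimum frequency for phrase terms.
#' @param language optional language identifier.
#' @return a `vocabulary`: named integer vector of term frequencies.
#' @export
build_vocabulary <- function(docs, min_count = 5, phrase_min_count = 1,
                             language = NULL) {
  tab <- table(unlist(docs, use.names = FALSE))
  counts <- as.integer(tab)
  terms <- names(tab)
  is_phrase <- grepl(" ", terms, fixed = TRUE)
  keep <- ifelse(is_phrase, counts >= phrase_min_count, counts >= min_count)
  vocabulary(counts[keep], terms[keep], language)
}

#' Construct a vocabulary object
#' @param counts integer frequencies.
#' @param terms character terms (single words or space-joined phrases).
#' @param language optional language identifier.
#' @return named integer vector of class `vocabulary`, sorted by term.
#' @export
vocabulary <- function(counts, terms, language = NULL) {
  stopifnot(length(counts) == length(terms))
  ord <- order(terms, method = "radix")
  out <- as.integer(counts)[ord]
  names(out) <- terms[ord]
  structure(out, language = language, class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  phr <- sum(grepl(" ", names(x), fixed = TRUE))
  cat("<vocabulary> ", length(x) - phr, " words + ", phr, " phrases",
      if (!is.null(attr(x, "language"))) paste0(" [", attr(x, "language"), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize / read a vocabulary as term\\tcount TSV
#' @param vocab a [vocabulary()].
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(paste(names(vocab), as.integer(vocab), sep = "\t"), path,
             useBytes = TRUE)
}

#' @rdname write_vocabulary
#' @param language optional language identifier for the result.
#' @export
read_vocabulary <- function(path, language = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  m <- do.call(rbind, parts)
  vocabulary(as.integer(m[, 2]), m[, 1], language)
}
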