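#' Embedding table constructor
#'
#' A dense term-vector table: one row per term, `d` columns. Phrase terms
#' are stored with single spaces between component words; the underscore
#' alias used during training is converted back on construction.
#'
#' @param mat numeric matrix with one row per term.
#' @param terms character vector of row terms.
#' @param language language identifier (or `"bilingual"`).
#' @return matrix of class `embedding_table`.
#' @export
embedding_table <- function(mat, terms, language = NULL) {
  stopifnot(nrow(mat) == length(terms))
  rownames(mat) <- terms
  structure(mat, language = language, class = c("embedding_table", "matrix"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x), " terms x d=", ncol(x),
      if (!is.null(attr(x, "language"))) paste0(" [", attr(x, "language"), "]"),
      "\n", sep = "")
  invisible(x)
}

# space-joined vocabulary term <-> single whitespace-free training token
term_to_token <- function(x) gsub(" ", "_", x, fixed = TRUE)
token_to_term <- function(x) gsub("_", " ", x, fixed = TRUE)

# shared SGNS driver over a list of token vectors
sgns_over_docs <- function(docs, d, window, negative, epochs, alpha,
                           subsample, min_count, seed) {
  tab <- table(unlist(docs, use.names = FALSE))
  tab <- tab[tab >= min_count]
  if (length(tab) == 0) stop("empty vocabulary for embedding training")
  # frequency-descending, term ascending: stable ids across runs
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  terms <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  id <- seq_along(terms)
  names(id) <- terms
  enc <- lapply(docs, function(x) {
    v <- id[x]
    v[!is.na(v)]
  })
  enc <- enc[lengths(enc) > 0]
  tokens <- unlist(enc, use.names = FALSE) - 1L
  doc_len <- lengths(enc)
  m <- cpp_sgns_train(tokens, doc_len, counts, as.integer(d),
                      as.integer(window), as.integer(negative),
                      as.integer(epochs), alpha, subsample, as.integer(seed))
  list(mat = m, terms = terms, counts = counts)
}

#' Train monolingual skip-gram embeddings
#'
#' Skip-gram with negative sampling over one language side of a retokenized
#' corpus. Phrase tokens (spaces) are handled through the underscore alias,
#' so each phrase receives a single vector. Deterministic for a fixed seed
#' (single worker).
#'
#' @param docs list of token vectors.
#' @param d embedding dimensionality.
#' @param window context window size.
#' @param negative negative samples per context pair.
#' @param epochs training passes over the corpus.
#' @param alpha initial learning rate.
#' @param subsample frequency subsampling threshold.
#' @param min_count minimum token frequency to receive a vector.
#' @param language language tag stored on the result.
#' @param seed integer seed.
#' @return an [embedding_table()].
#' @export
train_monolingual <- function(docs, d = 50, window = 5, negative = 5,
                              epochs = 5, alpha = 0.025, subsample = 1e-4,
                              min_count = 1, language = NULL, seed = 1) {
  stopifnot(d > 0, window > 0)
  docs <- lapply(docs, term_to_token)
  fit <- sgns_over_docs(docs, d, window, negative, epochs, alpha, subsample,
                        min_count, seed)
  embedding_table(fit$mat, token_to_term(fit$terms), language)
}

#' Merge an aligned document pair into one pseudo-document
#'
#' `"ratio"` mode interleaves the two documents in their original order,
#' emitting `ceiling(|S|/|T|)` tokens of the longer side per token of the
#' shorter side (length-ratio interleave); `"shuffle"` mode permutes the
#' multiset union under the seed. Both conserve the token multiset exactly.
#'
#' @param doc_s,doc_t non-empty token vectors.
#' @param mode `"ratio"` or `"shuffle"`.
#' @param seed seed for `"shuffle"` mode.
#' @return a token vector containing every token of both inputs once.
#' @export
merge_documents <- function(doc_s, doc_t, mode = c("ratio", "shuffle"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (length(doc_s) == 0 || length(doc_t) == 0) {
    stop("cannot merge an empty document")
  }
  if (mode == "shuffle") {
    both <- c(doc_s, doc_t)
    return(both[local_seed(seed, sample.int(length(both)))])
  }
  swap <- length(doc_t) > length(doc_s)
  long <- if (swap) doc_t else doc_s
  short <- if (swap) doc_s else doc_t
  k <- ceiling(length(long) / length(short))
  out <- character(length(long) + length(short))
  li <- 1L; si <- 1L; oi <- 1L
  while (si <= length(short)) {
    take <- min(k, length(long) - li + 1L)
    if (take > 0) {
      out[oi:(oi + take - 1L)] <- long[li:(li + take - 1L)]
      li <- li + take; oi <- oi + take
    }
    out[oi] <- short[si]
    si <- si + 1L; oi <- oi + 1L
  }
  if (li <= length(long)) {
    rest <- long[li:length(long)]
    out[oi:(oi + length(rest) - 1L)] <- rest
    oi <- oi + length(rest)
  }
  out[seq_len(oi - 1L)]
}

# internal language prefixes for the shared bilingual space
bi_prefix <- function(tokens, which) paste0(which, "\x01", tokens)

#' Train pseudo-bilingual merged-document embeddings
#'
#' Merges each aligned document pair into a single pseudo-document (see
#' [merge_documents()]) and trains skip-gram with a large window over the
#' result, yielding one shared space containing both languages' terms.
#' Terms are internally prefixed by language to avoid homograph collisions;
#' the prefix is stripped on lookup via [embedding_language()].
#'
#' @param corpus a tokenized [comparable_corpus()].
#' @param d,window,negative,epochs,alpha,subsample,min_count,seed as in
#'   [train_monolingual()]; the window defaults to 100 so that contexts span
#'   most of a merged document.
#' @param merge_mode passed to [merge_documents()].
#' @return a `bilingual_embedding` (an [embedding_table()] whose rownames
#'   keep the internal language prefix).
#' @export
train_bwesg <- function(corpus, d = 50, window = 100, negative = 5,
                        epochs = 5, alpha = 0.025, subsample = 1e-4,
                        min_count = 1, merge_mode = "ratio", seed = 1) {
  stopifnot(inherits(corpus, "comparable_corpus"), corpus$tokenized,
            window > 0)
  merged <- lapply(seq_along(corpus$source), function(i) {
    s <- bi_prefix(term_to_token(corpus$source[[i]]), "S")
    t <- bi_prefix(term_to_token(corpus$target[[i]]), "T")
    merge_documents(s, t, mode = merge_mode, seed = seed + i)
  })
  fit <- sgns_over_docs(merged, d, window, negative, epochs, alpha,
                        subsample, min_count, seed)
  out <- embedding_table(fit$mat, fit$terms, "bilingual")
  attr(out, "languages") <- corpus$languages
  class(out) <- c("bilingual_embedding", class(out))
  out
}

#' Extract one language's table from a bilingual embedding
#'
#' @param bi a `bilingual_embedding` from [train_bwesg()].
#' @param which `"source"` or `"target"`.
#' @return an [embedding_table()] with unprefixed terms.
#' @export
embedding_language <- function(bi, which = c("source", "target")) {
  which <- match.arg(which)
  tag <- if (which == "source") "S\x01" else "T\x01"
  keep <- startsWith(rownames(bi), tag)
  m <- bi[keep, , drop = FALSE]
  embedding_table(unclass(m),
                  token_to_term(substring(rownames(bi)[keep], 3)),
                  which)
}

#' Least-squares translation matrix between monolingual spaces
#'
#' Fits the linear map `M` minimizing `sum_i || M x_i - z_i ||^2` over the
#' training pairs with both sides embedded. With fewer pairs than the
#' dimensionality the problem is underdetermined and the minimum-norm
#' solution is returned with a warning.
#'
#' @param pairs a [lexicon()] of training translation pairs.
#' @param table_s,table_t [embedding_table()] objects.
#' @return a `d x d` matrix of class `linear_map`.
#' @export
fit_translation_matrix <- function(pairs, table_s, table_t) {
  ok <- pairs$source %in% rownames(table_s) & pairs$target %in% rownames(table_t)
  if (!any(ok)) stop("no training pair has both sides embedded")
  X <- unclass(table_s)[pairs$source[ok], , drop = FALSE]
  Z <- unclass(table_t)[pairs$target[ok], , drop = FALSE]
  d <- ncol(X)
  if (sum(ok) < d) {
    warning("underdetermined fit: ", sum(ok), " usable pairs for d = ", d,
            "; returning the minimum-norm solution")
  }
  # min-norm least squares via the pseudoinverse: X M' = Z
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  Mt <- sv$v %*% (dinv * crossprod(sv$u, Z))
  structure(t(Mt), class = c("linear_map", "matrix"))
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Cosine similarities between two sets of vectors
#' @param a,b numeric matrices with vectors in rows.
#' @return `nrow(a) x nrow(b)` similarity matrix.
#' @export
cosine_similarity <- function(a, b) {
  row_normalize(as.matrix(a)) %*% t(row_normalize(as.matrix(b)))
}

#' Similarity-driven BLI baseline
#'
#' The classical approach: score every target term by cosine similarity to
#' the (mapped) source vector. `"top"` mode proposes the single most similar
#' target per source; `"all"` mode proposes every target whose similarity
#' exceeds the threshold.
#'
#' @param source_terms character vector of source terms to translate.
#' @param table_s,table_t [embedding_table()] objects; for merged-space
#'   embeddings pass the two [embedding_language()] views and keep
#'   `map = NULL`.
#' @param map optional [fit_translation_matrix()] result for monolingual
#'   spaces.
#' @param mode `"top"` or `"all"`.
#' @param threshold similarity threshold for `"all"` mode (ignored in
#'   `"top"` mode unless supplied, in which case the top candidate must
#'   also exceed it).
#' @return data frame `source`, `target`, `score`.
#' @export
sim_baseline_predict <- function(source_terms, table_s, table_t, map = NULL,
                                 mode = c("top", "all"), threshold = NULL) {
  mode <- match.arg(mode)
  known <- source_terms %in% rownames(table_s)
  if (!all(known)) {
    warning(sum(!known), " source term(s) missing from the embedding table; skipped")
    source_terms <- source_terms[known]
  }
  if (length(source_terms) == 0) {
    return(data.frame(source = character(), target = character(),
                      score = numeric()))
  }
  X <- unclass(table_s)[source_terms, , drop = FALSE]
  if (!is.null(map)) X <- X %*% t(map)
  sims <- cosine_similarity(X, unclass(table_t))
  targets <- rownames(table_t)
  if (mode == "top") {
    j <- apply(sims, 1, which.max)
    out <- data.frame(source = source_terms, target = targets[j],
                      score = sims[cbind(seq_along(j), j)])
    if (!is.null(threshold)) out <- out[out$score > threshold, , drop = FALSE]
  } else {
    if (is.null(threshold)) stop("'all' mode requires a threshold")
    hit <- which(sims > threshold, arr.ind = TRUE)
    out <- data.frame(source = source_terms[hit[, 1]],
                      target = targets[hit[, 2]],
                      score = sims[hit])
    out <- out[order(out$source, -out$score), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `"<count> <dim>"`, then one `"term v1 ... vd"` line per term.
#' Phrase terms are written with the underscore alias and restored on read.
#'
#' @param table an [embedding_table()].
#' @param path file path.
#' @export
write_word2vec <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(table), ncol(table)), con)
  terms <- term_to_token(rownames(table))
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(terms[i], paste(formatC(table[i, ], format = "g", digits = 8),
                          collapse = " "))
  }, character(1))
  writeLines(body, con)
}

#' @rdname write_word2vec
#' @param language language tag for the result.
#' @export
read_word2vec <- function(path, language = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  terms <- vapply(parts, `[`, character(1), 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  stopifnot(nrow(m) == hdr[1])
  embedding_table(m, token_to_term(terms), language)
}
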