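# Synthetic comparable corpora and gold lexicons with controllable
# orthographic (cognate) and distributional (topical) signal. The source
# language draws words over the letters a-m; orthographically unrelated
# target words are drawn over the disjoint letters n-z, while cognate
# targets are produced from their source by a deterministic ordered rewrite
# rule set, emulating shared-root (Greek/Latin-style) spelling regularities.

SRC_ALPHABET <- letters[1:13]  # a..m
TGT_ALPHABET <- letters[14:26] # n..z

#' Default orthographic rewrite rules
#'
#' An ordered set of regex pattern/replacement rules applied to a source
#' word to derive its cognate translation: a consonant shift, two suffix
#' rewrites, and a final vowel append that guarantees every derived form
#' differs from its source. Cognate pairs end up 1-3 edits apart, far
#' closer than any unrelated target word.
#'
#' @return data frame of class `ruleset` with columns `pattern`,
#'   `replacement`, applied in row order.
#' @export
default_ruleset <- function() {
  structure(data.frame(
    pattern = c("c", "ia$", "gg", "([bdg])e$", "([a-z])$"),
    replacement = c("k", "ie", "g", "\\1a", "\\1e"),
    stringsAsFactors = FALSE), class = c("ruleset", "data.frame"))
}

#' Apply an ordered rewrite rule set to terms
#'
#' Rules are applied in order with `gsub`; multi-word terms are transformed
#' word by word. Deterministic.
#'
#' @param x character vector of terms.
#' @param rules a `ruleset` (see [default_ruleset()]).
#' @return transformed character vector.
#' @export
apply_rules <- function(x, rules = default_ruleset()) {
  one_word <- function(w) {
    for (i in seq_len(nrow(rules))) {
      w <- gsub(rules$pattern[i], rules$replacement[i], w)
    }
    w
  }
  vapply(strsplit(x, " ", fixed = TRUE), function(ws) {
    paste(vapply(ws, one_word, character(1)), collapse = " ")
  }, character(1))
}

# second-translation variant of a cognate target (a nearby spelling,
# mirroring pairs like desensitisatie/desensibilisatie)
variant_form <- function(x) paste0(x, "s")

#' Synthetic benchmark configuration
#'
#' @param n_pairs number of source terms (each contributes one gold pair;
#'   polysemous sources contribute a second).
#' @param cognate_rate exact fraction of sources whose target is derived by
#'   the rewrite rules.
#' @param polysemy_rate exact fraction of sources receiving a second
#'   translation.
#' @param phrase_pair_count number of entries that are two-word on both
#'   sides; defaults to 7.7% of `n_pairs`, the typical share of
#'   phrase-phrase pairs in a domain lexicon.
#' @param n_docs aligned document pairs.
#' @param doc_length terms drawn per document.
#' @param n_topics topics; each aligned pair is about one topic and each
#'   term belongs to one topic.
#' @param zipf_exponent exponent of the within-topic rank-frequency law.
#' @param n_filler non-lexicon filler term pairs mixed into the corpus.
#' @param min_count guaranteed corpus-wide frequency of every lexicon term
#'   on both sides (so vocabulary filtering retains the full lexicon).
#' @param word_length min/max characters of generated words.
#' @param seed integer seed; generation is byte-identical per seed.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_pairs = 5000, cognate_rate = 0.8,
                       polysemy_rate = 0.2,
                       phrase_pair_count = round(0.077 * n_pairs),
                       n_docs = 150, doc_length = 400, n_topics = 20,
                       zipf_exponent = 1.0, n_filler = round(0.1 * n_pairs),
                       min_count = 5, word_length = c(5, 9), seed = 1) {
  stopifnot(n_pairs > 0, cognate_rate >= 0, cognate_rate <= 1,
            polysemy_rate >= 0, polysemy_rate <= 1,
            phrase_pair_count >= 0, phrase_pair_count <= n_pairs,
            n_docs > 0, doc_length > 0, n_topics > 0, n_filler >= 0,
            min_count >= 1, length(word_length) == 2)
  structure(list(n_pairs = as.integer(n_pairs), cognate_rate = cognate_rate,
                 polysemy_rate = polysemy_rate,
                 phrase_pair_count = as.integer(phrase_pair_count),
                 n_docs = as.integer(n_docs),
                 doc_length = as.integer(doc_length),
                 n_topics = as.integer(n_topics),
                 zipf_exponent = zipf_exponent,
                 n_filler = as.integer(n_filler),
                 min_count = as.integer(min_count),
                 word_length = as.integer(word_length),
                 seed = as.integer(seed)),
            class = "gen_config")
}

random_words <- function(n, alphabet, len_range, exclude = character(0)) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    lens <- sample(seq(len_range[1], len_range[2]), n - length(out),
                   replace = TRUE)
    w <- vapply(lens, function(l) {
      paste(sample(alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, setdiff(w, exclude)))
    tries <- tries + 1L
    if (tries > 200L) {
      stop("alphabet exhausted while generating unique words")
    }
  }
  out[seq_len(n)]
}

#' Generate a gold lexicon with controllable cognate signal
#'
#' Exactly `round(cognate_rate * n_pairs)` sources get a rule-derived
#' (cognate) target; the rest get an orthographically unrelated target over
#' a disjoint alphabet. Exactly `round(polysemy_rate * n_pairs)` sources
#' receive a second translation: a spelling variant of the cognate target,
#' or a second unrelated word. `phrase_pair_count` entries are two-word on
#' both sides. Reproducible per seed.
#'
#' @param config a [gen_config()].
#' @param rules a `ruleset`.
#' @return a [lexicon()] with an extra logical column `cognate`.
#' @export
generate_lexicon <- function(config = gen_config(), rules = default_ruleset()) {
  stopifnot(inherits(config, "gen_config"))
  local_seed(config$seed, {
    n <- config$n_pairs
    n_phr <- config$phrase_pair_count
    n_single <- n - n_phr
    words <- random_words(n_single + 2L * n_phr, SRC_ALPHABET,
                          config$word_length)
    sources <- c(words[seq_len(n_single)],
                 if (n_phr > 0)
                   paste(words[n_single + seq_len(n_phr)],
                         words[n_single + n_phr + seq_len(n_phr)]))
    n_cog <- round(config$cognate_rate * n)
    cog_idx <- sort(sample.int(n, n_cog))
    is_cog <- seq_len(n) %in% cog_idx

    targets <- character(n)
    targets[is_cog] <- apply_rules(sources[is_cog], rules)
    # distinct sources can share a rule image (e.g. a c/k pair); replace the
    # colliding sources with fresh words until images are unique
    tries <- 0L
    while (anyDuplicated(targets[is_cog])) {
      tries <- tries + 1L
      if (tries > 50L) stop("cannot resolve rule-image collisions; ",
                            "use longer words or fewer pairs")
      dup <- which(is_cog)[duplicated(targets[is_cog])]
      repl <- random_words(length(dup), SRC_ALPHABET, config$word_length,
                           exclude = sources)
      sources[dup] <- repl
      targets[dup] <- apply_rules(repl, rules)
    }
    n_non <- n - n_cog
    if (n_non > 0) {
      non_words <- random_words(n_non + 2L * sum(!is_cog & grepl(" ", sources)),
                                TGT_ALPHABET, config$word_length)
      # two-word targets for non-cognate phrase sources
      ph <- grepl(" ", sources) & !is_cog
      k <- sum(ph)
      tg <- non_words[seq_len(n_non)]
      if (k > 0) {
        extra <- non_words[n_non + seq_len(2L * k)]
        tg[which(ph[!is_cog])] <- paste(extra[seq_len(k)],
                                        extra[k + seq_len(k)])
      }
      targets[!is_cog] <- tg
    }

    n_poly <- round(config$polysemy_rate * n)
    poly_idx <- sort(sample.int(n, n_poly))
    extra_src <- sources[poly_idx]
    extra_tgt <- character(n_poly)
    pc <- is_cog[poly_idx]
    extra_tgt[pc] <- variant_form(targets[poly_idx][pc])
    if (any(!pc)) {
      extra_tgt[!pc] <- random_words(sum(!pc), TGT_ALPHABET,
                                     config$word_length, exclude = targets)
    }

    lex <- lexicon(c(sources, extra_src), c(targets, extra_tgt))
    lex$cognate <- c(is_cog, pc)[match(pair_key(lex$source, lex$target),
                                       pair_key(c(sources, extra_src),
                                                c(targets, extra_tgt)))]
    lex
  })
}

#' Generate a comparable corpus around a gold lexicon
#'
#' Every source term (and `n_filler` filler pairs) is assigned to one of
#' `n_topics` topics. Each aligned document pair samples a topic and draws
#' `doc_length` terms from that topic under a Zipf-like rank-frequency law;
#' the source document emits the drawn source terms, the target document
#' emits a translation of each drawn term in independently shuffled order.
#' Multi-word terms are always emitted as adjacent word tokens. A final
#' top-up pass appends occurrences so every lexicon term reaches
#' `min_count` on its side, guaranteeing that vocabulary filtering retains
#' the full lexicon.
#'
#' @param lex a [generate_lexicon()] result.
#' @param config the same [gen_config()].
#' @return a tokenized [comparable_corpus()].
#' @export
generate_corpus <- function(lex, config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  local_seed(config$seed + 1L, {
    src_terms <- unique(lex$source)
    translations <- split(lex$target, lex$source)[src_terms]
    fill_s <- random_words(config$n_filler, SRC_ALPHABET, config$word_length,
                           exclude = src_terms)
    fill_t <- random_words(config$n_filler, TGT_ALPHABET, config$word_length,
                           exclude = unique(lex$target))
    all_src <- c(src_terms, fill_s)
    trans <- c(translations, as.list(fill_t))
    names(trans) <- all_src
    nterm <- length(all_src)

    topic <- sample.int(config$n_topics, nterm, replace = TRUE)
    by_topic <- split(seq_len(nterm), topic) # keyed by topic value
    topics_present <- as.integer(names(by_topic))
    # within-topic Zipf weights over a random rank order
    weights <- numeric(nterm)
    for (ti in by_topic) {
      r <- sample.int(length(ti))
      weights[ti] <- r^(-config$zipf_exponent)
    }

    src_docs <- vector("list", config$n_docs)
    tgt_docs <- vector("list", config$n_docs)
    tp <- rep_len(topics_present, config$n_docs)
    doc_topic <- tp[sample.int(length(tp))]
    draw_counts_s <- integer(nterm)
    tgt_count <- new.env(parent = emptyenv())
    emit_target <- function(term_ids) {
      vapply(term_ids, function(i) {
        tr <- trans[[i]]
        tr[sample.int(length(tr), 1L)]
      }, character(1))
    }
    for (di in seq_len(config$n_docs)) {
      ti <- by_topic[[as.character(doc_topic[di])]]
      ids <- ti[sample.int(length(ti), config$doc_length, replace = TRUE,
                           prob = weights[ti])]
      draw_counts_s[ids] <- draw_counts_s[ids] + 1L
      tgts <- emit_target(ids)
      for (tg in tgts) {
        tgt_count[[tg]] <- (tgt_count[[tg]] %||% 0L) + 1L
      }
      src_docs[[di]] <- unlist(strsplit(all_src[ids], " ", fixed = TRUE),
                               use.names = FALSE)
      tgt_docs[[di]] <- unlist(strsplit(tgts[sample.int(length(tgts))], " ",
                                        fixed = TRUE), use.names = FALSE)
    }

    # top-up: guarantee min_count for every lexicon term on its side
    doc_of_topic <- split(seq_len(config$n_docs), doc_topic)
    topic_slot <- function(id) {
      cand <- doc_of_topic[[as.character(topic[id])]]
      if (is.null(cand)) cand <- seq_len(config$n_docs)
      cand[sample.int(length(cand), 1L)]
    }
    # random-position insertion, so top-ups never fabricate adjacencies
    insert_at <- function(doc, tokens) {
      append(doc, tokens, after = sample.int(length(doc) + 1L, 1L) - 1L)
    }
    # multi-word terms must survive collocation extraction, whose score
    # carries a discount; keep their counts comfortably above it
    floor_of <- function(term) {
      if (grepl(" ", term, fixed = TRUE)) config$min_count + 10L
      else config$min_count
    }
    lex_ids <- match(unique(lex$source), all_src)
    for (id in lex_ids) {
      deficit <- floor_of(all_src[id]) - draw_counts_s[id]
      if (deficit > 0) {
        for (r in seq_len(deficit)) {
          di <- topic_slot(id)
          src_docs[[di]] <- insert_at(src_docs[[di]],
                                      strsplit(all_src[id], " ", fixed = TRUE)[[1]])
          tg <- emit_target(id)
          tgt_docs[[di]] <- insert_at(tgt_docs[[di]],
                                      strsplit(tg, " ", fixed = TRUE)[[1]])
          tgt_count[[tg]] <- (tgt_count[[tg]] %||% 0L) + 1L
        }
      }
    }
    src_of_target <- split(lex$source, lex$target)
    for (tg in unique(lex$target)) {
      deficit <- floor_of(tg) - (tgt_count[[tg]] %||% 0L)
      if (deficit > 0) {
        src <- src_of_target[[tg]][1]
        id <- match(src, all_src)
        for (r in seq_len(deficit)) {
          di <- topic_slot(id)
          src_docs[[di]] <- insert_at(src_docs[[di]],
                                      strsplit(src, " ", fixed = TRUE)[[1]])
          tgt_docs[[di]] <- insert_at(tgt_docs[[di]],
                                      strsplit(tg, " ", fixed = TRUE)[[1]])
          tgt_count[[tg]] <- (tgt_count[[tg]] %||% 0L) + 1L
        }
      }
    }
    comparable_corpus(src_docs, tgt_docs, c("synth-s", "synth-t"),
                      tokenized = TRUE)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Bundles a gold lexicon, a comparable corpus guaranteeing full lexicon
#' retention, the train/validation/test split, and the cognate source
#' subset (the synthetic analogue of a shared-root subset analysis).
#'
#' @param config a [gen_config()].
#' @param rules a `ruleset`.
#' @return a `bli_benchmark` list: `corpus`, `lexicon`, `split`,
#'   `cognate_sources`, `config`.
#' @export
generate_benchmark <- function(config = gen_config(),
                               rules = default_ruleset()) {
  lex <- generate_lexicon(config, rules)
  corpus <- generate_corpus(lex, config)
  split <- split_lexicon(lex, config$seed)
  structure(list(corpus = corpus, lexicon = lex, split = split,
                 cognate_sources = sort_c(unique(lex$source[lex$cognate])),
                 config = config),
            class = "bli_benchmark")
}

#' @export
print.bli_benchmark <- function(x, ...) {
  cat("<bli_benchmark> ", nrow(x$lexicon), " gold pairs (",
      length(x$cognate_sources), " cognate sources), ",
      length(x$corpus), " document pairs\n", sep = "")
  invisible(x)
}
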