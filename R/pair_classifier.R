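PAD_CHAR <- "<pad>"
UNK_CHAR <- "<unk>"

#' Build per-language character inventories
#'
#' The inventories contain exactly the characters occurring in the
#' vocabulary terms of each language (the space character of phrases
#' included), plus shared reserved `<pad>` and `<unk>` symbols at indices 1
#' and 2. Characters are sorted for determinism; characters unseen at
#' prediction time map to `<unk>`.
#'
#' @param vocab_s,vocab_t [vocabulary()] objects or character term vectors.
#' @return a `char_vocab` list with elements `source` and `target`.
#' @export
build_char_vocabs <- function(vocab_s, vocab_t) {
  inv <- function(v) {
    terms <- if (is.character(v)) v else names(v)
    chars <- sort_c(unique(unlist(strsplit(terms, ""), use.names = FALSE)))
    c(PAD_CHAR, UNK_CHAR, chars)
  }
  structure(list(source = inv(vocab_s), target = inv(vocab_t)),
            class = "char_vocab")
}

#' @export
print.char_vocab <- function(x, ...) {
  cat("<char_vocab> |C_S| = ", length(x$source) - 2, " + pad/unk, |C_T| = ",
      length(x$target) - 2, " + pad/unk\n", sep = "")
  invisible(x)
}

char_indices <- function(term, inventory) {
  ch <- strsplit(term, "")[[1]]
  idx <- match(ch, inventory)
  idx[is.na(idx)] <- 2L # <unk>
  idx
}

#' Encode a term pair as aligned padded character index sequences
#'
#' Both character sequences are padded with `<pad>` at the end of the
#' shorter term to the common length `max(nchar(source), nchar(target))`;
#' position `i` of the encoding carries the pair (source char i or pad,
#' target char i or pad). Spaces are encoded as ordinary characters.
#'
#' @param source,target non-empty terms.
#' @param char_vocab a [build_char_vocabs()] result.
#' @return list with integer vectors `src`, `tgt` and the padded `length`.
#' @export
encode_char_pair <- function(source, target, char_vocab) {
  if (!nzchar(source) || !nzchar(target)) {
    stop("cannot encode an empty term")
  }
  s <- char_indices(source, char_vocab$source)
  t <- char_indices(target, char_vocab$target)
  m <- max(length(s), length(t))
  list(src = c(s, rep(1L, m - length(s))),
       tgt = c(t, rep(1L, m - length(t))),
       length = m)
}

# vectorized encoding into Mmax x n index matrices for the C++ core
encode_pair_matrix <- function(sources, targets, char_vocab) {
  n <- length(sources)
  encs <- lapply(seq_len(n), function(i) {
    encode_char_pair(sources[i], targets[i], char_vocab)
  })
  lens <- vapply(encs, `[[`, integer(1), "length")
  m <- max(lens)
  src <- matrix(0L, m, n)
  tgt <- matrix(0L, m, n)
  for (i in seq_len(n)) {
    src[seq_len(lens[i]), i] <- encs[[i]]$src
    tgt[seq_len(lens[i]), i] <- encs[[i]]$tgt
  }
  list(src = src, tgt = tgt, len = as.integer(lens))
}

#' Word-level representation of a term pair
#'
#' The concatenation of the source and target term embeddings (length
#' `2 d`). The embedding tables are produced in advance and are never
#' updated by classifier training.
#'
#' @param source,target terms (vectorized, equal length).
#' @param table_s,table_t [embedding_table()] objects.
#' @return a `2d x n` matrix (one column per pair).
#' @export
word_pair_representation <- function(source, target, table_s, table_t) {
  miss <- setdiff(source, rownames(table_s))
  if (length(miss) > 0) {
    stop("source term(s) without embedding: ", paste(head(miss, 3), collapse = ", "))
  }
  miss <- setdiff(target, rownames(table_t))
  if (length(miss) > 0) {
    stop("target term(s) without embedding: ", paste(head(miss, 3), collapse = ", "))
  }
  rbind(t(unclass(table_s)[source, , drop = FALSE]),
        t(unclass(table_t)[target, , drop = FALSE]))
}

#' Pair-classifier configuration
#'
#' @param feature_set which representations feed the classifier:
#'   `"combined"` (word embeddings + character encoder), `"charpairs"`
#'   (character encoder only), `"word"` (embeddings only), or the
#'   handcrafted baselines `"ed_norm"`, `"log_ed_rank"`, `"ed_both"`.
#' @param lstm_cells LSTM memory cells per layer; defaults to 512 for the
#'   character-only model and 256 for the combined model.
#' @param n_hidden number of fully connected layers `H` between the
#'   representation and the output; forced to 0 for the one/two-dimensional
#'   edit-distance baselines.
#' @param hidden_width width of each hidden layer; defaults to the
#'   dimension of the input representation.
#' @param dropout_keep keep probability of dropout on the character
#'   encoder's output connections (training only).
#' @param d word-embedding dimensionality.
#' @param batch_size mini-batch size.
#' @param epochs training epochs; defaults to 150 (word), 250 (charpairs /
#'   combined) or 25 (edit-distance baselines).
#' @param n_negative negatives sampled per side per positive pair (`N_s`;
#'   each positive yields `2 N_s` negatives).
#' @param learning_rate Adam step size (other moments at defaults).
#' @param seed integer seed driving initialization, shuffling, dropout and
#'   negative sampling.
#' @return a `bli_model_config` list.
#' @export
model_config <- function(feature_set = c("combined", "charpairs", "word",
                                         "ed_norm", "log_ed_rank", "ed_both"),
                         lstm_cells = NULL, n_hidden = NULL,
                         hidden_width = NULL, dropout_keep = 0.5, d = 50,
                         batch_size = 10, epochs = NULL, n_negative = 5,
                         learning_rate = 1e-3, seed = 1) {
  feature_set <- match.arg(feature_set)
  is_ed <- feature_set %in% c("ed_norm", "log_ed_rank", "ed_both")
  use_char <- feature_set %in% c("combined", "charpairs")
  if (is.null(lstm_cells)) {
    lstm_cells <- if (feature_set == "charpairs") 512L else 256L
  }
  if (is.null(n_hidden)) n_hidden <- if (is_ed) 0L else 2L
  if (is_ed && n_hidden != 0) {
    stop("edit-distance feature sets use no hidden layers (H = 0): ",
         "the features are one-dimensional")
  }
  if (is.null(epochs)) {
    epochs <- switch(feature_set, word = 150L, combined = , charpairs = 250L, 25L)
  }
  stopifnot(n_hidden >= 0, dropout_keep > 0, dropout_keep <= 1,
            batch_size >= 1, n_negative >= 1)
  structure(list(feature_set = feature_set, use_char = use_char,
                 lstm_cells = as.integer(lstm_cells),
                 n_hidden = as.integer(n_hidden),
                 hidden_width = hidden_width,
                 dropout_keep = dropout_keep, d = as.integer(d),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_negative = as.integer(n_negative),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "bli_model_config")
}

#' Sample negative training pairs for one positive pair
#'
#' Uniformly samples `n_negative` target terms to pair with the positive's
#' source, and `n_negative` source terms to pair with the positive's
#' target. A sampled pair that occurs in the training lexicon is resampled.
#'
#' @param source,target the positive pair.
#' @param n_negative negatives per side (`N_s`).
#' @param vocab_s,vocab_t vocabularies ([vocabulary()] or character) to
#'   sample from.
#' @param train_lexicon the training [lexicon()] (pairs never emitted).
#' @param seed integer seed.
#' @return a data frame of `2 n_negative` rows with columns `source`,
#'   `target`.
#' @export
sample_negatives <- function(source, target, n_negative, vocab_s, vocab_t,
                             train_lexicon, seed = 1) {
  ts <- if (is.character(vocab_s)) vocab_s else names(vocab_s)
  tt <- if (is.character(vocab_t)) vocab_t else names(vocab_t)
  if (length(ts) <= n_negative || length(tt) <= n_negative) {
    stop("vocabulary too small to sample ", n_negative, " negatives per side")
  }
  forbidden <- pair_key(train_lexicon$source, train_lexicon$target)
  local_seed(seed, {
    draw <- function(fixed_side, pool, fixed_is_source) {
      out <- character(0)
      tries <- 0L
      while (length(out) < n_negative) {
        cand <- sample(pool, n_negative - length(out), replace = FALSE)
        key <- if (fixed_is_source) pair_key(fixed_side, cand)
               else pair_key(cand, fixed_side)
        out <- c(out, cand[!(key %in% forbidden)])
        tries <- tries + 1L
        if (tries > 100L) stop("cannot avoid lexicon collisions while sampling negatives")
      }
      out
    }
    neg_t <- draw(source, tt, TRUE)
    neg_s <- draw(target, ts, FALSE)
    data.frame(source = c(rep(source, n_negative), neg_s),
               target = c(neg_t, rep(target, n_negative)),
               stringsAsFactors = FALSE)
  })
}

# negatives for every positive at once (seeded, used by training)
sample_negatives_all <- function(positives, n_negative, vocab_s, vocab_t,
                                 seed) {
  rows <- lapply(seq_len(nrow(positives)), function(i) {
    sample_negatives(positives$source[i], positives$target[i], n_negative,
                     vocab_s, vocab_t, positives, seed = seed + i)
  })
  do.call(rbind, rows)
}

# assemble the fixed (non-character) feature matrix for a set of pairs
pair_features <- function(model, sources, targets) {
  fs <- model$feature_set
  feats <- NULL
  if (fs %in% c("combined", "word")) {
    feats <- word_pair_representation(sources, targets,
                                      model$embeddings$source,
                                      model$embeddings$target)
  }
  if (fs %in% c("ed_norm", "ed_both")) {
    feats <- rbind(feats, ed_norm = ed_norm(sources, targets))
  }
  if (fs %in% c("log_ed_rank", "ed_both")) {
    led <- vapply(seq_along(sources), function(i) {
      log_ed_rank(sources[i], targets[i], model$target_terms)
    }, numeric(1))
    feats <- rbind(feats, log_ed_rank = led)
  }
  if (is.null(feats)) feats <- matrix(0, 0, length(sources))
  feats
}

pair_char_encoding <- function(model, sources, targets) {
  if (!model$config$use_char) {
    return(list(src = matrix(0L, 0, 0), tgt = matrix(0L, 0, 0),
                len = integer(0)))
  }
  encode_pair_matrix(sources, targets, model$char_vocab)
}

#' Train the pair classification model
#'
#' Builds labeled training pairs from the training split (each positive pair
#' plus `2 N_s` uniformly sampled negatives), encodes them according to the
#' configured feature set, and minimizes the cross-entropy loss by
#' mini-batch Adam. Word embedding tables are held fixed; the character
#' encoder and feed-forward combiner are trained jointly. The decision
#' threshold is left untuned (`NA`); see [tune_threshold()].
#'
#' @param split a [split_lexicon()].
#' @param config a [model_config()].
#' @param embeddings list with [embedding_table()] elements `source` and
#'   `target` (required for `"word"` and `"combined"` feature sets).
#' @param char_vocab a [build_char_vocabs()] result (required when the
#'   character encoder is used).
#' @param vocab_s,vocab_t vocabularies used for negative sampling (and the
#'   target vocabulary of the `log_ed_rank` feature). For embedding-based
#'   feature sets, sampling is restricted to embedded terms.
#' @param verbose print the mean loss every few epochs.
#' @return a `bli_model` list: trained `params`, `config`, references to
#'   the fixed embeddings, the character vocabulary, per-epoch mean loss,
#'   and `threshold` (NA until tuned).
#' @export
train_pair_classifier <- function(split, config, embeddings = NULL,
                                  char_vocab = NULL, vocab_s, vocab_t,
                                  verbose = FALSE) {
  stopifnot(inherits(split, "split_lexicon"), inherits(config, "bli_model_config"))
  positives <- split$train
  if (nrow(positives) == 0) stop("empty training lexicon")
  ts <- if (is.character(vocab_s)) vocab_s else names(vocab_s)
  tt <- if (is.character(vocab_t)) vocab_t else names(vocab_t)
  needs_emb <- config$feature_set %in% c("combined", "word")
  if (needs_emb) {
    if (is.null(embeddings)) stop("feature set '", config$feature_set,
                                  "' requires embeddings")
    ts <- intersect(ts, rownames(embeddings$source))
    tt <- intersect(tt, rownames(embeddings$target))
    keep <- positives$source %in% ts & positives$target %in% tt
    if (!all(keep)) {
      warning(sum(!keep), " training pair(s) without embeddings dropped")
      positives <- positives[keep, , drop = FALSE]
    }
  }
  if (config$use_char && is.null(char_vocab)) {
    stop("character feature sets require a char_vocab")
  }

  negatives <- sample_negatives_all(positives, config$n_negative, ts, tt,
                                    config$seed)
  all_pairs <- rbind(positives[, c("source", "target")],
                     negatives[, c("source", "target")])
  labels <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))

  model <- list(config = config, feature_set = config$feature_set,
                embeddings = embeddings, char_vocab = char_vocab,
                target_terms = tt, threshold = NA_real_)
  class(model) <- "bli_model"

  feats <- pair_features(model, all_pairs$source, all_pairs$target)
  chars <- pair_char_encoding(model, all_pairs$source, all_pairs$target)

  a0_dim <- nrow(feats) + if (config$use_char) config$lstm_cells else 0L
  width <- config$hidden_width %||% a0_dim
  widths <- rep(as.integer(width), config$n_hidden)

  fit <- cpp_nn_train(feats, chars$src, chars$tgt, chars$len, labels,
                      length(char_vocab$source %||% character(0)),
                      length(char_vocab$target %||% character(0)),
                      config$lstm_cells, widths, config$dropout_keep,
                      config$batch_size, config$epochs,
                      config$learning_rate, config$seed)
  if (verbose && length(fit$epoch_loss) > 0) {
    message("epoch 1 loss ", signif(fit$epoch_loss[1], 4), " -> epoch ",
            length(fit$epoch_loss), " loss ",
            signif(tail(fit$epoch_loss, 1), 4))
  }
  model$params <- fit$params
  model$epoch_loss <- fit$epoch_loss
  model$n_hidden <- config$n_hidden
  model
}

#' @export
print.bli_model <- function(x, ...) {
  cat("<bli_model> features=", x$feature_set,
      if (x$config$use_char) paste0(", lstm_cells=", x$config$lstm_cells),
      ", H=", x$config$n_hidden,
      ", threshold=", if (is.na(x$threshold)) "untuned" else x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Classification score of term pairs
#'
#' Runs the trained network forward (dropout disabled) and returns the
#' translation score `f(p_S, p_T)` in (0, 1) for each pair.
#'
#' @param model a trained `bli_model`.
#' @param source,target equal-length term vectors.
#' @return numeric vector of scores.
#' @export
score_pairs <- function(model, source, target) {
  stopifnot(length(source) == length(target))
  if (length(source) == 0) return(numeric(0))
  feats <- pair_features(model, source, target)
  chars <- pair_char_encoding(model, source, target)
  as.numeric(cpp_nn_predict(model$params, feats, chars$src, chars$tgt,
                            chars$len,
                            length(model$char_vocab$source %||% character(0)),
                            length(model$char_vocab$target %||% character(0)),
                            model$config$n_hidden))
}

#' Character-pair representation of term pairs
#'
#' The character encoder's output: the second LSTM layer's hidden state at
#' the final position of the padded pair sequence (evaluation mode, no
#' dropout).
#'
#' @param model a trained `bli_model` with a character encoder.
#' @param source,target equal-length term vectors.
#' @return a `cells x n` matrix, one column per pair.
#' @export
char_pair_representation <- function(model, source, target) {
  if (!model$config$use_char) stop("model has no character encoder")
  chars <- pair_char_encoding(model, source, target)
  cpp_nn_char_repr(model$params, chars$src, chars$tgt, chars$len,
                   length(model$char_vocab$source),
                   length(model$char_vocab$target))
}

#' Cross-entropy loss
#'
#' `sum(-y log f - (1 - y) log(1 - f))` over scored pairs. Scores exactly 0
#' or 1 are clamped by `eps` (with a message) to keep the loss finite.
#'
#' @param scores numeric vector in `[0, 1]`.
#' @param labels 0/1 vector.
#' @param eps clamping epsilon.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(scores, labels, eps = 1e-7) {
  stopifnot(length(scores) == length(labels))
  if (any(scores <= 0 | scores >= 1)) {
    message("score(s) at 0 or 1 clamped by eps = ", eps)
  }
  s <- pmin(pmax(scores, eps), 1 - eps)
  sum(-labels * log(s) - (1 - labels) * log(1 - s))
}

#' Tune the decision threshold on the validation split
#'
#' Scores the validation candidate pairs once, then grid-searches
#' `t in {0.1, ..., 1.0}` for the value maximizing validation F1 in the
#' requested mode; ties go to the smallest `t`.
#'
#' @param model a trained `bli_model`.
#' @param validation the validation [lexicon()].
#' @param candidates [generate_candidates()] output covering the validation
#'   sources.
#' @param mode `"all"` (default: the mode that rewards recovering multiple
#'   translations) or `"top"`.
#' @param grid candidate thresholds.
#' @return the selected threshold, with the full `data.frame(threshold,
#'   f1)` in attribute `"grid"`.
#' @export
tune_threshold <- function(model, validation, candidates, mode = "all",
                           grid = seq(0.1, 1, by = 0.1)) {
  if (nrow(validation) == 0) stop("empty validation lexicon")
  cand <- candidates[candidates$source %in% validation$source, , drop = FALSE]
  scores <- score_pairs(model, cand$source, cand$candidate)
  f1s <- vapply(grid, function(t) {
    preds <- threshold_predictions(cand, scores, t, mode)
    evaluate_bli(preds, validation, mode)$f1
  }, numeric(1))
  best <- grid[which.max(f1s)] # which.max takes the first (smallest t) on ties
  attr(best, "grid") <- data.frame(threshold = grid, f1 = f1s)
  best
}

threshold_predictions <- function(cand, scores, threshold, mode,
                                  top_requires_threshold = TRUE) {
  df <- data.frame(source = cand$source, target = cand$candidate,
                   score = scores, stringsAsFactors = FALSE)
  if (mode == "all") {
    out <- df[df$score > threshold, , drop = FALSE]
  } else {
    df <- df[order(df$source, -df$score, df$target, method = "radix"), ,
             drop = FALSE]
    out <- df[!duplicated(df$source), , drop = FALSE]
    if (top_requires_threshold) out <- out[out$score > threshold, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify candidate translation pairs
#'
#' Scores each (source, candidate) pair and applies the decision rule:
#' `"all"` mode returns every candidate whose score exceeds the threshold;
#' `"top"` mode returns the best-scoring candidate per source, by default
#' only when it also exceeds the threshold (set
#' `top_requires_threshold = FALSE` for accuracy-at-1 style comparisons).
#'
#' @param model a trained `bli_model` with a tuned (or supplied) threshold.
#' @param candidates [generate_candidates()] output.
#' @param mode `"all"` or `"top"`.
#' @param threshold decision threshold; defaults to the model's tuned one.
#' @param top_requires_threshold whether `"top"` mode also applies the
#'   threshold.
#' @return data frame `source`, `target`, `score`.
#' @export
classify_pairs <- function(model, candidates, mode = c("all", "top"),
                           threshold = NULL,
                           top_requires_threshold = TRUE) {
  mode <- match.arg(mode)
  threshold <- threshold %||% model$threshold
  if (is.na(threshold)) stop("threshold not tuned; call tune_threshold()")
  if (nrow(candidates) == 0) {
    return(data.frame(source = character(), target = character(),
                      score = numeric()))
  }
  scores <- score_pairs(model, candidates$source, candidates$candidate)
  threshold_predictions(candidates, scores, threshold, mode,
                        top_requires_threshold)
}
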