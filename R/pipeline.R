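#' Build per-language resources from a tokenized corpus
#'
#' Runs phrase extraction (optional) and vocabulary construction on both
#' sides, producing everything the classifier needs short of embeddings.
#'
#' @param corpus a tokenized [comparable_corpus()].
#' @param phrase_cfg_s,phrase_cfg_t [phrase_config()] per side, or `NULL`
#'   to skip phrase extraction on that side.
#' @param min_count vocabulary threshold for single words.
#' @return list with `docs_s`, `docs_t` (retokenized), `vocab_s`,
#'   `vocab_t`, `phrases_s`, `phrases_t`.
#' @export
build_resources <- function(corpus, phrase_cfg_s = phrase_config(),
                            phrase_cfg_t = phrase_config(), min_count = 5) {
  stopifnot(inherits(corpus, "comparable_corpus"), corpus$tokenized)
  side <- function(docs, cfg) {
    if (is.null(cfg)) return(list(docs = docs, phrases = character(0)))
    extract_phrases(docs, cfg)
  }
  s <- side(corpus$source, phrase_cfg_s)
  t <- side(corpus$target, phrase_cfg_t)
  list(docs_s = s$docs, docs_t = t$docs,
       vocab_s = build_vocabulary(s$docs, min_count,
                                  language = corpus$languages[1]),
       vocab_t = build_vocabulary(t$docs, min_count,
                                  language = corpus$languages[2]),
       phrases_s = s$phrases, phrases_t = t$phrases)
}

#' Run a full train / tune / evaluate experiment on a benchmark
#'
#' End-to-end driver: phrase extraction and vocabularies, embeddings (as
#' needed by the feature set), classifier training on the train split,
#' threshold tuning on the validation split, candidate generation and
#' classification for the test sources, and F1 evaluation in both modes.
#'
#' @param bench a [generate_benchmark()] result (or a list with `corpus`,
#'   `lexicon`, `split`).
#' @param feature_set passed to [model_config()].
#' @param n_candidates `N_c` per criterion at prediction time (`2 N_c`
#'   candidates per source).
#' @param phrase_delta,phrase_threshold phrase-extraction settings (applied
#'   to both sides; the synthetic corpus is symmetric).
#' @param epochs,lstm_cells,batch_size,n_negative,seed overrides for
#'   [model_config()]; `NULL` keeps its defaults.
#' @param d embedding dimensionality.
#' @param sgns_epochs,bwesg_epochs embedding training passes.
#' @param subsample frequency-subsampling threshold for embedding training;
#'   0 disables it, appropriate for corpora far smaller than the web-scale
#'   collections the usual `1e-4` is calibrated for.
#' @param tune_mode evaluation mode optimized by threshold tuning.
#' @param exclude_known drop candidate pairs that already appear in the
#'   seed (train/validation) lexicon before prediction. Induction targets
#'   new translations; without this, a source whose translations are split
#'   between seed and test is penalized for re-proposing the seed pair.
#' @param min_count vocabulary threshold.
#' @param verbose print progress.
#' @return list with `model`, `threshold`, `eval_all`, `eval_top`,
#'   `predictions_all`, `predictions_top`, `candidates`,
#'   `candidate_recall`, `resources`, `embeddings`, `bilingual`.
#' @export
run_experiment <- function(bench, feature_set = "charpairs",
                           n_candidates = 5, phrase_delta = 5,
                           phrase_threshold = 2, epochs = NULL,
                           lstm_cells = NULL, batch_size = NULL,
                           n_negative = NULL, seed = 1, d = 50,
                           sgns_epochs = 5, bwesg_epochs = 3,
                           subsample = 0, tune_mode = "all", min_count = 5,
                           exclude_known = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  has_phrases <- any(grepl(" ", bench$lexicon$source, fixed = TRUE))
  pcfg <- if (has_phrases) phrase_config(phrase_threshold, phrase_delta) else NULL
  say("building vocabularies")
  res <- build_resources(bench$corpus, pcfg, pcfg, min_count)

  split <- bench$split
  flt <- function(lx) filter_lexicon(lx, res$vocab_s, res$vocab_t)
  split$train <- flt(split$train)
  split$validation <- flt(split$validation)
  split$test <- flt(split$test)

  cfg_args <- list(feature_set = feature_set, d = d, seed = seed)
  if (!is.null(epochs)) cfg_args$epochs <- epochs
  if (!is.null(lstm_cells)) cfg_args$lstm_cells <- lstm_cells
  if (!is.null(batch_size)) cfg_args$batch_size <- batch_size
  if (!is.null(n_negative)) cfg_args$n_negative <- n_negative
  config <- do.call(model_config, cfg_args)

  embeddings <- NULL
  if (feature_set %in% c("word", "combined")) {
    say("training monolingual embeddings")
    embeddings <- list(
      source = train_monolingual(res$docs_s, d = d, epochs = sgns_epochs,
                                 subsample = subsample,
                                 language = bench$corpus$languages[1],
                                 seed = seed),
      target = train_monolingual(res$docs_t, d = d, epochs = sgns_epochs,
                                 subsample = subsample,
                                 language = bench$corpus$languages[2],
                                 seed = seed + 1))
  }
  say("training merged-document bilingual embeddings")
  retok <- comparable_corpus(res$docs_s, res$docs_t,
                             bench$corpus$languages, tokenized = TRUE)
  bilingual <- train_bwesg(retok, d = d, epochs = bwesg_epochs,
                           subsample = subsample, seed = seed)

  char_vocab <- if (config$use_char) {
    build_char_vocabs(res$vocab_s, res$vocab_t)
  }

  say("training the pair classifier (", config$epochs, " epochs)")
  model <- train_pair_classifier(split, config, embeddings, char_vocab,
                                 res$vocab_s, res$vocab_t, verbose = verbose)

  drop_pairs <- function(cand, known) {
    if (!exclude_known || nrow(cand) == 0) return(cand)
    keep <- !(paste(cand$source, cand$candidate, sep = "\x1f") %in%
                paste(known$source, known$target, sep = "\x1f"))
    cand[keep, , drop = FALSE]
  }

  say("tuning the decision threshold")
  val_sources <- unique(split$validation$source)
  val_cand <- generate_candidates(val_sources, n_candidates, res$vocab_t,
                                  bilingual)
  val_cand <- drop_pairs(val_cand, split$train)
  thr <- tune_threshold(model, split$validation, val_cand, mode = tune_mode)
  model$threshold <- as.numeric(thr)

  say("predicting for the test sources")
  test_sources <- unique(split$test$source)
  test_cand <- generate_candidates(test_sources, n_candidates, res$vocab_t,
                                   bilingual)
  test_cand <- drop_pairs(test_cand, rbind(split$train[, c("source", "target")],
                                           split$validation[, c("source", "target")]))
  preds_all <- classify_pairs(model, test_cand, mode = "all")
  preds_top <- classify_pairs(model, test_cand, mode = "top")

  list(model = model, threshold = model$threshold,
       eval_all = evaluate_bli(preds_all, split$test, "all"),
       eval_top = evaluate_bli(preds_top, split$test, "top"),
       predictions_all = preds_all, predictions_top = preds_top,
       candidates = test_cand,
       candidate_recall = candidate_recall(test_cand, split$test),
       threshold_grid = attr(thr, "grid"),
       split = split, resources = res, embeddings = embeddings,
       bilingual = bilingual)
}
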