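#' Precision, recall and F1 of predicted translation pairs
#'
#' Precision is the fraction of predicted pairs present in the gold lexicon;
#' recall is the fraction of gold pairs predicted; F1 is their harmonic
#' mean (0 when precision + recall is 0). Each gold pair counts once in the
#' recall denominator, so sources with several translations must have every
#' translation found for full recall. In `"top"` mode at most one
#' prediction per source is permitted.
#'
#' @param predictions data frame with columns `source` and `target`.
#' @param gold a [lexicon()] (typically the test split); predictions must
#'   only reference its sources.
#' @param mode `"all"` or `"top"`.
#' @return a list of class `bli_eval` with `precision`, `recall`, `f1`,
#'   `n_predicted`, `n_gold`, `mode` (proportions in `[0, 1]`).
#' @export
evaluate_bli <- function(predictions, gold, mode = c("all", "top")) {
  mode <- match.arg(mode)
  stray <- setdiff(predictions$source, gold$source)
  if (length(stray) > 0) {
    stop("prediction for source term(s) absent from the gold lexicon: ",
         paste(head(stray, 3), collapse = ", "))
  }
  if (mode == "top" && anyDuplicated(predictions$source)) {
    stop("'top' mode permits at most one prediction per source")
  }
  npred <- nrow(predictions)
  ngold <- nrow(gold)
  hits <- sum(pair_key(predictions$source, predictions$target) %in%
                pair_key(gold$source, gold$target))
  precision <- if (npred > 0) hits / npred else 0
  recall <- if (ngold > 0) hits / ngold else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_predicted = npred, n_gold = ngold, mode = mode),
            class = "bli_eval")
}

#' @export
print.bli_eval <- function(x, ...) {
  cat(sprintf("<bli_eval mode=%s> P %.2f%%  R %.2f%%  F1 %.2f%%  (%d predicted / %d gold)\n",
              x$mode, 100 * x$precision, 100 * x$recall, 100 * x$f1,
              x$n_predicted, x$n_gold))
  invisible(x)
}

#' Frequency-stratified evaluation
#'
#' For each cut-off `c`, restricts both gold pairs and predictions to pairs
#' whose source and target corpus frequencies are at least `c`, then
#' evaluates. A cut-off of 0 reproduces the unfiltered evaluation; a
#' stratum with no gold pairs is reported as `NA`.
#'
#' @param predictions,gold,mode as in [evaluate_bli()].
#' @param vocab_s,vocab_t [vocabulary()] objects with term frequencies.
#' @param cutoffs numeric vector of minimum frequencies.
#' @return data frame with one row per cut-off: `cutoff`, `n_gold`,
#'   `precision`, `recall`, `f1`.
#' @export
frequency_stratified <- function(predictions, gold, vocab_s, vocab_t,
                                 cutoffs = c(0, 5, 10, 25, 50, 125),
                                 mode = "all") {
  freq_of <- function(vocab, terms) {
    f <- unclass(vocab)[match(terms, names(vocab))]
    ifelse(is.na(f), 0, f)
  }
  rows <- lapply(cutoffs, function(cc) {
    gk <- freq_of(vocab_s, gold$source) >= cc & freq_of(vocab_t, gold$target) >= cc
    g <- gold[gk, , drop = FALSE]
    class(g) <- c("lexicon", "data.frame")
    pk <- freq_of(vocab_s, predictions$source) >= cc &
      freq_of(vocab_t, predictions$target) >= cc &
      predictions$source %in% g$source
    p <- predictions[pk, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(cutoff = cc, n_gold = 0L, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_))
    }
    ev <- evaluate_bli(p, g, mode)
    data.frame(cutoff = cc, n_gold = nrow(g), precision = ev$precision,
               recall = ev$recall, f1 = ev$f1)
  })
  do.call(rbind, rows)
}

#' Evaluation restricted to a subset of source terms
#'
#' Restricts the gold lexicon (and the predictions) to pairs whose source
#' term belongs to `subset` — for example, the cognate subset of a synthetic
#' benchmark, the analogue of evaluating on pairs with shared Greek or
#' Latin roots.
#'
#' @param predictions,gold,mode as in [evaluate_bli()].
#' @param subset non-empty character vector of source terms.
#' @return a `bli_eval`.
#' @export
subset_eval <- function(predictions, gold, subset, mode = "all") {
  if (length(subset) == 0) stop("empty evaluation subset")
  g <- gold[gold$source %in% subset, , drop = FALSE]
  class(g) <- c("lexicon", "data.frame")
  p <- predictions[predictions$source %in% subset, , drop = FALSE]
  evaluate_bli(p, g, mode)
}
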