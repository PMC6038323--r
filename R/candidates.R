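#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance; spaces inside phrases are
#' ordinary characters. Vectorized over pairs (shorter argument recycled).
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  cpp_levenshtein(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Length-normalized edit distance
#'
#' `levenshtein(a, b)` divided by the average character length of the two
#' terms, the classic handcrafted orthographic feature.
#'
#' @param a,b non-empty character vectors.
#' @return numeric vector.
#' @export
ed_norm <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("ed_norm is undefined for empty strings")
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  levenshtein(a, b) / ((nchar(a) + nchar(b)) / 2)
}

#' Log edit-distance rank feature
#'
#' The natural logarithm of the 1-based rank of `target` in the target
#' vocabulary sorted by ascending edit distance to `source` (ties broken by
#' lexicographic order of the target term). The edit-distance-closest
#' target has feature value `log(1) = 0`.
#'
#' @param source source term.
#' @param target target term; must be in `target_vocab`.
#' @param target_vocab character vector of target vocabulary terms (or a
#'   [vocabulary()]).
#' @return numeric scalar (vectorized over `target`).
#' @export
log_ed_rank <- function(source, target, target_vocab) {
  terms <- if (is.character(target_vocab)) target_vocab else names(target_vocab)
  if (!all(target %in% terms)) {
    stop("target term(s) not in the target vocabulary: ",
         paste(setdiff(target, terms), collapse = ", "))
  }
  d <- cpp_ed_all(source, terms)
  ord <- order(d, terms, method = "radix")
  rank <- match(target, terms[ord])
  log(rank)
}

#' Generate translation candidates for source terms
#'
#' For each source term, the union of (1) the `n_c` edit-distance-nearest
#' target terms and (2) the `n_c` cosine-nearest target terms in the merged
#' bilingual embedding space. Duplicates are collapsed (tagged `"both"`), so
#' a candidate set may hold fewer than `2 n_c` targets. Used at prediction
#' time only; training negatives come from uniform sampling.
#'
#' @param source_terms character vector.
#' @param n_c candidates per criterion (`N_c`); the total per source is at
#'   most `2 n_c`.
#' @param target_vocab [vocabulary()] (or character vector) of target terms.
#' @param bilingual bilingual embedding from [train_bwesg()], or `NULL` to
#'   use edit-distance candidates only.
#' @return data frame `source`, `candidate`, `provenance`
#'   (`"ed"`/`"cosine"`/`"both"`), `ed`, `cosine`.
#' @export
generate_candidates <- function(source_terms, n_c, target_vocab,
                                bilingual = NULL) {
  targets <- if (is.character(target_vocab)) target_vocab else names(target_vocab)
  nt <- length(targets)
  if (n_c > nt) {
    warning("n_c = ", n_c, " exceeds |V_T| = ", nt, "; capped")
    n_c <- nt
  }
  source_terms <- unique(as.character(source_terms))
  topk <- cpp_ed_topk(source_terms, targets, n_c, lex_rank(targets))
  ed_df <- data.frame(
    source = rep(source_terms, each = n_c),
    candidate = targets[as.vector(topk$idx)],
    ed = as.vector(topk$dist),
    from_ed = TRUE, cosine = NA_real_, from_cos = FALSE,
    stringsAsFactors = FALSE)

  cos_df <- NULL
  if (!is.null(bilingual)) {
    es <- embedding_language(bilingual, "source")
    et <- embedding_language(bilingual, "target")
    have_src <- source_terms %in% rownames(es)
    et_known <- intersect(targets, rownames(et))
    if (!all(have_src)) {
      warning(sum(!have_src),
              " source term(s) lack a bilingual vector; cosine candidates skipped for them")
    }
    if (any(have_src) && length(et_known) > 0) {
      k <- min(n_c, length(et_known))
      sims <- cosine_similarity(unclass(es)[source_terms[have_src], , drop = FALSE],
                                unclass(et)[et_known, , drop = FALSE])
      picks <- lapply(seq_len(nrow(sims)), function(i) {
        ord <- order(-sims[i, ], et_known, method = "radix")[seq_len(k)]
        data.frame(source = source_terms[have_src][i],
                   candidate = et_known[ord],
                   cosine = sims[i, ord],
                   stringsAsFactors = FALSE)
      })
      cos_df <- do.call(rbind, picks)
      cos_df$from_cos <- TRUE
      cos_df$ed <- NA_real_
      cos_df$from_ed <- FALSE
    }
  }

  all_df <- rbind(ed_df[, c("source", "candidate", "ed", "cosine",
                            "from_ed", "from_cos")],
                  if (!is.null(cos_df))
                    cos_df[, c("source", "candidate", "ed", "cosine",
                               "from_ed", "from_cos")])
  key <- pair_key(all_df$source, all_df$candidate)
  agg_ed <- tapply(all_df$from_ed, key, any)
  agg_cos <- tapply(all_df$from_cos, key, any)
  first <- !duplicated(key)
  out <- all_df[first, , drop = FALSE]
  k1 <- key[first]
  out$from_ed <- as.logical(agg_ed[k1])
  out$from_cos <- as.logical(agg_cos[k1])
  # fill the missing metric for merged rows
  need_ed <- is.na(out$ed)
  if (any(need_ed)) {
    out$ed[need_ed] <- levenshtein(out$source[need_ed], out$candidate[need_ed])
  }
  out$provenance <- ifelse(out$from_ed & out$from_cos, "both",
                           ifelse(out$from_ed, "ed", "cosine"))
  out <- out[order(out$source, out$ed, out$candidate, method = "radix"),
             c("source", "candidate", "provenance", "ed", "cosine")]
  rownames(out) <- NULL
  out
}

#' Recall of gold pairs within generated candidate sets
#'
#' The fraction of gold pairs whose target appears among the candidates of
#' its source. Gold pairs whose source received no candidates count as
#' misses: candidate generation is part of the system.
#'
#' @param candidates output of [generate_candidates()].
#' @param gold a [lexicon()].
#' @return numeric scalar in `[0, 1]`.
#' @export
candidate_recall <- function(candidates, gold) {
  mean(pair_key(gold$source, gold$target) %in%
         pair_key(candidates$source, candidates$candidate))
}
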