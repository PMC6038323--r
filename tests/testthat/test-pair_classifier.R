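test_that("character inventories contain exactly the observed characters plus pad/unk", {
  cv <- build_char_vocabs(c("ab", "ba"), c("xy"))
  expect_identical(cv$source, c("<pad>", "<unk>", "a", "b"))
  expect_identical(cv$target, c("<pad>", "<unk>", "x", "y"))
  # a phrase contributes the space character
  cv2 <- build_char_vocabs(c("blood cell"), c("bloedcel"))
  expect_true(" " %in% cv2$source)
  # unseen characters map to <unk> (index 2)
  enc <- encode_char_pair("aZ", "xy", cv)
  expect_equal(enc$src, c(3L, 2L))
})

test_that("character pairs are padded at the end of the shorter term", {
  cv <- build_char_vocabs("blood cell", "bloedcel")
  enc <- encode_char_pair("blood cell", "bloedcel", cv)
  expect_equal(enc$length, 10)
  expect_equal(sum(enc$tgt == 1L), 2) # two pads on the target side
  expect_equal(sum(enc$src == 1L), 0)

  cv2 <- build_char_vocabs(c("ab", "a"), c("abc"))
  same <- encode_char_pair("ab", "ab", build_char_vocabs("ab", "ab"))
  expect_false(any(same$src == 1L) || any(same$tgt == 1L))
  short <- encode_char_pair("a", "abc", cv2)
  expect_equal(short$src[2:3], c(1L, 1L))
  expect_error(encode_char_pair("", "abc", cv2), "empty")
})

test_that("word pair representation is the concatenation of the two embeddings", {
  set.seed(4)
  es <- embedding_table(matrix(rnorm(6), 2, 3), c("a", "b"), "s")
  et <- embedding_table(matrix(rnorm(6), 2, 3), c("x", "y"), "t")
  rep1 <- word_pair_representation("a", "y", es, et)
  expect_equal(nrow(rep1), 6)
  expect_equal(as.numeric(rep1), c(unclass(es)["a", ], unclass(et)["y", ]))
  ez <- embedding_table(rbind(0, unclass(es)["b", ]), c("z0", "b"), "s")
  expect_equal(as.numeric(word_pair_representation("z0", "x", ez, et))[1:3],
               c(0, 0, 0))
  expect_error(word_pair_representation("missing", "x", es, et),
               "without embedding")
})

test_that("model_config applies the paper-style defaults per feature set", {
  expect_equal(model_config("charpairs")$lstm_cells, 512L)
  expect_equal(model_config("combined")$lstm_cells, 256L)
  expect_equal(model_config("word")$epochs, 150L)
  expect_equal(model_config("charpairs")$epochs, 250L)
  cfg <- model_config("ed_norm")
  expect_equal(cfg$epochs, 25L)
  expect_equal(cfg$n_hidden, 0L) # one-dimensional features need no hidden layer
  expect_error(model_config("ed_norm", n_hidden = 2), "no hidden layers")
})

test_that("a hand-set feed-forward network reproduces direct arithmetic", {
  # 2-feature toy model with H = 1 and hand-chosen weights
  es <- embedding_table(matrix(c(0.3, -0.2), 1, 2), "s1", "s")
  et <- embedding_table(matrix(c(0.1, 0.4), 1, 2), "t1", "t")
  split <- split_lexicon(lexicon(paste0("s", 1:9), paste0("t", 1:9)), 1)
  cfg <- model_config("word", d = 2, epochs = 0L, n_hidden = 1L,
                      hidden_width = 2L, seed = 7)
  es9 <- embedding_table(matrix(seq(-0.4, 0.4, length.out = 18), 9, 2),
                         paste0("s", 1:9), "s")
  et9 <- embedding_table(matrix(seq(0.4, -0.4, length.out = 18), 9, 2),
                         paste0("t", 1:9), "t")
  model <- train_pair_classifier(split, cfg,
                                 embeddings = list(source = es9, target = et9),
                                 vocab_s = paste0("s", 1:9),
                                 vocab_t = paste0("t", 1:9))
  Wh <- matrix(c(0.5, -0.3, 0.2, 0.1, -0.6, 0.4, 0.9, -0.2), 2, 4)
  bh <- c(0.05, -0.1)
  Wo <- matrix(c(1.2, -0.7), 1, 2)
  bo <- 0.3
  model$params$Wh_1 <- Wh
  model$params$bh_1 <- bh
  model$params$Wo <- Wo
  model$params$bo <- bo
  got <- score_pairs(model, "s2", "t5")
  a0 <- as.numeric(word_pair_representation("s2", "t5", es9, et9))
  expect_equal(got, ref_ff_score(a0, list(Wh), list(bh), Wo, bo),
               tolerance = 1e-10)

  # all-zero output layer scores exactly sigmoid(0) = 0.5
  model$params$Wo <- matrix(0, 1, 2)
  model$params$bo <- 0
  expect_equal(score_pairs(model, "s2", "t5"), 0.5)
})

test_that("H = 0 wires the representation straight to the output unit", {
  set.seed(6)
  es <- embedding_table(matrix(rnorm(12), 6, 2), paste0("s", 1:6), "s")
  et <- embedding_table(matrix(rnorm(12), 6, 2), paste0("t", 1:6), "t")
  es[1, ] <- c(1, 0); et[2, ] <- c(0, 1)
  split <- split_lexicon(lexicon(paste0("s", 1:6), paste0("t", 1:6)), 1)
  cfg <- model_config("word", d = 2, epochs = 0L, n_hidden = 0L,
                      n_negative = 2, seed = 1)
  model <- train_pair_classifier(split, cfg,
                                 embeddings = list(source = es, target = et),
                                 vocab_s = paste0("s", 1:6),
                                 vocab_t = paste0("t", 1:6))
  w <- c(0.25, -0.5, 0.75, -1)
  model$params$Wo <- matrix(w, 1, 4)
  model$params$bo <- 0.1
  a0 <- as.numeric(word_pair_representation("s1", "t2", es, et))
  expect_equal(score_pairs(model, "s1", "t2"),
               1 / (1 + exp(-(sum(w * a0) + 0.1))))
})

test_that("the compiled character encoder matches an independent R reference", {
  bench <- tiny_benchmark()
  vocab_s <- unique(bench$lexicon$source)
  vocab_t <- unique(bench$lexicon$target)
  cv <- build_char_vocabs(vocab_s, vocab_t)
  split <- bench$split
  cfg <- model_config("charpairs", lstm_cells = 8, epochs = 0L, seed = 5,
                      n_hidden = 1L, hidden_width = 8L)
  model <- train_pair_classifier(split, cfg, char_vocab = cv,
                                 vocab_s = vocab_s, vocab_t = vocab_t)
  pairs <- bench$split$test[1:5, ]
  got <- char_pair_representation(model, pairs$source, pairs$target)
  for (i in seq_len(5)) {
    enc <- encode_char_pair(pairs$source[i], pairs$target[i], cv)
    want <- ref_lstm_repr(model$params, enc$src, enc$tgt,
                          length(cv$source), length(cv$target))
    expect_equal(got[, i], want, tolerance = 1e-10)
  }
  # batch assembly (length sorting / masking) must not change per-pair output
  one <- char_pair_representation(model, pairs$source[3], pairs$target[3])
  expect_equal(one[, 1], got[, 3], tolerance = 1e-12)
  # eval-mode scoring is deterministic (dropout off)
  s1 <- score_pairs(model, pairs$source, pairs$target)
  s2 <- score_pairs(model, pairs$source, pairs$target)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("negative sampling emits 2*N_s pairs, avoids the lexicon, and is seeded", {
  lex <- lexicon(c("s1", "s2"), c("t1", "t2"))
  vs <- paste0("s", 1:20); vt <- paste0("t", 1:20)
  neg <- sample_negatives("s1", "t1", 5, vs, vt, lex, seed = 3)
  expect_equal(nrow(neg), 10)
  expect_false(any(paste(neg$source, neg$target) %in%
                     paste(lex$source, lex$target)))
  neg2 <- sample_negatives("s1", "t1", 5, vs, vt, lex, seed = 3)
  expect_identical(neg, neg2)
  # forced exclusion: the only non-lexicon target must always be chosen
  lex2 <- lexicon(rep("s1", 2), c("t1", "t2"))
  for (sd in 1:10) {
    n1 <- sample_negatives("s1", "t1", 1, c("s1", "s9"), c("t1", "t2", "t3"),
                           lex2, seed = sd)
    expect_equal(n1$target[1], "t3")
  }
  expect_error(sample_negatives("s1", "t1", 5, vs[1:3], vt[1:3], lex),
               "too small")
})

test_that("cross-entropy matches hand arithmetic and clamps saturated scores", {
  expect_equal(cross_entropy_loss(0.5, 1), -log(0.5))
  expect_lt(cross_entropy_loss(1 - 1e-9, 1), 1e-6)
  scores <- c(0.9, 0.2, 0.6, 0.4)
  labels <- c(1, 0, 1, 0)
  want <- sum(-labels * log(scores) - (1 - labels) * log(1 - scores))
  expect_equal(cross_entropy_loss(scores, labels), want)
  expect_message(v <- cross_entropy_loss(c(0, 1), c(0, 1)), "clamped")
  expect_true(is.finite(v))
})

test_that("training reduces the loss, freezes embeddings, and honors zero epochs", {
  bench <- tiny_benchmark()
  res <- cached("tiny_res",
                build_resources(bench$corpus, phrase_config(2, 5),
                                phrase_config(2, 5), 5))
  emb <- cached("tiny_emb", list(
    source = train_monolingual(res$docs_s, d = 20, epochs = 3, seed = 1),
    target = train_monolingual(res$docs_t, d = 20, epochs = 3, seed = 2)))
  emb_before <- list(source = unclass(emb$source), target = unclass(emb$target))
  split <- bench$split
  split$train <- filter_lexicon(split$train, res$vocab_s, res$vocab_t)
  cfg <- model_config("combined", d = 20, lstm_cells = 12, epochs = 8L,
                      hidden_width = 24L, seed = 9)
  cv <- build_char_vocabs(res$vocab_s, res$vocab_t)
  model <- train_pair_classifier(split, cfg, emb, cv,
                                 res$vocab_s, res$vocab_t)
  expect_length(model$epoch_loss, 8)
  expect_lt(tail(model$epoch_loss, 1), model$epoch_loss[1])
  # embedding tables are bit-identical after joint training
  expect_identical(unclass(emb$source), emb_before$source)
  expect_identical(unclass(emb$target), emb_before$target)

  cfg0 <- model_config("combined", d = 20, lstm_cells = 12, epochs = 0L,
                       seed = 9)
  m0 <- train_pair_classifier(split, cfg0, emb, cv, res$vocab_s, res$vocab_t)
  expect_length(m0$epoch_loss, 0)
  s <- score_pairs(m0, split$train$source[1:4], split$train$target[1:4])
  expect_true(all(s > 0 & s < 1))
})

test_that("an edit-distance baseline solves a separable toy problem perfectly", {
  # positives share spelling (ed_norm ~ 0); negatives are maximally far
  src <- vapply(rep(6, 30), random_string, character(1), alphabet = letters[1:6])
  src <- unique(src)
  tgt <- src # identical spelling -> ed_norm 0
  lex <- lexicon(src, tgt)
  split <- split_lexicon(lex, 2)
  far <- vapply(rep(6, 40), random_string, character(1),
                alphabet = LETTERS[1:6])
  vocab_t <- unique(c(tgt, far))
  cfg <- model_config("ed_norm", epochs = 25L, n_negative = 3, seed = 11)
  model <- train_pair_classifier(split, cfg, vocab_s = src, vocab_t = vocab_t)
  cand <- generate_candidates(unique(split$test$source), 3, vocab_t)
  thr <- tune_threshold(model, split$validation,
                        generate_candidates(unique(split$validation$source),
                                            3, vocab_t))
  model$threshold <- as.numeric(thr)
  preds <- classify_pairs(model, cand, mode = "all")
  ev <- evaluate_bli(preds, split$test, "all")
  expect_equal(ev$f1, 1)
})

test_that("threshold tuning returns the exhaustive-grid argmax with smallest-t ties", {
  bench <- tiny_benchmark()
  vocab_t <- unique(bench$lexicon$target)
  cv <- build_char_vocabs(unique(bench$lexicon$source), vocab_t)
  cfg <- model_config("charpairs", lstm_cells = 12, epochs = 6L, seed = 13)
  model <- train_pair_classifier(bench$split, cfg, char_vocab = cv,
                                 vocab_s = unique(bench$lexicon$source),
                                 vocab_t = vocab_t)
  val <- bench$split$validation
  cand <- generate_candidates(unique(val$source), 4, vocab_t)
  thr <- tune_threshold(model, val, cand, mode = "all")
  grid <- attr(thr, "grid")
  # brute-force scan oracle over the same scored candidates
  scores <- score_pairs(model, cand$source, cand$candidate)
  ref <- vapply(grid$threshold, function(t) {
    keep <- scores > t
    hits <- sum(paste(cand$source[keep], cand$candidate[keep]) %in%
                  paste(val$source, val$target))
    ref_f1(hits, sum(keep), nrow(val))
  }, numeric(1))
  expect_equal(grid$f1, ref)
  expect_equal(as.numeric(thr), grid$threshold[which.max(grid$f1)])
  # all-equal curve ties to the smallest threshold
  flat <- tune_threshold(model, val, cand[0, ], mode = "all")
  expect_equal(as.numeric(flat), 0.1)
  expect_error(tune_threshold(model, val[0, ], cand), "empty validation")
})

test_that("classification applies the decision rule in both modes", {
  # use a trivially rigged model via direct threshold_predictions-like path
  bench <- tiny_benchmark()
  vocab_t <- unique(bench$lexicon$target)
  cv <- build_char_vocabs(unique(bench$lexicon$source), vocab_t)
  cfg <- model_config("charpairs", lstm_cells = 8, epochs = 0L, seed = 1)
  model <- train_pair_classifier(bench$split, cfg, char_vocab = cv,
                                 vocab_s = unique(bench$lexicon$source),
                                 vocab_t = vocab_t)
  srcs <- unique(bench$split$test$source)[1:10]
  cand <- generate_candidates(srcs, 3, vocab_t)
  scores <- score_pairs(model, cand$source, cand$candidate)

  model$threshold <- 0
  top <- classify_pairs(model, cand, mode = "top")
  expect_equal(nrow(top), length(unique(cand$source)))
  expect_false(anyDuplicated(top$source) > 0)

  model$threshold <- 1 # scores are < 1, so nothing passes
  expect_equal(nrow(classify_pairs(model, cand, mode = "all")), 0)
  expect_equal(nrow(classify_pairs(model, cand[0, ], mode = "all")), 0)

  model$threshold <- as.numeric(quantile(scores, 0.5))
  all_preds <- classify_pairs(model, cand, mode = "all")
  expect_true(all(all_preds$score > model$threshold))
  # top predictions are a subset of all-mode predictions
  top2 <- classify_pairs(model, cand, mode = "top")
  expect_true(all(paste(top2$source, top2$target) %in%
                    paste(all_preds$source, all_preds$target)))
})
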