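test_that("ratio merging interleaves by length ratio and conserves tokens", {
  out <- merge_documents(c("s1", "s2", "s3", "s4"), c("t1", "t2"))
  expect_identical(out, c("s1", "s2", "t1", "s3", "s4", "t2"))
  # inverse ratio: longer target side
  out2 <- merge_documents(c("s1", "s2"), c("t1", "t2", "t3", "t4"))
  expect_identical(out2, c("t1", "t2", "s1", "t3", "t4", "s2"))
  # conservation on ragged lengths
  set.seed(5)
  for (i in 1:20) {
    a <- sample(letters, sample(1:15, 1), replace = TRUE)
    b <- sample(LETTERS, sample(1:15, 1), replace = TRUE)
    m <- merge_documents(a, b)
    expect_identical(sort(m), sort(c(a, b)))
  }
  expect_error(merge_documents(character(0), "x"), "empty")
})

test_that("shuffle merging is seed-deterministic and conserves the multiset", {
  a <- paste0("s", 1:7); b <- paste0("t", 1:4)
  m1 <- merge_documents(a, b, mode = "shuffle", seed = 9)
  m2 <- merge_documents(a, b, mode = "shuffle", seed = 9)
  expect_identical(m1, m2)
  expect_identical(sort(m1), sort(c(a, b)))
})

test_that("skip-gram training returns the requested dimensionality, deterministically", {
  docs <- tiny_benchmark()$corpus$source
  e1 <- train_monolingual(docs, d = 20, epochs = 1, seed = 4)
  e2 <- train_monolingual(docs, d = 20, epochs = 1, seed = 4)
  expect_identical(unclass(e1), unclass(e2))
  expect_equal(ncol(e1), 20)
  expect_true(all(is.finite(e1)))
  expect_error(train_monolingual(list(character(0))), "empty vocabulary")
})

test_that("words with shared contexts embed closer than random word pairs", {
  set.seed(8)
  # "aaa" and "bbb" are interchangeable in context; others are random
  docs <- lapply(1:300, function(i) {
    w <- sample(c("aaa", "bbb"), 1)
    c(sample(c("ctx1", "ctx2"), 1), w, sample(c("ctx3", "ctx4"), 1),
      sample(paste0("r", 1:30), 5, replace = TRUE))
  })
  emb <- train_monolingual(docs, d = 25, epochs = 10, subsample = 0, seed = 2)
  target_cos <- cosine_similarity(emb["aaa", , drop = FALSE],
                                  emb["bbb", , drop = FALSE])[1, 1]
  others <- unclass(emb)[paste0("r", 1:30), ]
  rand_cos <- cosine_similarity(others, others)
  mean_rand <- mean(rand_cos[upper.tri(rand_cos)])
  expect_gt(target_cos, mean_rand)
})

test_that("merged-document embeddings cover both languages and carry cross-lingual signal", {
  bench <- tiny_benchmark()
  bi <- train_bwesg(bench$corpus, d = 25, window = 50, epochs = 3, seed = 6)
  es <- embedding_language(bi, "source")
  et <- embedding_language(bi, "target")
  expect_equal(nrow(bi), nrow(es) + nrow(et))

  # planted translation pairs should sit closer than random cross-lingual pairs
  lex <- bench$lexicon
  ok <- lex$source %in% rownames(es) & lex$target %in% rownames(et)
  lex <- lex[ok, ][1:50, ]
  pair_cos <- rowMeans(row_norm(unclass(es)[lex$source, ]) *
                         row_norm(unclass(et)[lex$target, ]))
  set.seed(1)
  rand_t <- sample(rownames(et), 50)
  rand_cos <- rowMeans(row_norm(unclass(es)[lex$source, ]) *
                         row_norm(unclass(et)[rand_t, ]))
  expect_gt(mean(pair_cos), mean(rand_cos))
})

test_that("an exact linear relation between spaces is recovered by least squares", {
  set.seed(3)
  d <- 8; n <- 40
  X <- matrix(rnorm(n * d), n, d)
  R <- qr.Q(qr(matrix(rnorm(d * d), d))) # random rotation
  Z <- X %*% t(R)
  terms_s <- paste0("s", 1:n); terms_t <- paste0("t", 1:n)
  es <- embedding_table(X, terms_s, "s")
  et <- embedding_table(Z, terms_t, "t")
  train <- lexicon(terms_s[1:25], terms_t[1:25])
  M <- fit_translation_matrix(train, es, et)
  expect_lt(max(abs(M - R)), 1e-6)

  # identity spaces give the identity map
  ei <- embedding_table(X, terms_s, "s")
  Mi <- fit_translation_matrix(lexicon(terms_s[1:20], terms_s[1:20]), ei, ei)
  expect_lt(max(abs(Mi - diag(d))), 1e-6)

  # held-out pairs retrieved at rank 1
  preds <- sim_baseline_predict(terms_s[26:40], es, et, map = M, mode = "top")
  expect_identical(preds$target, terms_t[26:40])

  expect_warning(fit_translation_matrix(lexicon("s1", "t1"), es, et),
                 "underdetermined")
  expect_error(fit_translation_matrix(lexicon("zz", "yy"), es, et),
               "no training pair")
})

test_that("similarity baseline respects top/all semantics", {
  m <- diag(3)
  es <- embedding_table(m[1:2, , drop = FALSE], c("s1", "s2"), "s")
  et <- embedding_table(m, c("t1", "t2", "t3"), "t")
  top <- sim_baseline_predict(c("s1", "s2"), es, et, mode = "top")
  expect_identical(top$target, c("t1", "t2")) # identical vectors win argmax
  all_none <- sim_baseline_predict("s1", es, et, mode = "all",
                                   threshold = 1 + 1e-9)
  expect_equal(nrow(all_none), 0)
  all_some <- sim_baseline_predict("s1", es, et, mode = "all", threshold = 0.5)
  expect_identical(all_some$target, "t1")
  expect_warning(sim_baseline_predict(c("s1", "nope"), es, et, mode = "top"),
                 "missing")
})

test_that("word2vec text round-trips, including phrase terms", {
  set.seed(2)
  m <- matrix(rnorm(6), 3, 2)
  tab <- embedding_table(m, c("word", "blood cell", "x"), "en")
  f <- tempfile()
  write_word2vec(tab, f)
  back <- read_word2vec(f, "en")
  expect_identical(rownames(back), rownames(tab))
  expect_equal(unclass(back), unclass(tab), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(as.integer(strsplit(readLines(f, n = 1), " ")[[1]]), c(3L, 2L))
})
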