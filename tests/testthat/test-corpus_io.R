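test_that("read_corpus aligns documents and enforces equal counts", {
  dirs <- write_corpus_dirs(list("Blood cell biology.", "Cranial nerves."),
                            list("Bloedcel biologie.", "Hersenzenuwen."))
  corp <- read_corpus(dirs$source, dirs$target, c("en", "nl"))
  expect_s3_class(corp, "comparable_corpus")
  expect_length(corp, 2)
  expect_false(corp$tokenized)

  # 3 vs 2 documents must fail
  writeLines("extra", file.path(dirs$source, "doc_999.txt"))
  expect_error(read_corpus(dirs$source, dirs$target), "alignment error")

  # empty directories give an empty corpus with a warning
  e1 <- tempfile(); e2 <- tempfile()
  dir.create(e1); dir.create(e2)
  expect_warning(empty <- read_corpus(e1, e2), "empty corpus")
  expect_length(empty, 0)
})

test_that("read_corpus accepts manifest files and names unreadable files", {
  dirs <- write_corpus_dirs(list("a b"), list("c d"))
  man_s <- tempfile(); man_t <- tempfile()
  writeLines(list.files(dirs$source, full.names = TRUE), man_s)
  writeLines(list.files(dirs$target, full.names = TRUE), man_t)
  corp <- read_corpus(man_s, man_t)
  expect_length(corp, 1)

  writeLines(c(list.files(dirs$source, full.names = TRUE), "/no/such/file"),
             man_s)
  writeLines(c(list.files(dirs$target, full.names = TRUE),
               list.files(dirs$target, full.names = TRUE)), man_t)
  expect_error(read_corpus(man_s, man_t), "/no/such/file")
})

test_that("preprocessing lowercases, strips edge punctuation, and is idempotent", {
  expect_identical(tokenize("Blood Cell."), c("blood", "cell"))
  expect_identical(tokenize("EPO, EMDR"), c("epo", "emdr"))
  expect_identical(tokenize(""), character(0))
  # internal hyphens and apostrophes survive
  expect_identical(tokenize("X-ray's scan"), c("x-ray's", "scan"))

  corp <- comparable_corpus(list("Blood Cell.", "(EPO, EMDR)"),
                            list("Bloedcel!", ""))
  expect_message(p1 <- preprocess_corpus(corp), "empty")
  expect_true(p1$tokenized)
  expect_identical(p1$source[[1]], c("blood", "cell"))
  suppressMessages(p2 <- preprocess_corpus(p1))
  expect_identical(p1$source, p2$source)
  expect_identical(p1$target, p2$target)
})

test_that("read_lexicon parses, lowercases, dedupes and reports bad rows", {
  f <- tempfile()
  writeLines(c("Angiography\tangiografie",
               "angiography\tangiografie",
               "x\ty1", "x\ty2"), f)
  lex <- read_lexicon(f)
  expect_s3_class(lex, "lexicon")
  expect_equal(nrow(lex), 3)
  expect_true(any(lex$source == "angiography" & lex$target == "angiografie"))
  expect_equal(sum(lex$source == "x"), 2) # multiple translations allowed

  writeLines(c("a\tb", "broken row"), f)
  expect_error(read_lexicon(f), "line 2")
})

test_that("filter_lexicon keeps exactly the in-vocabulary pairs and is monotone", {
  lex <- lexicon(c("a", "b", "c"), c("x", "y", "z"))
  small <- filter_lexicon(lex, c("a", "b"), c("x", "z"))
  expect_equal(small$source, "a")
  big <- filter_lexicon(lex, c("a", "b", "c"), c("x", "y", "z"))
  expect_equal(nrow(big), 3)
  # subset of input, monotone in vocabulary
  expect_true(all(pair_key <- paste(small$source, small$target) %in%
                    paste(big$source, big$target)))
})

test_that("split_lexicon partitions 80/20 then 80/20 and is reproducible", {
  lex <- lexicon(paste0("s", 1:100), paste0("t", 1:100))
  sp <- split_lexicon(lex, seed = 1)
  expect_equal(c(nrow(sp$train), nrow(sp$validation), nrow(sp$test)),
               c(64, 16, 20))
  sp2 <- split_lexicon(lex, seed = 1)
  expect_identical(sp, sp2)
  # partition: disjoint, union equals the input
  all_pairs <- rbind(sp$train[1:2], sp$validation[1:2], sp$test[1:2])
  expect_equal(nrow(all_pairs), 100)
  expect_false(any(duplicated(all_pairs)))
  expect_setequal(paste(all_pairs$source, all_pairs$target),
                  paste(lex$source, lex$target))
  expect_error(split_lexicon(lexicon(c("a", "b"), c("x", "y"))), "too small")
})

test_that("lexicon_stats reports composition, polysemy and retention", {
  lex <- lexicon(c("blood cell", "nerve", "nerve", "heart attack"),
                 c("bloed cel", "zenuw", "nerf", "hartaanval"))
  st <- lexicon_stats(lex)
  expect_equal(st$phrase_phrase_pct, 25)
  expect_equal(st$word_phrase_pct, 25)
  expect_equal(st$word_word_pct, 50)
  # sources {nerve: 2, blood cell: 1, heart attack: 1} -> 1/3 multi
  expect_equal(st$multi_translation_pct, 100 / 3)

  one <- lexicon("a", "b")
  expect_equal(lexicon_stats(one)$word_word_pct, 100)

  # retention from entry counts
  orig <- lexicon(paste0("s", 1:50), paste0("t", 1:50))
  kept <- filter_lexicon(orig, paste0("s", 1:20), paste0("t", 1:50))
  st2 <- lexicon_stats(kept, original = orig)
  expect_equal(st2$retention_pct, 40)

  # mean corpus frequency uses the vocabulary counts
  v_s <- vocabulary(c(10L, 30L), c("a", "b"), "s")
  v_t <- vocabulary(c(7L), c("x"), "t")
  st3 <- lexicon_stats(lexicon(c("a", "b"), c("x", "x")), v_s, v_t)
  expect_equal(st3$mean_source_freq, 20)
  expect_equal(st3$mean_target_freq, 7)
})
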