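# shared fixtures and independent reference implementations

# cache expensive objects across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small cognate-heavy benchmark used by several classifier tests
tiny_benchmark <- function() {
  cached("tiny_benchmark", {
    generate_benchmark(gen_config(n_pairs = 250, n_docs = 30,
                                  doc_length = 150, n_filler = 30,
                                  phrase_pair_count = 10, seed = 3))
  })
}

# write a corpus to a temporary directory pair (for read_corpus tests)
write_corpus_dirs <- function(docs_s, docs_t, root = tempfile("corp")) {
  ds <- file.path(root, "source"); dt <- file.path(root, "target")
  dir.create(ds, recursive = TRUE); dir.create(dt, recursive = TRUE)
  for (i in seq_along(docs_s)) {
    writeLines(docs_s[[i]], file.path(ds, sprintf("doc_%03d.txt", i)))
  }
  for (i in seq_along(docs_t)) {
    writeLines(docs_t[[i]], file.path(dt, sprintf("doc_%03d.txt", i)))
  }
  list(source = ds, target = dt)
}

# independent two-layer LSTM forward pass (reference for the compiled
# encoder): plain R, single sequence, same parameterization
ref_lstm_repr <- function(params, src_idx, tgt_idx, n_src, n_tgt) {
  C <- ncol(params$Wh1)
  sig <- function(x) 1 / (1 + exp(-x))
  onehot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  h1 <- c1 <- h2 <- c2 <- numeric(C)
  for (t in seq_along(src_idx)) {
    x <- c(onehot(src_idx[t], n_src), onehot(tgt_idx[t], n_tgt))
    pre1 <- params$Wx1 %*% x + params$Wh1 %*% h1 + params$b1
    i1 <- sig(pre1[1:C]); f1 <- sig(pre1[(C + 1):(2 * C)])
    g1 <- tanh(pre1[(2 * C + 1):(3 * C)]); o1 <- sig(pre1[(3 * C + 1):(4 * C)])
    c1 <- f1 * c1 + i1 * g1
    h1 <- o1 * tanh(c1)
    pre2 <- params$Wx2 %*% h1 + params$Wh2 %*% h2 + params$b2
    i2 <- sig(pre2[1:C]); f2 <- sig(pre2[(C + 1):(2 * C)])
    g2 <- tanh(pre2[(2 * C + 1):(3 * C)]); o2 <- sig(pre2[(3 * C + 1):(4 * C)])
    c2 <- f2 * c2 + i2 * g2
    h2 <- o2 * tanh(c2)
  }
  as.numeric(h2)
}

# reference feed-forward scorer for hand-checkable networks
ref_ff_score <- function(a0, Wh, bh, Wo, bo) {
  sig <- function(x) 1 / (1 + exp(-x))
  a <- a0
  for (i in seq_along(Wh)) a <- sig(Wh[[i]] %*% a + bh[[i]])
  as.numeric(sig(Wo %*% a + bo))
}

# hand F1 from a contingency of hits / predicted / gold
ref_f1 <- function(hits, n_pred, n_gold) {
  p <- if (n_pred > 0) hits / n_pred else 0
  r <- if (n_gold > 0) hits / n_gold else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

random_string <- function(len, alphabet = letters) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

row_norm <- function(m) m / sqrt(rowSums(m^2))
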