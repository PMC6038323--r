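---
title: "Mining term translations from comparable corpora: the bilex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining term translations from comparable corpora: the bilex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilex)
```

## The problem

Specialized domains such as biomedicine coin terminology faster than
bilingual dictionaries can track it, and parallel corpora for such domains
are scarce. What is often available instead is a *comparable corpus*:
pairs of documents in two languages that discuss the same topic without
being translations of each other (for example, topic-aligned encyclopedia
articles). Bilingual lexicon induction (BLI) is the task of mining
translation pairs — single words and multi-word terms — from such corpora,
starting from a modest seed lexicon.

Domain terminology has a property that generic BLI methods underuse: terms
in related languages frequently descend from shared Greek or Latin roots
(*angiography : angiografie*), so spelling itself is a strong translation
signal, alongside the distributional signal that translations occur in
topically aligned contexts.

## The model

bilex frames BLI as binary classification over candidate pairs
$(p^S, p^T) \in V^S \times V^T$. A network $f$ produces a translation
score in $(0,1)$ and the decision rule is

$$ g(p^S, p^T) = +1 \iff f(p^S, p^T) > t, $$

with $t$ a threshold tuned on validation F1. Thresholding (rather than
taking a single argmax per source) lets one source term legitimately keep
several translations.

The score combines two representations:

* **Character-pair encoder.** The two terms are written as aligned
  character sequences: position $i$ carries the one-hot pair (source char
  $i$, target char $i$), the shorter term padded at the end with a special
  padding symbol; the space inside multi-word terms is an ordinary
  character. A two-layer LSTM reads this sequence, and its second layer's
  hidden output at the final position is the pair representation
  $r^{ST}_c$. Dropout (keep probability 0.5) is applied to the encoder's
  output connections during training.
* **Word-level representation.** $r^{ST}_p$ is the concatenation of the two
  terms' $d$-dimensional word embeddings ($d = 50$), trained in advance and
  held fixed during classifier training. Two embedding types are supported:
  monolingual skip-gram with negative sampling (window 5), and
  pseudo-bilingual embeddings obtained by merging each aligned document
  pair into one pseudo-document (length-ratio interleave by default) and
  training skip-gram with a large window (100) over the result, which
  places both languages in one space.

The combined input $r_{h_0} = r^{ST}_p \,\|\, r^{ST}_c$ (or a single
representation for the single-component models, or raw edit-distance
features for the handcrafted baselines) passes through $H$ fully connected
sigmoid layers ($H = 2$ by default; $H = 0$ for the one/two-dimensional
edit-distance baselines, which reduce to logistic models) and a sigmoid
output unit. Training minimizes cross-entropy with mini-batch Adam
(batches of 10): each gold pair is joined by $2 N_s$ negatives formed by
pairing its source with $N_s$ uniformly sampled target terms and its
target with $N_s$ sampled source terms (default $2 N_s = 10$), resampling
any collision with the training lexicon. Negative sets are drawn once per
run under the run seed.

### Vocabularies and phrases

Vocabularies contain every word occurring at least `min_count = 5` times
plus multi-word collocations extracted iteratively: in each of 4 passes,
an adjacent bigram is merged when its score

$$ \mathrm{score}(w_i, w_j) = \frac{\mathrm{count}(w_i w_j) - \delta}
   {\mathrm{count}(w_i)\,\mathrm{count}(w_j)} \cdot |V| $$

exceeds a threshold; merged tokens act as single tokens in later passes,
and a merge is only allowed while the resulting phrase stays within
`pass + 1` words, so 4 passes yield n-grams up to length 5. $|V|$ is the
type count of the current pass. The discount $\delta$ suppresses phrases
built from very rare words. $(\delta, \mathrm{threshold})$ can be tuned
per language by maximizing recall of the training lexicon's multi-word
terms ([tune_extraction()]). Words that only ever occur inside an
extracted phrase are not given their own vocabulary entry, since no
representation would be learned for them.

### Candidate generation and evaluation

Scoring all $|V^S| \times |V^T|$ pairs is quadratic, so prediction scores
only $2 N_c$ candidates per source: the $N_c$ targets nearest in edit
distance plus the $N_c$ nearest by cosine in the merged bilingual space,
duplicates collapsed (default $2 N_c = 10$). Gold pairs whose target never
enters the candidate set count as recall failures — candidate generation
is part of the system.

Since induction targets translations *not yet* in the seed lexicon, the
pipeline by default removes candidate pairs that already appear in the
train/validation lexicon before prediction (`exclude_known`). With
entry-level splits this matters for sources with several translations:
re-proposing the known seed pair for such a source is correct model
behavior but would be scored as a false positive against the test split.

Evaluation reports precision, recall and F1 in two modes: *top* (at most
one prediction per source, the best-scoring candidate above $t$) and
*all* (every candidate above $t$), the latter rewarding correct handling
of sources with several translations. Each gold pair counts once in the
recall denominator. The threshold grid is $t \in \{0.1, \ldots, 1.0\}$,
ties to the smallest $t$; tuning optimizes all-mode F1 by default.

## The synthetic benchmark

No public corpus accompanies the method at the scale this package targets,
so `generate_benchmark()` builds one with controllable signal:

* **Lexicon.** `n_pairs` source words over the letters a–m. An exact
  `cognate_rate` fraction of targets is derived from the source by an
  ordered, deterministic rewrite rule set (consonant shift, suffix
  rewrites, and a final vowel append that guarantees every derived form
  differs from its source) — these pairs sit 1–3 edits apart, emulating
  shared-root spelling. The remaining targets are random words over the
  *disjoint* letters n–z, so unrelated pairs are maximally distinct in
  both inventory and edit distance. An exact `polysemy_rate` fraction of
  sources (default 0.2, matching the share of multi-translation sources
  typical of domain lexicons) receives a second translation: a spelling
  variant of the cognate target, or a second unrelated word.
  `phrase_pair_count` entries (default 7.7% of `n_pairs`) are two-word on
  both sides.
* **Corpus.** Terms (plus filler pairs) are partitioned into topics; each
  aligned document pair samples a topic and draws terms under a Zipf-like
  within-topic rank-frequency law (exponent 1). The source document emits
  the drawn source terms; the target document emits a translation of each
  drawn term in independently shuffled order, so translations co-occur at
  the document level without sentence alignment. Multi-word terms are
  always emitted as adjacent tokens. A top-up pass inserts occurrences at
  random positions until every lexicon word reaches `min_count` (multi-word
  terms reach `min_count + 10`, keeping their collocation score clear of
  the discount), which guarantees 100% lexicon retention after vocabulary
  filtering.
* Generation is byte-identical under a fixed seed.

What the generator does **not** emulate: natural morphology and syntax,
ambiguous spelling overlap between related and unrelated pairs, bursty
document-level frequencies, or noisy seed lexicons. Passing the synthetic
experiments therefore demonstrates that the implementation learns the two
planted signals and that the pipeline is internally consistent — not that
a particular F1 carries over to real corpora.

The two signals are separable by construction: a character-only model must
beat a word-only model on cognate-pure data and the reverse on
cognate-free data (this is a test invariant), which is precisely the
diagnostic that motivates combining the two representations.

## Numerical and design choices

* **Recurrent core.** The encoder, combiner, Adam, and the skip-gram
  trainer are implemented in compiled code inside the package; the test
  suite checks the encoder against an independent plain-R LSTM reference
  and the trainer against learning-curve and separability properties.
  Parameters start from uniform(−0.1, 0.1) with forget-gate biases at 1;
  all randomness (initialization, shuffling, dropout, sampling) derives
  from one integer seed per run.
* **"Output at the final state"** is the second LSTM layer's hidden output
  (not the cell state) at the last padded position.
* **Hidden width.** Unstated upstream; default is the width of $r_{h_0}$,
  constant across the $H$ layers — capacity without new hyper-parameters.
* **Loss clamping.** Scores are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside
  the loss to avoid $\log 0$.
* **Ties.** Candidate and rank ties break lexicographically (C locale);
  threshold ties take the smaller $t$; greedy phrase merging is
  left-to-right and non-overlapping.
* **Splits** are by lexicon entry (80/20, then 80/20 of the training
  portion), so two translations of one source can land in different
  splits; nothing upstream mandates stratification by source.
* **Subsampling at small scale.** The word2vec frequency-subsampling rule
  compares counts against `threshold × corpus size`; at the classic
  `1e-4` a synthetic corpus of ~10^5 tokens would lose nearly every
  token. The embedding trainers keep `1e-4` as their default for
  realistic corpora, but `run_experiment()` disables subsampling — a
  corpus-scale calibration, not a tuned value.
* **Problem sizes.** The bundled experiments train on benchmarks of
  250–5,000 pairs with 48 (character-only) or 24 (combined) LSTM cells,
  mini-batches of 20–40 and ≤ 35 epochs. The synthetic alphabet has 13
  letters and the vocabularies a few thousand entries, so the settings
  appropriate for a real bilingual corpus (hundreds of cells, hundreds of
  epochs, batches of 10 — the package defaults in `model_config()`) are
  unnecessary there; the smaller sizes are the package's choice of
  experiment scale.

## Known limitations

* Byte-level character handling: multi-byte UTF-8 characters are treated
  as byte sequences by the edit-distance and encoder machinery; for
  non-ASCII scripts a transliteration step (out of scope here) would be
  required anyway.
* The underscore alias that makes phrase tokens single tokens during
  embedding training assumes corpus tokens contain no literal underscores.
* Fixed (per-run) negative sets rather than per-epoch resampling; with
  the default $2N_s = 10$ this has not been a practical limitation on the
  synthetic benchmarks.
* The word-level route depends entirely on the quality of the input
  embeddings; on very small corpora it saturates near the topical level
  of granularity.
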