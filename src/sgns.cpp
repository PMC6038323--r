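#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and deterministic for a
// given seed. Follows the reference word2vec procedure: dynamic window,
// frequency subsampling, unigram^{3/4} noise distribution, linear learning
// rate decay. Windows never cross document boundaries.

// precomputed logistic table over [-6, 6], word2vec-style
static const int EXP_TABLE_SIZE = 1000;
static const double MAX_EXP = 6.0;
static double exp_table[EXP_TABLE_SIZE];
static bool exp_table_ready = false;

static inline void init_exp_table() {
  if (exp_table_ready) return;
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    exp_table[i] = e / (e + 1.0);
  }
  exp_table_ready = true;
}

static inline double sigmoidd(double x) {
  if (x >= MAX_EXP) return 1.0;
  if (x <= -MAX_EXP) return 0.0;
  return exp_table[(int)((x + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0))];
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(IntegerVector tokens, IntegerVector doc_len,
                             IntegerVector counts, int d, int window,
                             int negative, int epochs, double alpha0,
                             double sample, int seed) {
  const int V = counts.size();
  const R_xlen_t N = tokens.size();
  if (V == 0) stop("empty vocabulary");
  init_exp_table();

  // unigram^{0.75} table for negative sampling
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < V; ++i) total += std::pow((double)counts[i], 0.75);
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((double)a / table_size > cum && i < V - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0((size_t)V * d), syn1((size_t)V * d, 0.0);
  uint64_t rng = (uint64_t)seed ? (uint64_t)seed : 1ULL;
  auto next_rand = [&rng]() {
    rng = rng * 25214903917ULL + 11ULL;
    return rng;
  };
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (((next_rand() & 0xFFFF) / 65536.0) - 0.5) / d;
  }

  double train_words = 0;
  for (int i = 0; i < V; ++i) train_words += counts[i];

  std::vector<double> neu1e(d);
  const double total_work = (double)epochs * N;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    R_xlen_t pos = 0;
    for (R_xlen_t dnum = 0; dnum < doc_len.size(); ++dnum) {
      R_xlen_t start = pos, end = pos + doc_len[dnum];
      // subsample this document's tokens
      std::vector<int> sent;
      sent.reserve(end - start);
      for (R_xlen_t p = start; p < end; ++p) {
        int w = tokens[p];
        if (sample > 0) {
          double f = (double)counts[w];
          double keep = (std::sqrt(f / (sample * train_words)) + 1.0) *
                        (sample * train_words) / f;
          if (keep < ((next_rand() & 0xFFFF) / 65536.0)) continue;
        }
        sent.push_back(w);
      }
      const int sl = (int)sent.size();
      for (int p = 0; p < sl; ++p) {
        double alpha = alpha0 * (1.0 - processed / (total_work + 1.0));
        if (alpha < alpha0 * 0.0001) alpha = alpha0 * 0.0001;
        processed += 1.0;
        int w = sent[p];
        int red = (int)(next_rand() % (uint64_t)window); // shrink window
        int lo = p - (window - red), hi = p + (window - red);
        if (lo < 0) lo = 0;
        if (hi >= sl) hi = sl - 1;
        for (int c = lo; c <= hi; ++c) {
          if (c == p) continue;
          int ctx = sent[c];
          double *v_in = &syn0[(size_t)ctx * d];
          for (int k = 0; k < d; ++k) neu1e[k] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = w;
              label = 1.0;
            } else {
              target = table[(next_rand() >> 16) % table_size];
              if (target == w) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * d];
            double dot = 0.0;
            for (int k = 0; k < d; ++k) dot += v_in[k] * v_out[k];
            double g = (label - sigmoidd(dot)) * alpha;
            if (g == 0.0) continue; // saturated in the right direction
            for (int k = 0; k < d; ++k) {
              neu1e[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < d; ++k) v_in[k] += neu1e[k];
        }
      }
      pos = end;
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(V, d);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = syn0[(size_t)i * d + k];
  return out;
}
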