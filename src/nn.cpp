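// Pair-classification network: an optional two-layer LSTM over aligned
// character pairs, concatenated with fixed word-embedding features and/or raw
// edit-distance features, followed by H fully connected sigmoid layers and a
// sigmoid output. Trained with mini-batch Adam on cross-entropy. All
// randomness (initialization, shuffling, dropout) comes from one mt19937
// stream seeded by the caller, so runs are reproducible.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double SCORE_EPS = 1e-7;

struct LSTMParams {
  mat Wx1, Wh1, Wx2, Wh2; // Wx1: 4C x (nS+nT); others 4C x C
  vec b1, b2;
  int C = 0, nS = 0, nT = 0;
  bool active = false;
};

struct FFParams {
  std::vector<mat> Wh;
  std::vector<vec> bh;
  rowvec Wo;
  double bo = 0.0;
};

static inline mat sigm(const mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---- parameter plumbing -----------------------------------------------------

static List pack_params(const LSTMParams &lp, const FFParams &fp) {
  List out;
  if (lp.active) {
    out["Wx1"] = lp.Wx1; out["Wh1"] = lp.Wh1; out["b1"] = lp.b1;
    out["Wx2"] = lp.Wx2; out["Wh2"] = lp.Wh2; out["b2"] = lp.b2;
  }
  for (size_t i = 0; i < fp.Wh.size(); ++i) {
    out["Wh_" + std::to_string(i + 1)] = fp.Wh[i];
    out["bh_" + std::to_string(i + 1)] = fp.bh[i];
  }
  out["Wo"] = fp.Wo;
  out["bo"] = fp.bo;
  return out;
}

static void unpack_params(List params, int H, bool use_char, int nS, int nT,
                          LSTMParams &lp, FFParams &fp) {
  if (use_char) {
    lp.Wx1 = as<mat>(params["Wx1"]); lp.Wh1 = as<mat>(params["Wh1"]);
    lp.b1 = as<vec>(params["b1"]);
    lp.Wx2 = as<mat>(params["Wx2"]); lp.Wh2 = as<mat>(params["Wh2"]);
    lp.b2 = as<vec>(params["b2"]);
    lp.C = lp.Wh1.n_cols; lp.nS = nS; lp.nT = nT;
    lp.active = true;
  }
  fp.Wh.clear(); fp.bh.clear();
  for (int i = 0; i < H; ++i) {
    fp.Wh.push_back(as<mat>(params["Wh_" + std::to_string(i + 1)]));
    fp.bh.push_back(as<vec>(params["bh_" + std::to_string(i + 1)]));
  }
  fp.Wo = as<rowvec>(params["Wo"]);
  fp.bo = as<double>(params["bo"]);
}

static mat uinit(int r, int c, std::mt19937 &rng, double s = 0.1) {
  std::uniform_real_distribution<double> U(-s, s);
  mat m(r, c);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) m(i, j) = U(rng);
  return m;
}

static void init_params(LSTMParams &lp, FFParams &fp, bool use_char, int cells,
                        int nS, int nT, int a0_dim, const std::vector<int> &widths,
                        std::mt19937 &rng) {
  if (use_char) {
    lp.C = cells; lp.nS = nS; lp.nT = nT; lp.active = true;
    lp.Wx1 = uinit(4 * cells, nS + nT, rng);
    lp.Wh1 = uinit(4 * cells, cells, rng);
    lp.Wx2 = uinit(4 * cells, cells, rng);
    lp.Wh2 = uinit(4 * cells, cells, rng);
    lp.b1 = arma::zeros<vec>(4 * cells);
    lp.b2 = arma::zeros<vec>(4 * cells);
    // standard positive forget-gate bias so memory persists at init
    lp.b1.subvec(cells, 2 * cells - 1).fill(1.0);
    lp.b2.subvec(cells, 2 * cells - 1).fill(1.0);
  }
  int prev = a0_dim;
  for (size_t i = 0; i < widths.size(); ++i) {
    fp.Wh.push_back(uinit(widths[i], prev, rng));
    fp.bh.push_back(arma::zeros<vec>(widths[i]));
    prev = widths[i];
  }
  fp.Wo = uinit(1, prev, rng);
  fp.bo = 0.0;
}

// ---- LSTM forward / backward ------------------------------------------------

struct LSTMCache {
  std::vector<mat> i1, f1, g1, o1, c1, h1, i2, f2, g2, o2, c2, h2;
  std::vector<int> nb; // active batch prefix size at each timestep
  mat rc;              // C x B: layer-2 output at each sequence's final step
};

// Batch columns must be sorted by decreasing sequence length so that active
// sequences at any timestep form a prefix.
static void lstm_forward(const LSTMParams &lp, const arma::imat &src,
                         const arma::imat &tgt, const std::vector<int> &len,
                         LSTMCache &K) {
  const int B = src.n_cols, C = lp.C;
  const int T = *std::max_element(len.begin(), len.end());
  K.nb.resize(T);
  K.i1.resize(T); K.f1.resize(T); K.g1.resize(T); K.o1.resize(T);
  K.c1.resize(T); K.h1.resize(T);
  K.i2.resize(T); K.f2.resize(T); K.g2.resize(T); K.o2.resize(T);
  K.c2.resize(T); K.h2.resize(T);
  K.rc.zeros(C, B);
  mat h1p = arma::zeros<mat>(C, B), c1p = h1p, h2p = h1p, c2p = h1p;
  for (int t = 0; t < T; ++t) {
    int nb = 0;
    while (nb < B && len[nb] > t) ++nb;
    K.nb[t] = nb;
    // layer 1: one-hot char-pair input gathered as columns of Wx1
    mat pre1 = lp.Wh1 * h1p.cols(0, nb - 1);
    pre1.each_col() += lp.b1;
    for (int b = 0; b < nb; ++b) {
      pre1.col(b) += lp.Wx1.col(src(t, b) - 1);
      pre1.col(b) += lp.Wx1.col(lp.nS + tgt(t, b) - 1);
    }
    mat i1 = sigm(pre1.rows(0, C - 1));
    mat f1 = sigm(pre1.rows(C, 2 * C - 1));
    mat g1 = arma::tanh(pre1.rows(2 * C, 3 * C - 1));
    mat o1 = sigm(pre1.rows(3 * C, 4 * C - 1));
    mat c1 = f1 % c1p.cols(0, nb - 1) + i1 % g1;
    mat h1 = o1 % arma::tanh(c1);
    // layer 2
    mat pre2 = lp.Wx2 * h1 + lp.Wh2 * h2p.cols(0, nb - 1);
    pre2.each_col() += lp.b2;
    mat i2 = sigm(pre2.rows(0, C - 1));
    mat f2 = sigm(pre2.rows(C, 2 * C - 1));
    mat g2 = arma::tanh(pre2.rows(2 * C, 3 * C - 1));
    mat o2 = sigm(pre2.rows(3 * C, 4 * C - 1));
    mat c2 = f2 % c2p.cols(0, nb - 1) + i2 % g2;
    mat h2 = o2 % arma::tanh(c2);
    K.i1[t] = i1; K.f1[t] = f1; K.g1[t] = g1; K.o1[t] = o1;
    K.c1[t] = c1; K.h1[t] = h1;
    K.i2[t] = i2; K.f2[t] = f2; K.g2[t] = g2; K.o2[t] = o2;
    K.c2[t] = c2; K.h2[t] = h2;
    h1p.cols(0, nb - 1) = h1; c1p.cols(0, nb - 1) = c1;
    h2p.cols(0, nb - 1) = h2; c2p.cols(0, nb - 1) = c2;
    for (int b = 0; b < nb; ++b)
      if (len[b] == t + 1) K.rc.col(b) = h2.col(b);
  }
}

struct LSTMGrads {
  mat Wx1, Wh1, Wx2, Wh2;
  vec b1, b2;
  void zeros(const LSTMParams &lp) {
    Wx1.zeros(arma::size(lp.Wx1)); Wh1.zeros(arma::size(lp.Wh1));
    Wx2.zeros(arma::size(lp.Wx2)); Wh2.zeros(arma::size(lp.Wh2));
    b1.zeros(arma::size(lp.b1)); b2.zeros(arma::size(lp.b2));
  }
};

static void lstm_backward(const LSTMParams &lp, const arma::imat &src,
                          const arma::imat &tgt, const std::vector<int> &len,
                          const LSTMCache &K, const mat &d_rc, LSTMGrads &G) {
  const int B = src.n_cols, C = lp.C;
  const int T = (int)K.nb.size();
  mat dh2 = arma::zeros<mat>(C, B), dc2 = dh2, dh1 = dh2, dc1 = dh2;
  for (int t = T - 1; t >= 0; --t) {
    const int nb = K.nb[t];
    // gradient from the final-state output connection enters at each
    // sequence's last step
    for (int b = 0; b < nb; ++b)
      if (len[b] == t + 1) dh2.col(b) = d_rc.col(b);
    mat c2p = (t > 0) ? mat(K.c2[t - 1].cols(0, nb - 1))
                      : arma::zeros<mat>(C, nb);
    mat c1p = (t > 0) ? mat(K.c1[t - 1].cols(0, nb - 1))
                      : arma::zeros<mat>(C, nb);
    mat h2p = (t > 0) ? mat(K.h2[t - 1].cols(0, nb - 1))
                      : arma::zeros<mat>(C, nb);
    mat h1p = (t > 0) ? mat(K.h1[t - 1].cols(0, nb - 1))
                      : arma::zeros<mat>(C, nb);

    // layer 2
    mat th2 = arma::tanh(K.c2[t]);
    mat dh = dh2.cols(0, nb - 1);
    mat dc = dc2.cols(0, nb - 1) + dh % K.o2[t] % (1.0 - th2 % th2);
    mat do_ = dh % th2 % K.o2[t] % (1.0 - K.o2[t]);
    mat di_ = dc % K.g2[t] % K.i2[t] % (1.0 - K.i2[t]);
    mat df_ = dc % c2p % K.f2[t] % (1.0 - K.f2[t]);
    mat dg_ = dc % K.i2[t] % (1.0 - K.g2[t] % K.g2[t]);
    mat D2 = arma::join_cols(di_, df_, dg_, do_);
    G.Wx2 += D2 * K.h1[t].t();
    G.Wh2 += D2 * h2p.t();
    G.b2 += arma::sum(D2, 1);
    dh2.cols(0, nb - 1) = lp.Wh2.t() * D2;
    dc2.cols(0, nb - 1) = dc % K.f2[t];
    mat dh1_t = lp.Wx2.t() * D2; // into layer 1 output

    // layer 1
    mat th1 = arma::tanh(K.c1[t]);
    mat dhl1 = dh1.cols(0, nb - 1) + dh1_t;
    mat dcl1 = dc1.cols(0, nb - 1) + dhl1 % K.o1[t] % (1.0 - th1 % th1);
    mat do1 = dhl1 % th1 % K.o1[t] % (1.0 - K.o1[t]);
    mat di1 = dcl1 % K.g1[t] % K.i1[t] % (1.0 - K.i1[t]);
    mat df1 = dcl1 % c1p % K.f1[t] % (1.0 - K.f1[t]);
    mat dg1 = dcl1 % K.i1[t] % (1.0 - K.g1[t] % K.g1[t]);
    mat D1 = arma::join_cols(di1, df1, dg1, do1);
    G.Wh1 += D1 * h1p.t();
    G.b1 += arma::sum(D1, 1);
    for (int b = 0; b < nb; ++b) {
      G.Wx1.col(src(t, b) - 1) += D1.col(b);
      G.Wx1.col(lp.nS + tgt(t, b) - 1) += D1.col(b);
    }
    dh1.cols(0, nb - 1) = lp.Wh1.t() * D1;
    dc1.cols(0, nb - 1) = dcl1 % K.f1[t];
  }
}

// ---- feed-forward -----------------------------------------------------------

static rowvec ff_forward(const FFParams &fp, const mat &a0,
                         std::vector<mat> &acts) {
  acts.clear();
  acts.push_back(a0);
  for (size_t i = 0; i < fp.Wh.size(); ++i) {
    mat a = fp.Wh[i] * acts.back();
    a.each_col() += fp.bh[i];
    acts.push_back(sigm(a));
  }
  rowvec pre = fp.Wo * acts.back() + fp.bo;
  return 1.0 / (1.0 + arma::exp(-pre));
}

struct FFGrads {
  std::vector<mat> Wh;
  std::vector<vec> bh;
  rowvec Wo;
  double bo;
  void zeros(const FFParams &fp) {
    Wh.clear(); bh.clear();
    for (size_t i = 0; i < fp.Wh.size(); ++i) {
      Wh.push_back(arma::zeros<mat>(arma::size(fp.Wh[i])));
      bh.push_back(arma::zeros<vec>(arma::size(fp.bh[i])));
    }
    Wo = arma::zeros<rowvec>(fp.Wo.n_elem);
    bo = 0.0;
  }
};

// d_pre_out = score - y (cross-entropy + sigmoid), averaged over the batch
static mat ff_backward(const FFParams &fp, const std::vector<mat> &acts,
                       const rowvec &dpre, FFGrads &G) {
  G.Wo += dpre * acts.back().t();
  G.bo += arma::accu(dpre);
  mat da = fp.Wo.t() * dpre;
  for (int i = (int)fp.Wh.size() - 1; i >= 0; --i) {
    mat dz = da % acts[i + 1] % (1.0 - acts[i + 1]);
    G.Wh[i] += dz * acts[i].t();
    G.bh[i] += arma::sum(dz, 1);
    da = fp.Wh[i].t() * dz;
  }
  return da; // gradient w.r.t. a0
}

// ---- Adam -------------------------------------------------------------------

struct AdamState {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void add(const mat &p) {
    m.push_back(arma::zeros<mat>(arma::size(p)));
    v.push_back(arma::zeros<mat>(arma::size(p)));
  }
  void step(mat &p, const mat &g, size_t k, double lr) {
    m[k] = b1 * m[k] + (1 - b1) * g;
    v[k] = b2 * v[k] + (1 - b2) * (g % g);
    double bc1 = 1 - std::pow(b1, (double)t), bc2 = 1 - std::pow(b2, (double)t);
    p -= lr * (m[k] / bc1) / (arma::sqrt(v[k] / bc2) + eps);
  }
};

// ---- batch assembly ---------------------------------------------------------

struct Batch {
  mat feat;            // (wdim+edim) x nb fixed features
  arma::imat src, tgt; // T x nb char indices (1-based), 0 beyond length
  std::vector<int> len;
  vec y;
  std::vector<int> orig; // original example indices (for score scatter)
};

static Batch make_batch(const std::vector<int> &ids, const mat &fixed,
                        const IntegerMatrix &src, const IntegerMatrix &tgt,
                        const IntegerVector &len, const vec &labels,
                        bool use_char) {
  Batch B;
  std::vector<int> ord(ids);
  if (use_char) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return len[a] > len[b]; });
  }
  const int nb = (int)ord.size();
  if (fixed.n_rows > 0) {
    B.feat.set_size(fixed.n_rows, nb);
    for (int b = 0; b < nb; ++b) B.feat.col(b) = fixed.col(ord[b]);
  }
  if (use_char) {
    int T = 0;
    for (int b = 0; b < nb; ++b) T = std::max(T, (int)len[ord[b]]);
    B.src.set_size(T, nb); B.tgt.set_size(T, nb);
    B.len.resize(nb);
    for (int b = 0; b < nb; ++b) {
      B.len[b] = len[ord[b]];
      for (int t = 0; t < T; ++t) {
        B.src(t, b) = (t < B.len[b]) ? src(t, ord[b]) : 0;
        B.tgt(t, b) = (t < B.len[b]) ? tgt(t, ord[b]) : 0;
      }
    }
  }
  B.y.set_size(nb);
  for (int b = 0; b < nb; ++b) B.y[b] = labels[ord[b]];
  B.orig = ord;
  return B;
}

// ---- exported entry points --------------------------------------------------

// fixed_feats: (wdim+edim) x n matrix of non-char features (may be 0 x n).
// char_src/char_tgt: Mmax x n 1-based index matrices; seq_len: per-example
// padded pair length (0 x 0 matrices and empty seq_len when chars unused).
// [[Rcpp::export]]
List cpp_nn_train(arma::mat fixed_feats, IntegerMatrix char_src,
                  IntegerMatrix char_tgt, IntegerVector seq_len,
                  arma::vec labels, int n_src_chars, int n_tgt_chars,
                  int cells, IntegerVector hidden_widths, double keep_prob,
                  int batch_size, int epochs, double lr, int seed) {
  const int n = labels.n_elem;
  const bool use_char = seq_len.size() > 0;
  const int H = hidden_widths.size();
  std::mt19937 rng((unsigned)seed);

  int a0_dim = fixed_feats.n_rows + (use_char ? cells : 0);
  std::vector<int> widths(hidden_widths.begin(), hidden_widths.end());
  LSTMParams lp; FFParams fp;
  init_params(lp, fp, use_char, cells, n_src_chars, n_tgt_chars, a0_dim,
              widths, rng);

  // Adam over the flattened parameter list
  AdamState adam;
  std::vector<mat *> plist;
  if (use_char) {
    plist = {&lp.Wx1, &lp.Wh1, &lp.Wx2, &lp.Wh2};
  }
  std::vector<vec *> pvecs;
  if (use_char) pvecs = {&lp.b1, &lp.b2};
  for (size_t i = 0; i < fp.Wh.size(); ++i) plist.push_back(&fp.Wh[i]);
  for (size_t i = 0; i < fp.bh.size(); ++i) pvecs.push_back(&fp.bh[i]);
  for (auto *p : plist) adam.add(*p);
  for (auto *p : pvecs) adam.add(mat(*p));
  adam.add(mat(fp.Wo));
  adam.add(mat(1, 1));

  std::vector<double> epoch_loss;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double loss_sum = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int stop_ = std::min(n, start + batch_size);
      std::vector<int> ids(perm.begin() + start, perm.begin() + stop_);
      Batch B = make_batch(ids, fixed_feats, char_src, char_tgt, seq_len,
                           labels, use_char);
      const int nb = (int)ids.size();

      LSTMCache K;
      mat drop_mask;
      mat a0;
      if (use_char) {
        lstm_forward(lp, B.src, B.tgt, B.len, K);
        drop_mask.set_size(cells, nb);
        for (arma::uword j = 0; j < drop_mask.n_cols; ++j)
          for (arma::uword i = 0; i < drop_mask.n_rows; ++i)
            drop_mask(i, j) = (U01(rng) < keep_prob) ? 1.0 / keep_prob : 0.0;
        mat rc_drop = K.rc % drop_mask;
        a0 = (B.feat.n_rows > 0) ? arma::join_cols(B.feat, rc_drop) : rc_drop;
      } else {
        a0 = B.feat;
      }

      std::vector<mat> acts;
      rowvec score = ff_forward(fp, a0, acts);
      rowvec sc = arma::clamp(score, SCORE_EPS, 1.0 - SCORE_EPS);
      for (int b = 0; b < nb; ++b)
        loss_sum += -B.y[b] * std::log(sc[b]) -
                    (1.0 - B.y[b]) * std::log(1.0 - sc[b]);

      rowvec dpre = (score - B.y.t()) / (double)nb;
      FFGrads fg; fg.zeros(fp);
      mat da0 = ff_backward(fp, acts, dpre, fg);

      LSTMGrads lg;
      if (use_char) {
        lg.zeros(lp);
        mat d_rc = da0.rows(a0.n_rows - cells, a0.n_rows - 1) % drop_mask;
        lstm_backward(lp, B.src, B.tgt, B.len, K, d_rc, lg);
      }

      // Adam step
      adam.t += 1;
      size_t k = 0;
      if (use_char) {
        adam.step(lp.Wx1, lg.Wx1, k++, lr);
        adam.step(lp.Wh1, lg.Wh1, k++, lr);
        adam.step(lp.Wx2, lg.Wx2, k++, lr);
        adam.step(lp.Wh2, lg.Wh2, k++, lr);
      }
      for (size_t i = 0; i < fp.Wh.size(); ++i) adam.step(fp.Wh[i], fg.Wh[i], k++, lr);
      if (use_char) {
        mat b1m(lp.b1), g1m(lg.b1);
        adam.step(b1m, g1m, k++, lr); lp.b1 = b1m.col(0);
        mat b2m(lp.b2), g2m(lg.b2);
        adam.step(b2m, g2m, k++, lr); lp.b2 = b2m.col(0);
      }
      for (size_t i = 0; i < fp.bh.size(); ++i) {
        mat bm(fp.bh[i]), gm(fg.bh[i]);
        adam.step(bm, gm, k++, lr); fp.bh[i] = bm.col(0);
      }
      mat wo(fp.Wo), gwo(fg.Wo);
      adam.step(wo, gwo, k++, lr); fp.Wo = wo.row(0);
      mat bo(1, 1); bo(0, 0) = fp.bo;
      mat gbo(1, 1); gbo(0, 0) = fg.bo;
      adam.step(bo, gbo, k++, lr); fp.bo = bo(0, 0);

      if (!std::isfinite(loss_sum))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
    }
    epoch_loss.push_back(loss_sum / n);
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["params"] = pack_params(lp, fp),
                      _["epoch_loss"] = wrap(epoch_loss));
}

// [[Rcpp::export]]
arma::vec cpp_nn_predict(List params, arma::mat fixed_feats,
                         IntegerMatrix char_src, IntegerMatrix char_tgt,
                         IntegerVector seq_len, int n_src_chars,
                         int n_tgt_chars, int n_hidden_layers) {
  const bool use_char = seq_len.size() > 0;
  LSTMParams lp; FFParams fp;
  unpack_params(params, n_hidden_layers, use_char, n_src_chars, n_tgt_chars,
                lp, fp);
  const int n = use_char ? seq_len.size() : fixed_feats.n_cols;
  vec out(n);
  vec dummy_y = arma::zeros<vec>(n);
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  // predict in chunks to bound memory
  const int chunk = 256;
  for (int start = 0; start < n; start += chunk) {
    int stop_ = std::min(n, start + chunk);
    std::vector<int> sub(ids.begin() + start, ids.begin() + stop_);
    Batch B = make_batch(sub, fixed_feats, char_src, char_tgt, seq_len,
                         dummy_y, use_char);
    mat a0;
    if (use_char) {
      LSTMCache K;
      lstm_forward(lp, B.src, B.tgt, B.len, K);
      a0 = (B.feat.n_rows > 0) ? arma::join_cols(B.feat, K.rc) : K.rc;
    } else {
      a0 = B.feat;
    }
    std::vector<mat> acts;
    rowvec score = ff_forward(fp, a0, acts);
    for (size_t b = 0; b < B.orig.size(); ++b) out[B.orig[b]] = score[b];
  }
  return out;
}

// Character-pair representation r_c (layer-2 LSTM output at the final
// position), evaluation mode (no dropout).
// [[Rcpp::export]]
arma::mat cpp_nn_char_repr(List params, IntegerMatrix char_src,
                           IntegerMatrix char_tgt, IntegerVector seq_len,
                           int n_src_chars, int n_tgt_chars) {
  LSTMParams lp; FFParams fp;
  // FF part unused; request 0 hidden layers but Wo/bo must exist in params
  unpack_params(params, 0, true, n_src_chars, n_tgt_chars, lp, fp);
  const int n = seq_len.size();
  vec dummy_y = arma::zeros<vec>(n);
  mat fixed(0, n);
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  Batch B = make_batch(ids, fixed, char_src, char_tgt, seq_len, dummy_y, true);
  LSTMCache K;
  lstm_forward(lp, B.src, B.tgt, B.len, K);
  mat out(lp.C, n);
  for (size_t b = 0; b < B.orig.size(); ++b) out.col(B.orig[b]) = K.rc.col(b);
  return out;
}
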