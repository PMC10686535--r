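// Recurrent sequence models used by the entity and relation extractors:
// a linear-chain CRF (forward-backward, Viterbi), a single-layer
// bidirectional LSTM with hand-derived backpropagation-through-time, and
// an attention pooling head for binary sequence classification.
//
// All parameters are passed as plain matrices from R (column vectors as
// n x 1, row vectors as 1 x n) so the R-side SGD loop can treat every
// parameter uniformly. Token ids are 1-based; 0 marks "no token".
// Dropout uses R's RNG (unif_rand) so set.seed() on the R side makes
// training runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logsumexp_vec(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(x - m)));
}

// ---------------------------------------------------------------------------
// Linear-chain CRF
// ---------------------------------------------------------------------------

// Forward recursion in log space; fills alpha (L x K), returns log Z.
static double crf_forward_alpha(const mat& em, const mat& tr,
                                const vec& start, const vec& stop,
                                mat& alpha) {
  const int L = em.n_rows, K = em.n_cols;
  alpha.set_size(L, K);
  alpha.row(0) = start.t() + em.row(0);
  for (int t = 1; t < L; ++t) {
    for (int j = 0; j < K; ++j) {
      vec s = alpha.row(t - 1).t() + tr.col(j);
      alpha(t, j) = logsumexp_vec(s) + em(t, j);
    }
  }
  vec fin = alpha.row(L - 1).t() + stop;
  return logsumexp_vec(fin);
}

// Negative log-likelihood of the gold path; optionally accumulates
// gradients (d_em is per-sentence and overwritten; d_tr/d_start/d_stop are
// accumulated so batches can share them).
static double crf_nll(const mat& em, const mat& tr,
                      const vec& start, const vec& stop,
                      const arma::ivec& tags, bool want_grad,
                      mat& d_em, mat& d_tr, vec& d_start, vec& d_stop) {
  const int L = em.n_rows, K = em.n_cols;
  mat alpha;
  double logZ = crf_forward_alpha(em, tr, start, stop, alpha);
  double gold = start(tags(0) - 1) + em(0, tags(0) - 1);
  for (int t = 1; t < L; ++t)
    gold += tr(tags(t - 1) - 1, tags(t) - 1) + em(t, tags(t) - 1);
  gold += stop(tags(L - 1) - 1);
  double nll = logZ - gold;
  if (!want_grad) return nll;

  mat beta(L, K);
  beta.row(L - 1) = stop.t();
  for (int t = L - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      vec s = tr.row(i).t() + em.row(t + 1).t() + beta.row(t + 1).t();
      beta(t, i) = logsumexp_vec(s);
    }
  }
  // unary marginals P(y_t = j)
  mat marg = arma::exp(alpha + beta - logZ);
  d_em = marg;
  for (int t = 0; t < L; ++t) d_em(t, tags(t) - 1) -= 1.0;
  d_start += marg.row(0).t();
  d_start(tags(0) - 1) -= 1.0;
  d_stop += marg.row(L - 1).t();
  d_stop(tags(L - 1) - 1) -= 1.0;
  // pairwise marginals P(y_t = i, y_{t+1} = j)
  for (int t = 0; t + 1 < L; ++t) {
    mat P = arma::exp(arma::repmat(alpha.row(t).t(), 1, K) + tr +
                      arma::repmat(em.row(t + 1) + beta.row(t + 1), K, 1) -
                      logZ);
    d_tr += P;
    d_tr(tags(t) - 1, tags(t + 1) - 1) -= 1.0;
  }
  return nll;
}

// Highest-scoring path; ties broken toward the lowest tag index.
static arma::ivec viterbi_path(const mat& em, const mat& tr,
                               const vec& start, const vec& stop) {
  const int L = em.n_rows, K = em.n_cols;
  arma::ivec path(L);
  if (L == 0) return path;
  mat delta(L, K);
  arma::imat psi(L, K, arma::fill::zeros);
  delta.row(0) = start.t() + em.row(0);
  for (int t = 1; t < L; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = NEG_INF;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double s = delta(t - 1, i) + tr(i, j);
        if (s > best) { best = s; arg = i; }
      }
      delta(t, j) = best + em(t, j);
      psi(t, j) = arg;
    }
  }
  int arg = 0;
  double best = NEG_INF;
  for (int j = 0; j < K; ++j) {
    double s = delta(L - 1, j) + stop(j);
    if (s > best) { best = s; arg = j; }
  }
  path(L - 1) = arg + 1;
  for (int t = L - 1; t > 0; --t) {
    arg = psi(t, arg);
    path(t - 1) = arg + 1;
  }
  return path;
}

// [[Rcpp::export]]
List cpp_crf_nll(const arma::mat& emissions, const arma::mat& trans,
                 const arma::vec& start, const arma::vec& stop,
                 const arma::ivec& tags, bool grad = false) {
  const int K = emissions.n_cols;
  mat d_em, d_tr(K, K, arma::fill::zeros);
  vec d_start(K, arma::fill::zeros), d_stop(K, arma::fill::zeros);
  double nll = crf_nll(emissions, trans, start, stop, tags, grad,
                       d_em, d_tr, d_start, d_stop);
  if (!grad) return List::create(Named("nll") = nll);
  return List::create(Named("nll") = nll, Named("d_emissions") = d_em,
                      Named("d_trans") = d_tr, Named("d_start") = d_start,
                      Named("d_stop") = d_stop);
}

// [[Rcpp::export]]
IntegerVector cpp_viterbi(const arma::mat& emissions, const arma::mat& trans,
                          const arma::vec& start, const arma::vec& stop) {
  arma::ivec p = viterbi_path(emissions, trans, start, stop);
  return wrap(p);
}

// [[Rcpp::export]]
double cpp_crf_logz(const arma::mat& emissions, const arma::mat& trans,
                    const arma::vec& start, const arma::vec& stop) {
  mat alpha;
  return crf_forward_alpha(emissions, trans, start, stop, alpha);
}

// ---------------------------------------------------------------------------
// Single-direction LSTM over one sequence
// ---------------------------------------------------------------------------

struct SeqCache {
  mat Xe;               // T x d, embedded input after dropout
  mat mask;             // T x d inverted-dropout factors (empty if unused)
  mat I, F, G, O, C, Th; // T x H gate activations, cell, tanh(cell)
  mat Hs;               // (T+1) x H hidden states, row 0 is the zero state
  uvec ids;             // 1-based token ids
};

static void lstm_seq_forward(const mat& E, const mat& Wx, const mat& Wh,
                             const rowvec& b, const uvec& ids,
                             double p_in, bool training, SeqCache& sc) {
  const int T = ids.n_elem, d = E.n_cols, H = Wh.n_rows;
  sc.ids = ids;
  sc.Xe.set_size(T, d);
  for (int t = 0; t < T; ++t) {
    if (ids(t) > 0) sc.Xe.row(t) = E.row(ids(t) - 1);
    else sc.Xe.row(t).zeros();
  }
  if (training && p_in > 0) {
    const double keep = 1.0 - p_in;
    sc.mask.set_size(T, d);
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < d; ++k)
        sc.mask(t, k) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    sc.Xe %= sc.mask;
  } else {
    sc.mask.reset();
  }
  mat A = sc.Xe * Wx;
  A.each_row() += b;
  sc.I.set_size(T, H); sc.F.set_size(T, H); sc.G.set_size(T, H);
  sc.O.set_size(T, H); sc.C.set_size(T, H); sc.Th.set_size(T, H);
  sc.Hs.set_size(T + 1, H);
  sc.Hs.row(0).zeros();
  rowvec c_prev(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    rowvec a = A.row(t) + sc.Hs.row(t) * Wh;
    rowvec i = 1.0 / (1.0 + arma::exp(-a.cols(0, H - 1)));
    rowvec f = 1.0 / (1.0 + arma::exp(-a.cols(H, 2 * H - 1)));
    rowvec g = arma::tanh(a.cols(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + arma::exp(-a.cols(3 * H, 4 * H - 1)));
    rowvec c = f % c_prev + i % g;
    rowvec th = arma::tanh(c);
    sc.I.row(t) = i; sc.F.row(t) = f; sc.G.row(t) = g; sc.O.row(t) = o;
    sc.C.row(t) = c; sc.Th.row(t) = th;
    sc.Hs.row(t + 1) = o % th;
    c_prev = c;
  }
}

// BPTT. dH is T x H (loss gradient at each hidden output). Accumulates
// parameter gradients; returns the gradient at the embedded input
// (dropout mask already applied).
static mat lstm_seq_backward(const mat& Wx, const mat& Wh, const mat& dH,
                             const SeqCache& sc, mat& dWx, mat& dWh,
                             rowvec& db) {
  const int T = dH.n_rows, H = Wh.n_rows;
  mat dA(T, 4 * H);
  rowvec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    rowvec dh = dH.row(t) + dh_next;
    rowvec I = sc.I.row(t), F = sc.F.row(t), G = sc.G.row(t),
           O = sc.O.row(t), Th = sc.Th.row(t);
    rowvec do_ = dh % Th;
    rowvec dao = do_ % O % (1.0 - O);
    rowvec dc = dh % O % (1.0 - Th % Th) + dc_next;
    rowvec dai = dc % G % I % (1.0 - I);
    rowvec dag = dc % I % (1.0 - G % G);
    rowvec cprev = (t > 0) ? rowvec(sc.C.row(t - 1))
                           : rowvec(H, arma::fill::zeros);
    rowvec daf = dc % cprev % F % (1.0 - F);
    dA(t, arma::span(0, H - 1)) = dai;
    dA(t, arma::span(H, 2 * H - 1)) = daf;
    dA(t, arma::span(2 * H, 3 * H - 1)) = dag;
    dA(t, arma::span(3 * H, 4 * H - 1)) = dao;
    dc_next = dc % F;
    dh_next = dA.row(t) * Wh.t();
  }
  dWx += sc.Xe.t() * dA;
  dWh += sc.Hs.rows(0, T - 1).t() * dA;
  db += arma::sum(dA, 0);
  mat dXe = dA * Wx.t();
  if (sc.mask.n_elem) dXe %= sc.mask;
  return dXe;
}

static void accum_embedding_grad(mat& dE, const SeqCache& sc, const mat& dXe) {
  for (arma::uword t = 0; t < sc.ids.n_elem; ++t)
    if (sc.ids(t) > 0) dE.row(sc.ids(t) - 1) += dXe.row(t);
}

// Bidirectional encoding of one sequence: returns T x 2H [forward; backward]
// hidden states. The backward direction is run on the reversed sequence.
static mat bilstm_seq_forward(const mat& E, const mat& Wx_f, const mat& Wh_f,
                              const rowvec& b_f, const mat& Wx_b,
                              const mat& Wh_b, const rowvec& b_b,
                              const uvec& ids, double p_in, bool training,
                              SeqCache& cf, SeqCache& cb) {
  const int T = ids.n_elem, H = Wh_f.n_rows;
  lstm_seq_forward(E, Wx_f, Wh_f, b_f, ids, p_in, training, cf);
  uvec ids_r = arma::reverse(ids);
  lstm_seq_forward(E, Wx_b, Wh_b, b_b, ids_r, p_in, training, cb);
  mat Hcat(T, 2 * H);
  Hcat.cols(0, H - 1) = cf.Hs.rows(1, T);
  Hcat.cols(H, 2 * H - 1) = arma::flipud(cb.Hs.rows(1, T));
  return Hcat;
}

struct BiGrads {
  mat dE, dWx_f, dWh_f, dWx_b, dWh_b;
  rowvec db_f, db_b;
  void init(int V, int d, int H) {
    dE.zeros(V, d);
    dWx_f.zeros(d, 4 * H); dWh_f.zeros(H, 4 * H); db_f.zeros(4 * H);
    dWx_b.zeros(d, 4 * H); dWh_b.zeros(H, 4 * H); db_b.zeros(4 * H);
  }
};

static void bilstm_seq_backward(const mat& Wx_f, const mat& Wh_f,
                                const mat& Wx_b, const mat& Wh_b,
                                const mat& dHcat, SeqCache& cf, SeqCache& cb,
                                BiGrads& g) {
  const int H = Wh_f.n_rows;
  mat dHf = dHcat.cols(0, H - 1);
  mat dHb = arma::flipud(dHcat.cols(H, 2 * H - 1));
  mat dXf = lstm_seq_backward(Wx_f, Wh_f, dHf, cf, g.dWx_f, g.dWh_f, g.db_f);
  accum_embedding_grad(g.dE, cf, dXf);
  mat dXb = lstm_seq_backward(Wx_b, Wh_b, dHb, cb, g.dWx_b, g.dWh_b, g.db_b);
  accum_embedding_grad(g.dE, cb, dXb);
}

// ---------------------------------------------------------------------------
// NER model: BiLSTM emissions + CRF
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ner_batch(const List& params, const List& seqs, const List& tags,
                   double p_in, double p_out, bool training) {
  const mat E = as<mat>(params["E"]);
  const mat Wx_f = as<mat>(params["Wx_f"]), Wh_f = as<mat>(params["Wh_f"]);
  const mat Wx_b = as<mat>(params["Wx_b"]), Wh_b = as<mat>(params["Wh_b"]);
  const rowvec b_f = as<mat>(params["b_f"]).row(0);
  const rowvec b_b = as<mat>(params["b_b"]).row(0);
  const mat Wout = as<mat>(params["Wout"]);
  const rowvec bout = as<mat>(params["bout"]).row(0);
  const mat trans = as<mat>(params["trans"]);
  const vec start = as<mat>(params["start"]).col(0);
  const vec stop = as<mat>(params["stop"]).col(0);
  const int V = E.n_rows, d = E.n_cols, H = Wh_f.n_rows, K = trans.n_rows;

  BiGrads g;
  g.init(V, d, H);
  mat dWout(2 * H, K, arma::fill::zeros), dTrans(K, K, arma::fill::zeros);
  rowvec dbout(K, arma::fill::zeros);
  vec dStart(K, arma::fill::zeros), dStop(K, arma::fill::zeros);

  double loss = 0.0;
  int n = 0;
  const int S = seqs.size();
  for (int s = 0; s < S; ++s) {
    uvec ids = as<uvec>(seqs[s]);
    const int T = ids.n_elem;
    if (T == 0) continue;
    arma::ivec tg = as<arma::ivec>(tags[s]);
    SeqCache cf, cb;
    mat Hcat = bilstm_seq_forward(E, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b,
                                  ids, p_in, training, cf, cb);
    mat Mout;
    if (training && p_out > 0) {
      const double keep = 1.0 - p_out;
      Mout.set_size(T, 2 * H);
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < 2 * H; ++k)
          Mout(t, k) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      Hcat %= Mout;
    }
    mat Em = Hcat * Wout;
    Em.each_row() += bout;
    mat d_em;
    loss += crf_nll(Em, trans, start, stop, tg, true,
                    d_em, dTrans, dStart, dStop);
    n += 1;
    dWout += Hcat.t() * d_em;
    dbout += arma::sum(d_em, 0);
    mat dHcat = d_em * Wout.t();
    if (Mout.n_elem) dHcat %= Mout;
    bilstm_seq_backward(Wx_f, Wh_f, Wx_b, Wh_b, dHcat, cf, cb, g);
  }
  List grads = List::create(
      Named("E") = g.dE, Named("Wx_f") = g.dWx_f, Named("Wh_f") = g.dWh_f,
      Named("b_f") = mat(g.db_f), Named("Wx_b") = g.dWx_b,
      Named("Wh_b") = g.dWh_b, Named("b_b") = mat(g.db_b),
      Named("Wout") = dWout, Named("bout") = mat(dbout),
      Named("trans") = dTrans, Named("start") = mat(dStart),
      Named("stop") = mat(dStop));
  return List::create(Named("loss") = loss, Named("n") = n,
                      Named("grads") = grads);
}

// [[Rcpp::export]]
List cpp_ner_predict(const List& params, const List& seqs) {
  const mat E = as<mat>(params["E"]);
  const mat Wx_f = as<mat>(params["Wx_f"]), Wh_f = as<mat>(params["Wh_f"]);
  const mat Wx_b = as<mat>(params["Wx_b"]), Wh_b = as<mat>(params["Wh_b"]);
  const rowvec b_f = as<mat>(params["b_f"]).row(0);
  const rowvec b_b = as<mat>(params["b_b"]).row(0);
  const mat Wout = as<mat>(params["Wout"]);
  const rowvec bout = as<mat>(params["bout"]).row(0);
  const mat trans = as<mat>(params["trans"]);
  const vec start = as<mat>(params["start"]).col(0);
  const vec stop = as<mat>(params["stop"]).col(0);

  const int S = seqs.size();
  List out(S);
  for (int s = 0; s < S; ++s) {
    uvec ids = as<uvec>(seqs[s]);
    if (ids.n_elem == 0) { out[s] = IntegerVector(0); continue; }
    SeqCache cf, cb;
    mat Hcat = bilstm_seq_forward(E, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b,
                                  ids, 0.0, false, cf, cb);
    mat Em = Hcat * Wout;
    Em.each_row() += bout;
    out[s] = wrap(viterbi_path(Em, trans, start, stop));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Relation model: BiLSTM + attention pooling + logistic output
// ---------------------------------------------------------------------------

static inline double softplus(double z) {
  return (z > 0) ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

// [[Rcpp::export]]
List cpp_rel_batch(const List& params, const List& seqs,
                   const NumericVector& labels, double p_in, bool training) {
  const mat E = as<mat>(params["E"]);
  const mat Wx_f = as<mat>(params["Wx_f"]), Wh_f = as<mat>(params["Wh_f"]);
  const mat Wx_b = as<mat>(params["Wx_b"]), Wh_b = as<mat>(params["Wh_b"]);
  const rowvec b_f = as<mat>(params["b_f"]).row(0);
  const rowvec b_b = as<mat>(params["b_b"]).row(0);
  const vec v = as<mat>(params["v"]).col(0);
  const vec w = as<mat>(params["w"]).col(0);
  const double bo = as<mat>(params["b"])(0, 0);
  const int V = E.n_rows, d = E.n_cols, H = Wh_f.n_rows;

  BiGrads g;
  g.init(V, d, H);
  vec dv(2 * H, arma::fill::zeros), dw(2 * H, arma::fill::zeros);
  double dbo = 0.0, loss = 0.0;
  int n = 0;
  const int S = seqs.size();
  for (int s = 0; s < S; ++s) {
    uvec ids = as<uvec>(seqs[s]);
    const int T = ids.n_elem;
    if (T == 0) continue;
    const double y = labels[s];
    SeqCache cf, cb;
    mat Hcat = bilstm_seq_forward(E, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b,
                                  ids, p_in, training, cf, cb);
    mat U = arma::tanh(Hcat);           // T x 2H
    vec e = U * v;                      // T
    e -= e.max();
    vec a = arma::exp(e);
    a /= arma::accu(a);                 // attention weights
    vec ctx = Hcat.t() * a;             // 2H
    double z = arma::dot(ctx, w) + bo;
    loss += softplus(z) - y * z;
    n += 1;
    double dz = 1.0 / (1.0 + std::exp(-z)) - y;
    dw += dz * ctx;
    dbo += dz;
    vec dctx = dz * w;
    vec da = Hcat * dctx;               // T
    mat dHcat = a * dctx.t();           // T x 2H
    vec de = a % (da - arma::dot(a, da));
    dv += U.t() * de;
    dHcat += (de * v.t()) % (1.0 - U % U);
    bilstm_seq_backward(Wx_f, Wh_f, Wx_b, Wh_b, dHcat, cf, cb, g);
  }
  List grads = List::create(
      Named("E") = g.dE, Named("Wx_f") = g.dWx_f, Named("Wh_f") = g.dWh_f,
      Named("b_f") = mat(g.db_f), Named("Wx_b") = g.dWx_b,
      Named("Wh_b") = g.dWh_b, Named("b_b") = mat(g.db_b),
      Named("v") = mat(dv), Named("w") = mat(dw),
      Named("b") = mat(1, 1, arma::fill::value(dbo)));
  return List::create(Named("loss") = loss, Named("n") = n,
                      Named("grads") = grads);
}

// [[Rcpp::export]]
List cpp_rel_predict(const List& params, const List& seqs,
                     bool want_attention = false) {
  const mat E = as<mat>(params["E"]);
  const mat Wx_f = as<mat>(params["Wx_f"]), Wh_f = as<mat>(params["Wh_f"]);
  const mat Wx_b = as<mat>(params["Wx_b"]), Wh_b = as<mat>(params["Wh_b"]);
  const rowvec b_f = as<mat>(params["b_f"]).row(0);
  const rowvec b_b = as<mat>(params["b_b"]).row(0);
  const vec v = as<mat>(params["v"]).col(0);
  const vec w = as<mat>(params["w"]).col(0);
  const double bo = as<mat>(params["b"])(0, 0);

  const int S = seqs.size();
  NumericVector probs(S);
  List attn(S);
  for (int s = 0; s < S; ++s) {
    uvec ids = as<uvec>(seqs[s]);
    if (ids.n_elem == 0) { probs[s] = 0.0; continue; }
    SeqCache cf, cb;
    mat Hcat = bilstm_seq_forward(E, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b,
                                  ids, 0.0, false, cf, cb);
    mat U = arma::tanh(Hcat);
    vec e = U * v;
    e -= e.max();
    vec a = arma::exp(e);
    a /= arma::accu(a);
    vec ctx = Hcat.t() * a;
    double z = arma::dot(ctx, w) + bo;
    probs[s] = 1.0 / (1.0 + std::exp(-z));
    if (want_attention) attn[s] = wrap(a);
  }
  if (want_attention)
    return List::create(Named("prob") = probs, Named("attention") = attn);
  return List::create(Named("prob") = probs);
}
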