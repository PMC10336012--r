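// Small transformer encoder trained as a masked language model, with
// manual backpropagation and Adam.  Post-layer-norm architecture: learned
// token + position embeddings; per layer multi-head self-attention and a
// ReLU feed-forward block, each with a residual connection followed by
// layer norm; the output head ties the token embedding (logits = h E^T +
// b).  Sequences are processed at their true length (no padding), one at
// a time, with gradients accumulated per batch and one Adam step per
// batch.  All randomness (init, shuffling, masking) lives on the R side,
// so results are bit-reproducible for a given seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct Param {
  mat w, g, m, v;  // weight, gradient, Adam first/second moments
  void init(int r, int c) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct Layer {
  Param Wq, Wk, Wv, Wo, bq, bk, bv, bo;
  Param W1, b1, W2, b2;
  Param g1, be1, g2, be2;  // layer-norm scale/shift
};

struct Model {
  int V, D, H, L, F, maxlen;
  Param E;     // V x D token embedding (tied with the output head)
  Param P;     // maxlen x D position embedding
  Param bout;  // 1 x V output bias
  std::vector<Layer> layers;
  long step;

  void collect(std::vector<Param *> &ps) {
    ps.push_back(&E); ps.push_back(&P); ps.push_back(&bout);
    for (int l = 0; l < L; ++l) {
      Layer &ly = layers[l];
      Param *arr[] = {&ly.Wq, &ly.Wk, &ly.Wv, &ly.Wo, &ly.bq, &ly.bk,
                      &ly.bv, &ly.bo, &ly.W1, &ly.b1, &ly.W2, &ly.b2,
                      &ly.g1, &ly.be1, &ly.g2, &ly.be2};
      for (int i = 0; i < 16; ++i) ps.push_back(arr[i]);
    }
  }
};

static Model *get_model(SEXP ptr) {
  XPtr<Model> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP tf_new(int vocab, int d_model, int n_heads, int n_layers, int d_ff,
            int max_len) {
  if (d_model % n_heads != 0) stop("d_model must be divisible by n_heads");
  Model *m = new Model();
  m->V = vocab; m->D = d_model; m->H = n_heads; m->L = n_layers;
  m->F = d_ff; m->maxlen = max_len; m->step = 0;
  m->E.init(vocab, d_model);
  m->P.init(max_len, d_model);
  m->bout.init(1, vocab);
  m->layers.resize(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    Layer &ly = m->layers[l];
    ly.Wq.init(d_model, d_model); ly.Wk.init(d_model, d_model);
    ly.Wv.init(d_model, d_model); ly.Wo.init(d_model, d_model);
    ly.bq.init(1, d_model); ly.bk.init(1, d_model);
    ly.bv.init(1, d_model); ly.bo.init(1, d_model);
    ly.W1.init(d_model, d_ff); ly.b1.init(1, d_ff);
    ly.W2.init(d_ff, d_model); ly.b2.init(1, d_model);
    ly.g1.init(1, d_model); ly.g1.w.ones();
    ly.be1.init(1, d_model);
    ly.g2.init(1, d_model); ly.g2.w.ones();
    ly.be2.init(1, d_model);
  }
  XPtr<Model> ptr(m, true);
  return ptr;
}

// [[Rcpp::export]]
List tf_get_weights(SEXP ptr) {
  Model *m = get_model(ptr);
  std::vector<Param *> ps;
  m->collect(ps);
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) out[i] = wrap(ps[i]->w);
  out.attr("step") = (double)m->step;
  return out;
}

// [[Rcpp::export]]
void tf_set_weights(SEXP ptr, List ws) {
  Model *m = get_model(ptr);
  std::vector<Param *> ps;
  m->collect(ps);
  if ((size_t)ws.size() != ps.size()) stop("weight list length mismatch");
  for (size_t i = 0; i < ps.size(); ++i) {
    mat w = as<mat>(ws[i]);
    if (w.n_rows != ps[i]->w.n_rows || w.n_cols != ps[i]->w.n_cols)
      stop("weight shape mismatch at slot %d", (int)i + 1);
    ps[i]->w = w;
  }
  if (ws.hasAttribute("step")) m->step = (long)as<double>(ws.attr("step"));
}

// [[Rcpp::export]]
List tf_dims(SEXP ptr) {
  Model *m = get_model(ptr);
  return List::create(_["vocab"] = m->V, _["d_model"] = m->D,
                      _["n_heads"] = m->H, _["n_layers"] = m->L,
                      _["d_ff"] = m->F, _["max_len"] = m->maxlen);
}

struct LayerCache {
  mat x_in;
  std::vector<mat> A;  // per-head T x T attention
  mat Q, K, Vm;
  mat ctx;
  mat xhat1;           // LN1 normalized input
  vec iv1c;            // LN1 per-row 1/sd
  mat h;               // T x F ReLU activations
  mat xhat2;
  vec iv2c;
};

struct FwdCache {
  std::vector<LayerCache> lc;
  mat xout;  // T x D final hidden states
};

static void layer_norm_fwd(const mat &x, const Param &g, const Param &b,
                           mat &xhat, vec &ivc, mat &y) {
  vec mu = arma::mean(x, 1);
  vec va = arma::var(x, 1, 1);  // population variance per row
  ivc = 1.0 / arma::sqrt(va + LN_EPS);
  xhat = x.each_col() - mu;
  xhat.each_col() %= ivc;
  y = xhat.each_row() % g.w;
  y.each_row() += b.w;
}

// dy -> dx; accumulates dg, db.
static mat layer_norm_bwd(const mat &dy, const mat &xhat, const vec &ivc,
                          Param &g, Param &b) {
  int D = dy.n_cols;
  g.g += arma::sum(dy % xhat, 0);
  b.g += arma::sum(dy, 0);
  mat dxhat = dy.each_row() % g.w;
  vec s1 = arma::sum(dxhat, 1) / D;
  vec s2 = arma::sum(dxhat % xhat, 1) / D;
  mat dx = dxhat;
  dx.each_col() -= s1;
  dx -= xhat.each_col() % s2;
  dx.each_col() %= ivc;
  return dx;
}

static mat relu_bwd(const mat &dh, const mat &h) {
  mat out = dh;
  out.elem(arma::find(h <= 0)).zeros();
  return out;
}

static void forward(Model *m, const arma::uvec &ids, FwdCache &C,
                    bool keep_cache) {
  int T = ids.n_elem;
  if (T > m->maxlen) stop("sequence longer than max_len");
  mat x = m->E.w.rows(ids) + m->P.w.rows(0, T - 1);
  C.lc.resize(m->L);
  int dh = m->D / m->H;
  double sc = 1.0 / std::sqrt((double)dh);
  for (int l = 0; l < m->L; ++l) {
    Layer &ly = m->layers[l];
    LayerCache &L = C.lc[l];
    if (keep_cache) L.x_in = x;
    L.Q = x * ly.Wq.w; L.Q.each_row() += ly.bq.w;
    L.K = x * ly.Wk.w; L.K.each_row() += ly.bk.w;
    L.Vm = x * ly.Wv.w; L.Vm.each_row() += ly.bv.w;
    L.ctx.set_size(T, m->D);
    L.A.resize(m->H);
    for (int h = 0; h < m->H; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat S = sc * (L.Q.cols(c0, c1) * L.K.cols(c0, c1).t());
      S.each_col() -= arma::max(S, 1);
      mat A = arma::exp(S);
      A.each_col() /= arma::sum(A, 1);
      L.A[h] = A;
      L.ctx.cols(c0, c1) = A * L.Vm.cols(c0, c1);
    }
    mat attn_out = L.ctx * ly.Wo.w;
    attn_out.each_row() += ly.bo.w;
    mat y1;
    layer_norm_fwd(x + attn_out, ly.g1, ly.be1, L.xhat1, L.iv1c, y1);
    mat hpre = y1 * ly.W1.w;
    hpre.each_row() += ly.b1.w;
    L.h = arma::clamp(hpre, 0.0, arma::datum::inf);  // ReLU
    mat f = L.h * ly.W2.w;
    f.each_row() += ly.b2.w;
    mat y2;
    layer_norm_fwd(y1 + f, ly.g2, ly.be2, L.xhat2, L.iv2c, y2);
    x = y2;
  }
  C.xout = x;
}

// Backward for one sequence given d(xout); accumulates parameter grads
// and adds the embedding gradients (token + position) directly.
static void backward(Model *m, const arma::uvec &ids, FwdCache &C, mat dx) {
  int T = ids.n_elem;
  int dh = m->D / m->H;
  double sc = 1.0 / std::sqrt((double)dh);
  for (int l = m->L - 1; l >= 0; --l) {
    Layer &ly = m->layers[l];
    LayerCache &L = C.lc[l];
    mat dres2 = layer_norm_bwd(dx, L.xhat2, L.iv2c, ly.g2, ly.be2);
    mat dy1 = dres2;                       // res2 = y1 + f
    ly.W2.g += L.h.t() * dres2;            // f = h W2 + b2
    ly.b2.g += arma::sum(dres2, 0);
    mat dh_ = relu_bwd(dres2 * ly.W2.w.t(), L.h);
    mat y1 = L.xhat1.each_row() % ly.g1.w; // recompute y1
    y1.each_row() += ly.be1.w;
    ly.W1.g += y1.t() * dh_;               // hpre = y1 W1 + b1
    ly.b1.g += arma::sum(dh_, 0);
    dy1 += dh_ * ly.W1.w.t();
    mat dres1 = layer_norm_bwd(dy1, L.xhat1, L.iv1c, ly.g1, ly.be1);
    mat dx_in = dres1;                     // res1 = x + attn_out
    ly.Wo.g += L.ctx.t() * dres1;          // attn_out = ctx Wo + bo
    ly.bo.g += arma::sum(dres1, 0);
    mat dctx = dres1 * ly.Wo.w.t();
    mat dQ(T, m->D, arma::fill::zeros), dK(T, m->D, arma::fill::zeros),
        dV(T, m->D, arma::fill::zeros);
    for (int h = 0; h < m->H; ++h) {
      int c0 = h * dh, c1 = (h + 1) * dh - 1;
      const mat &A = L.A[h];
      mat dctx_h = dctx.cols(c0, c1);
      mat dA = dctx_h * L.Vm.cols(c0, c1).t();
      dV.cols(c0, c1) = A.t() * dctx_h;
      vec rs = arma::sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rs);
      dQ.cols(c0, c1) = sc * (dS * L.K.cols(c0, c1));
      dK.cols(c0, c1) = sc * (dS.t() * L.Q.cols(c0, c1));
    }
    ly.Wq.g += L.x_in.t() * dQ; ly.bq.g += arma::sum(dQ, 0);
    ly.Wk.g += L.x_in.t() * dK; ly.bk.g += arma::sum(dK, 0);
    ly.Wv.g += L.x_in.t() * dV; ly.bv.g += arma::sum(dV, 0);
    dx_in += dQ * ly.Wq.w.t() + dK * ly.Wk.w.t() + dV * ly.Wv.w.t();
    dx = dx_in;
  }
  // x0 = E[ids] + P[0..T-1]
  for (int t = 0; t < T; ++t) {
    m->E.g.row(ids[t]) += dx.row(t);
    m->P.g.row(t) += dx.row(t);
  }
}

// Cross-entropy on labeled positions.  labels: 0 = ignore, else 1-based
// token id.  Returns summed loss, number of correct argmax predictions,
// and fills dxout (scaled by 1/n_total_labels later by the caller via
// `scale`).
static double mlm_head(Model *m, const arma::uvec &ids, const mat &xout,
                       const IntegerVector &labels, double scale, mat &dxout,
                       int &correct, bool want_grad) {
  int T = ids.n_elem;
  double loss = 0.0;
  if (want_grad) dxout.zeros(T, m->D);
  for (int t = 0; t < T; ++t) {
    int lab = labels[t];
    if (lab == 0) continue;
    rowvec logits = xout.row(t) * m->E.w.t() + m->bout.w;
    double mx = logits.max();
    rowvec ex = arma::exp(logits - mx);
    double Z = arma::accu(ex);
    rowvec p = ex / Z;
    loss -= std::log(std::max(p[lab - 1], 1e-12));
    if ((int)logits.index_max() == lab - 1) ++correct;
    if (want_grad) {
      rowvec dlog = p * scale;
      dlog[lab - 1] -= scale;
      dxout.row(t) += dlog * m->E.w;
      m->E.g += dlog.t() * xout.row(t);   // tied output projection
      m->bout.g += dlog;
    }
  }
  return loss;
}

// One Adam step over all parameters using accumulated gradients.
static void adam_step(Model *m, double lr, double beta1, double beta2,
                      double eps) {
  m->step += 1;
  double c1 = 1.0 - std::pow(beta1, (double)m->step);
  double c2 = 1.0 - std::pow(beta2, (double)m->step);
  std::vector<Param *> ps;
  m->collect(ps);
  for (size_t i = 0; i < ps.size(); ++i) {
    Param &p = *ps[i];
    p.m = beta1 * p.m + (1.0 - beta1) * p.g;
    p.v = beta2 * p.v + (1.0 - beta2) * (p.g % p.g);
    p.w -= lr * (p.m / c1) / (arma::sqrt(p.v / c2) + eps);
    p.g.zeros();
  }
}

// ids / labels: lists of integer vectors (1-based ids; label 0 = ignore).
// [[Rcpp::export]]
List tf_train_batch(SEXP ptr, List ids, List labels, double lr,
                    double beta1 = 0.9, double beta2 = 0.999,
                    double eps = 1e-8) {
  Model *m = get_model(ptr);
  int B = ids.size();
  long ntot = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector lab = labels[b];
    for (int t = 0; t < lab.size(); ++t) if (lab[t] != 0) ++ntot;
  }
  if (ntot == 0) stop("batch has no labeled (masked) positions");
  double scale = 1.0 / (double)ntot;
  double loss = 0.0;
  int correct = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector iv = ids[b];
    IntegerVector lab = labels[b];
    arma::uvec u(iv.size());
    for (int t = 0; t < iv.size(); ++t) u[t] = iv[t] - 1;
    FwdCache C;
    forward(m, u, C, true);
    mat dxout;
    loss += mlm_head(m, u, C.xout, lab, scale, dxout, correct, true);
    backward(m, u, C, dxout);
  }
  adam_step(m, lr, beta1, beta2, eps);
  return List::create(_["loss"] = loss / ntot, _["correct"] = correct,
                      _["n"] = (double)ntot);
}

// [[Rcpp::export]]
List tf_eval_batch(SEXP ptr, List ids, List labels) {
  Model *m = get_model(ptr);
  int B = ids.size();
  double loss = 0.0;
  int correct = 0;
  long ntot = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector iv = ids[b];
    IntegerVector lab = labels[b];
    arma::uvec u(iv.size());
    for (int t = 0; t < iv.size(); ++t) u[t] = iv[t] - 1;
    FwdCache C;
    forward(m, u, C, false);
    mat dummy;
    loss += mlm_head(m, u, C.xout, lab, 0.0, dummy, correct, false);
    for (int t = 0; t < lab.size(); ++t) if (lab[t] != 0) ++ntot;
  }
  return List::create(_["loss"] = ntot ? loss / ntot : NA_REAL,
                      _["correct"] = correct, _["n"] = (double)ntot);
}

// Final-layer hidden states for one sequence: T x D.
// [[Rcpp::export]]
arma::mat tf_encode(SEXP ptr, IntegerVector ids) {
  Model *m = get_model(ptr);
  arma::uvec u(ids.size());
  for (int t = 0; t < ids.size(); ++t) u[t] = ids[t] - 1;
  FwdCache C;
  forward(m, u, C, false);
  return C.xout;
}

// Per-layer, per-head attention maps: list (layers) of T x T x H cubes.
// [[Rcpp::export]]
List tf_attention(SEXP ptr, IntegerVector ids) {
  Model *m = get_model(ptr);
  arma::uvec u(ids.size());
  for (int t = 0; t < ids.size(); ++t) u[t] = ids[t] - 1;
  FwdCache C;
  forward(m, u, C, false);
  List out(m->L);
  int T = ids.size();
  for (int l = 0; l < m->L; ++l) {
    arma::cube cu(T, T, m->H);
    for (int h = 0; h < m->H; ++h) cu.slice(h) = C.lc[l].A[h];
    out[l] = cu;
  }
  return out;
}

// Feed-forward ReLU activations, concatenated over layers: T x (L*F).
// [[Rcpp::export]]
arma::mat tf_ffn_activations(SEXP ptr, IntegerVector ids) {
  Model *m = get_model(ptr);
  arma::uvec u(ids.size());
  for (int t = 0; t < ids.size(); ++t) u[t] = ids[t] - 1;
  FwdCache C;
  forward(m, u, C, false);
  int T = ids.size();
  mat out(T, m->L * m->F);
  for (int l = 0; l < m->L; ++l)
    out.cols(l * m->F, (l + 1) * m->F - 1) = C.lc[l].h;
  return out;
}
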