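// Encoder-decoder transformer over two disease node sets, with the
// column-norm softmax scoring head, fused sigmoid+BCE loss, analytic
// backward pass and an Adam step.  Parameters travel as one flat numeric
// vector so the R side can treat the model as opaque state; layout is
// fixed by the config (layers, d_model, heads, ff_dim) and identical for
// pack/unpack.  All randomness (init, dropout) is driven by an explicit
// seed so runs are bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
#if defined(__GLIBC__)
#include <malloc.h>
#endif

// Saturated attention and vanishing gradients produce many subnormal
// doubles; x86 handles those via microcode traps that slow GEMMs by an
// order of magnitude.  Flushing them to zero is numerically irrelevant
// here (|x| < 1e-308) and keeps step cost flat over training.
static inline void enable_ftz() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
#if defined(__GLIBC__)
  // The per-batch activation caches are a few hundred KB each and vary in
  // shape, so glibc keeps serving them via mmap/munmap; the zero-fill page
  // faults then dominate the GEMMs.  Keep them on the reusable heap.
  static bool tuned = false;
  if (!tuned) {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
    tuned = true;
  }
#endif
}

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;
static const double MASK_NEG = -1e30;

struct Cfg {
  int L, d, h, f;
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.L = as<int>(cfg["layers"]);
  c.d = as<int>(cfg["d_model"]);
  c.h = as<int>(cfg["heads"]);
  c.f = as<int>(cfg["ff_dim"]);
  if (c.d % c.h != 0) stop("d_model must be divisible by heads");
  return c;
}

struct AttnP { mat Wq, Wk, Wv, Wo; vec bq, bk, bv, bo; };
struct LNP   { vec g, b; };
struct FFP   { mat W1, W2; vec b1, b2; };
struct EncL  { AttnP at; LNP ln1; FFP ff; LNP ln2; };
struct DecL  { AttnP self; LNP ln1; AttnP cross; LNP ln2; FFP ff; LNP ln3; };
struct Params {
  std::vector<EncL> enc;
  std::vector<DecL> dec;
  vec w; double b;
};

// ---- flat <-> struct -------------------------------------------------------

static size_t attn_size(int d) { return 4ull * d * d + 4ull * d; }
static size_t ln_size(int d)   { return 2ull * d; }
static size_t ff_size(int d, int f) { return 2ull * (size_t)d * f + (size_t)d + f; }

static size_t n_params(const Cfg& c) {
  size_t enc1 = attn_size(c.d) + ln_size(c.d) + ff_size(c.d, c.f) + ln_size(c.d);
  size_t dec1 = 2 * attn_size(c.d) + 3 * ln_size(c.d) + ff_size(c.d, c.f);
  return (size_t)c.L * (enc1 + dec1) + c.d + 1;
}

struct Reader {
  const double* p; size_t off;
  mat M(int r, int c) { mat m(r, c); std::copy(p + off, p + off + (size_t)r * c, m.memptr()); off += (size_t)r * c; return m; }
  vec V(int n) { vec v(n); std::copy(p + off, p + off + n, v.memptr()); off += n; return v; }
  double S() { return p[off++]; }
};
struct Writer {
  double* p; size_t off;
  void M(const mat& m) { std::copy(m.memptr(), m.memptr() + m.n_elem, p + off); off += m.n_elem; }
  void V(const vec& v) { std::copy(v.memptr(), v.memptr() + v.n_elem, p + off); off += v.n_elem; }
  void S(double s) { p[off++] = s; }
};

static AttnP read_attn(Reader& r, int d) {
  AttnP a;
  a.Wq = r.M(d, d); a.bq = r.V(d);
  a.Wk = r.M(d, d); a.bk = r.V(d);
  a.Wv = r.M(d, d); a.bv = r.V(d);
  a.Wo = r.M(d, d); a.bo = r.V(d);
  return a;
}
static LNP read_ln(Reader& r, int d) { LNP l; l.g = r.V(d); l.b = r.V(d); return l; }
static FFP read_ff(Reader& r, int d, int f) {
  FFP ff; ff.W1 = r.M(d, f); ff.b1 = r.V(f); ff.W2 = r.M(f, d); ff.b2 = r.V(d); return ff;
}

static Params unpack(const double* src, const Cfg& c) {
  Reader r{src, 0};
  Params P;
  P.enc.resize(c.L); P.dec.resize(c.L);
  for (int l = 0; l < c.L; ++l) {
    P.enc[l].at  = read_attn(r, c.d);
    P.enc[l].ln1 = read_ln(r, c.d);
    P.enc[l].ff  = read_ff(r, c.d, c.f);
    P.enc[l].ln2 = read_ln(r, c.d);
  }
  for (int l = 0; l < c.L; ++l) {
    P.dec[l].self  = read_attn(r, c.d);
    P.dec[l].ln1   = read_ln(r, c.d);
    P.dec[l].cross = read_attn(r, c.d);
    P.dec[l].ln2   = read_ln(r, c.d);
    P.dec[l].ff    = read_ff(r, c.d, c.f);
    P.dec[l].ln3   = read_ln(r, c.d);
  }
  P.w = r.V(c.d); P.b = r.S();
  return P;
}

static void write_attn(Writer& w, const AttnP& a) {
  w.M(a.Wq); w.V(a.bq); w.M(a.Wk); w.V(a.bk); w.M(a.Wv); w.V(a.bv); w.M(a.Wo); w.V(a.bo);
}
static void write_ln(Writer& w, const LNP& l) { w.V(l.g); w.V(l.b); }
static void write_ff(Writer& w, const FFP& f) { w.M(f.W1); w.V(f.b1); w.M(f.W2); w.V(f.b2); }

static void pack(const Params& P, double* dst, const Cfg& c) {
  Writer w{dst, 0};
  for (int l = 0; l < c.L; ++l) {
    write_attn(w, P.enc[l].at); write_ln(w, P.enc[l].ln1);
    write_ff(w, P.enc[l].ff);   write_ln(w, P.enc[l].ln2);
  }
  for (int l = 0; l < c.L; ++l) {
    write_attn(w, P.dec[l].self); write_ln(w, P.dec[l].ln1);
    write_attn(w, P.dec[l].cross); write_ln(w, P.dec[l].ln2);
    write_ff(w, P.dec[l].ff); write_ln(w, P.dec[l].ln3);
  }
  w.V(P.w); w.S(P.b);
}

static Params zero_like(const Cfg& c) {
  Params G;
  G.enc.resize(c.L); G.dec.resize(c.L);
  auto za = [&](AttnP& a) {
    a.Wq.zeros(c.d, c.d); a.bq.zeros(c.d); a.Wk.zeros(c.d, c.d); a.bk.zeros(c.d);
    a.Wv.zeros(c.d, c.d); a.bv.zeros(c.d); a.Wo.zeros(c.d, c.d); a.bo.zeros(c.d);
  };
  auto zl = [&](LNP& l) { l.g.zeros(c.d); l.b.zeros(c.d); };
  auto zf = [&](FFP& f) { f.W1.zeros(c.d, c.f); f.b1.zeros(c.f); f.W2.zeros(c.f, c.d); f.b2.zeros(c.d); };
  for (int l = 0; l < c.L; ++l) {
    za(G.enc[l].at); zl(G.enc[l].ln1); zf(G.enc[l].ff); zl(G.enc[l].ln2);
    za(G.dec[l].self); zl(G.dec[l].ln1); za(G.dec[l].cross); zl(G.dec[l].ln2);
    zf(G.dec[l].ff); zl(G.dec[l].ln3);
  }
  G.w.zeros(c.d); G.b = 0.0;
  return G;
}

// ---- building blocks -------------------------------------------------------

struct AttnCache {
  mat Xq, Xkv, Q, K, V, O;     // O = concat of head outputs, pre out-projection
  arma::cube P;                // n_q x n_k x h attention weights
};

// key_mask: length n_k, 1 = real token, 0 = padded (excluded as a key).
static mat attn_fwd(const AttnP& p, const mat& Xq, const mat& Xkv,
                    const vec* key_mask, int h, AttnCache* cc) {
  int d = p.Wq.n_cols, dk = d / h;
  double scale = 1.0 / std::sqrt((double)dk);
  mat Q = Xq * p.Wq;  Q.each_row() += p.bq.t();
  mat K = Xkv * p.Wk; K.each_row() += p.bk.t();
  mat V = Xkv * p.Wv; V.each_row() += p.bv.t();
  mat O(Xq.n_rows, d);
  arma::cube Pc(Xq.n_rows, Xkv.n_rows, h);
  rowvec maskrow;
  if (key_mask) maskrow = ((1.0 - *key_mask) * MASK_NEG).t();
  for (int i = 0; i < h; ++i) {
    arma::span sp(i * dk, (i + 1) * dk - 1);
    // softmax computed in place inside the cache slice: no temporaries
    mat Sm(Pc.slice_memptr(i), Xq.n_rows, Xkv.n_rows, false, true);
    Sm = Q.cols(sp) * K.cols(sp).t();
    Sm *= scale;
    if (key_mask) Sm.each_row() += maskrow;
    Sm.each_col() -= arma::max(Sm, 1);
    Sm.transform([](double x) { return std::exp(x); });
    Sm.each_col() /= arma::sum(Sm, 1);
    O.cols(sp) = Sm * V.cols(sp);
  }
  mat out = O * p.Wo; out.each_row() += p.bo.t();
  if (cc) { cc->Xq = Xq; cc->Xkv = Xkv; cc->Q = std::move(Q); cc->K = std::move(K); cc->V = std::move(V); cc->O = std::move(O); cc->P = std::move(Pc); }
  return out;
}

// returns dXq; accumulates dXkv into dXkv_acc and parameter grads into g.
static mat attn_bwd(const AttnP& p, AttnP& g, const AttnCache& cc,
                    const mat& dout, mat& dXkv_acc, int h) {
  int d = p.Wq.n_cols, dk = d / h;
  double scale = 1.0 / std::sqrt((double)dk);
  g.Wo += cc.O.t() * dout;
  g.bo += arma::sum(dout, 0).t();
  mat dO = dout * p.Wo.t();
  mat dQ(cc.Q.n_rows, d);
  mat dK(cc.K.n_rows, d);
  mat dV(cc.V.n_rows, d);
  for (int i = 0; i < h; ++i) {
    arma::span sp(i * dk, (i + 1) * dk - 1);
    const mat Pm(const_cast<double*>(cc.P.slice_memptr(i)),
                 cc.Q.n_rows, cc.K.n_rows, false, true);
    mat dP = dO.cols(sp) * cc.V.cols(sp).t();
    dV.cols(sp) = Pm.t() * dO.cols(sp);
    vec rs = arma::sum(dP % Pm, 1);
    dP.each_col() -= rs;     // softmax backward, in place
    dP %= Pm;
    dP *= scale;
    dQ.cols(sp) = dP * cc.K.cols(sp);
    dK.cols(sp) = dP.t() * cc.Q.cols(sp);
  }
  g.Wq += cc.Xq.t() * dQ;  g.bq += arma::sum(dQ, 0).t();
  g.Wk += cc.Xkv.t() * dK; g.bk += arma::sum(dK, 0).t();
  g.Wv += cc.Xkv.t() * dV; g.bv += arma::sum(dV, 0).t();
  dXkv_acc += dK * p.Wk.t() + dV * p.Wv.t();
  return dQ * p.Wq.t();
}

struct LNCache { mat xhat; vec inv; };

static mat ln_fwd(const LNP& p, const mat& X, LNCache* cc) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  vec inv = 1.0 / arma::sqrt(v + LN_EPS);
  mat xhat = xc.each_col() % inv;
  mat Y = xhat.each_row() % p.g.t();
  Y.each_row() += p.b.t();
  if (cc) { cc->xhat = xhat; cc->inv = inv; }
  return Y;
}

static mat ln_bwd(const LNP& p, LNP& g, const LNCache& cc, const mat& dY) {
  g.g += arma::sum(dY % cc.xhat, 0).t();
  g.b += arma::sum(dY, 0).t();
  mat dxhat = dY.each_row() % p.g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cc.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= cc.xhat.each_col() % m2;
  dX.each_col() %= cc.inv;
  return dX;
}

struct FFCache { mat X, R; arma::umat pos; };

static mat ff_fwd(const FFP& p, const mat& X, FFCache* cc) {
  mat H = X * p.W1; H.each_row() += p.b1.t();
  arma::umat pos = (H > 0);
  mat R = H % arma::conv_to<mat>::from(pos);
  mat O = R * p.W2; O.each_row() += p.b2.t();
  if (cc) { cc->X = X; cc->R = R; cc->pos = pos; }
  return O;
}

static mat ff_bwd(const FFP& p, FFP& g, const FFCache& cc, const mat& dO) {
  g.W2 += cc.R.t() * dO;
  g.b2 += arma::sum(dO, 0).t();
  mat dR = dO * p.W2.t();
  mat dH = dR % arma::conv_to<mat>::from(cc.pos);
  g.W1 += cc.X.t() * dH;
  g.b1 += arma::sum(dH, 0).t();
  return dH * p.W1.t();
}

// inverted dropout; mask entries are 0 or 1/(1-rate).  A splitmix64
// stream (seeded from the caller's mt19937) keeps mask generation cheap
// relative to the GEMMs.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  double next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ull);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ull;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebull;
    z ^= z >> 31;
    return (double)(z >> 11) * 0x1.0p-53;
  }
};

static mat drop_mask(SplitMix64& rng, double rate, int r, int c) {
  mat m(r, c);
  if (rate <= 0.0) { m.ones(); return m; }
  double keep = 1.0 - rate;
  double inv = 1.0 / keep;
  double* p = m.memptr();
  for (arma::uword i = 0; i < m.n_elem; ++i)
    p[i] = (rng.next() < keep) ? inv : 0.0;
  return m;
}

// ---- full forward (with caches) -------------------------------------------

struct EncCache { AttnCache at; LNCache ln1; FFCache ff; LNCache ln2; mat x_in, d1, d2; };
struct DecCache {
  AttnCache self; LNCache ln1; AttnCache cross; LNCache ln2; FFCache ff; LNCache ln3;
  mat x_in, h1, h2, d1, d2, d3;
};

struct FwdCache {
  std::vector<EncCache> enc;
  std::vector<DecCache> dec;
  mat mem, dec_out;
  vec s, ypool, cn;
  double logit, prob;
};

// maskA/maskB may be empty vecs (no padding).  Head statistics are computed
// over real (unmasked) B rows only.
static void model_fwd(const Params& P, const Cfg& c, const mat& Ea, const mat& Eb,
                      const vec& maskA, const vec& maskB,
                      double dropout, SplitMix64* rng, FwdCache& F) {
  const vec* mA = maskA.n_elem ? &maskA : nullptr;
  const vec* mB = maskB.n_elem ? &maskB : nullptr;
  F.enc.resize(c.L); F.dec.resize(c.L);
  mat X = Ea;
  for (int l = 0; l < c.L; ++l) {
    EncCache& e = F.enc[l];
    e.x_in = X;
    mat A = attn_fwd(P.enc[l].at, X, X, mA, c.h, &e.at);
    e.d1 = rng ? drop_mask(*rng, dropout, A.n_rows, A.n_cols) : mat(A.n_rows, A.n_cols, arma::fill::ones);
    mat H = ln_fwd(P.enc[l].ln1, X + A % e.d1, &e.ln1);
    mat Fo = ff_fwd(P.enc[l].ff, H, &e.ff);
    e.d2 = rng ? drop_mask(*rng, dropout, Fo.n_rows, Fo.n_cols) : mat(Fo.n_rows, Fo.n_cols, arma::fill::ones);
    X = ln_fwd(P.enc[l].ln2, H + Fo % e.d2, &e.ln2);
  }
  F.mem = X;
  mat Y = Eb;
  for (int l = 0; l < c.L; ++l) {
    DecCache& dcc = F.dec[l];
    dcc.x_in = Y;
    mat A = attn_fwd(P.dec[l].self, Y, Y, mB, c.h, &dcc.self);
    dcc.d1 = rng ? drop_mask(*rng, dropout, A.n_rows, A.n_cols) : mat(A.n_rows, A.n_cols, arma::fill::ones);
    dcc.h1 = ln_fwd(P.dec[l].ln1, Y + A % dcc.d1, &dcc.ln1);
    mat C = attn_fwd(P.dec[l].cross, dcc.h1, F.mem, mA, c.h, &dcc.cross);
    dcc.d2 = rng ? drop_mask(*rng, dropout, C.n_rows, C.n_cols) : mat(C.n_rows, C.n_cols, arma::fill::ones);
    dcc.h2 = ln_fwd(P.dec[l].ln2, dcc.h1 + C % dcc.d2, &dcc.ln2);
    mat Fo = ff_fwd(P.dec[l].ff, dcc.h2, &dcc.ff);
    dcc.d3 = rng ? drop_mask(*rng, dropout, Fo.n_rows, Fo.n_cols) : mat(Fo.n_rows, Fo.n_cols, arma::fill::ones);
    Y = ln_fwd(P.dec[l].ln3, dcc.h2 + Fo % dcc.d3, &dcc.ln3);
  }
  F.dec_out = Y;
  // scoring head over real B rows
  arma::uvec keep = mB ? arma::find(maskB > 0.5) : arma::regspace<arma::uvec>(0, Y.n_rows - 1);
  mat Yk = Y.rows(keep);
  vec cn = arma::sum(Yk % Yk, 1);          // squared L2 norm of each column of X = row of dec out
  vec e = arma::exp(cn - cn.max());
  F.s = e / arma::accu(e);
  F.cn = cn;
  F.ypool = Yk.t() * F.s;
  F.logit = arma::dot(P.w, F.ypool) + P.b;
  F.prob = 1.0 / (1.0 + std::exp(-F.logit));
}

// dlogit -> grads; assumes no padding (training batches carry exact sizes).
static void model_bwd(const Params& P, const Cfg& c, Params& G, FwdCache& F, double dlogit) {
  G.w += dlogit * F.ypool;
  G.b += dlogit;
  vec dyp = dlogit * P.w;
  mat& Y = F.dec_out;
  vec ds = Y * dyp;                         // n_b
  mat dY = F.s * dyp.t();                   // n_b x d
  vec dcn = F.s % (ds - arma::dot(F.s, ds));
  dY += 2.0 * (Y.each_col() % dcn);
  mat dMem(F.mem.n_rows, c.d, arma::fill::zeros);
  for (int l = c.L - 1; l >= 0; --l) {
    DecCache& dcc = F.dec[l];
    mat dS3 = ln_bwd(P.dec[l].ln3, G.dec[l].ln3, dcc.ln3, dY);
    mat dFo = dS3 % dcc.d3;
    mat dH2 = dS3 + ff_bwd(P.dec[l].ff, G.dec[l].ff, dcc.ff, dFo);
    mat dS2 = ln_bwd(P.dec[l].ln2, G.dec[l].ln2, dcc.ln2, dH2);
    mat dC = dS2 % dcc.d2;
    mat dH1 = dS2 + attn_bwd(P.dec[l].cross, G.dec[l].cross, dcc.cross, dC, dMem, c.h);
    mat dS1 = ln_bwd(P.dec[l].ln1, G.dec[l].ln1, dcc.ln1, dH1);
    mat dA = dS1 % dcc.d1;
    mat dYkv(dS1.n_rows, c.d, arma::fill::zeros);
    mat dYq = attn_bwd(P.dec[l].self, G.dec[l].self, dcc.self, dA, dYkv, c.h);
    dY = dS1 + dYq + dYkv;
  }
  mat dX = dMem;
  for (int l = c.L - 1; l >= 0; --l) {
    EncCache& e = F.enc[l];
    mat dS2 = ln_bwd(P.enc[l].ln2, G.enc[l].ln2, e.ln2, dX);
    mat dFo = dS2 % e.d2;
    mat dH = dS2 + ff_bwd(P.enc[l].ff, G.enc[l].ff, e.ff, dFo);
    mat dS1 = ln_bwd(P.enc[l].ln1, G.enc[l].ln1, e.ln1, dH);
    mat dA = dS1 % e.d1;
    mat dXkv(dS1.n_rows, c.d, arma::fill::zeros);
    mat dXq = attn_bwd(P.enc[l].at, G.enc[l].at, e.at, dA, dXkv, c.h);
    dX = dS1 + dXq + dXkv;
  }
}

// ---- exported --------------------------------------------------------------

// [[Rcpp::export]]
int tspe_n_params_cpp(List cfg) {
  return (int)n_params(read_cfg(cfg));
}

// [[Rcpp::export]]
NumericVector tspe_init_cpp(List cfg, int seed) {
  Cfg c = read_cfg(cfg);
  std::mt19937 rng(seed);
  NumericVector out((R_xlen_t)n_params(c));
  double* p = REAL(out);
  Params P = zero_like(c);
  auto xavier = [&](mat& M) {
    double lim = std::sqrt(6.0 / (M.n_rows + M.n_cols));
    std::uniform_real_distribution<double> U(-lim, lim);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i) M(i, j) = U(rng);
  };
  auto init_attn = [&](AttnP& a) { xavier(a.Wq); xavier(a.Wk); xavier(a.Wv); xavier(a.Wo); };
  auto init_ln = [&](LNP& l) { l.g.ones(); l.b.zeros(); };
  auto init_ff = [&](FFP& f) { xavier(f.W1); xavier(f.W2); };
  for (int l = 0; l < c.L; ++l) {
    init_attn(P.enc[l].at); init_ln(P.enc[l].ln1); init_ff(P.enc[l].ff); init_ln(P.enc[l].ln2);
    init_attn(P.dec[l].self); init_ln(P.dec[l].ln1);
    init_attn(P.dec[l].cross); init_ln(P.dec[l].ln2);
    init_ff(P.dec[l].ff); init_ln(P.dec[l].ln3);
  }
  {
    double lim = std::sqrt(6.0 / (c.d + 1));
    std::uniform_real_distribution<double> U(-lim, lim);
    for (int i = 0; i < c.d; ++i) P.w(i) = U(rng);
    P.b = 0.0;
  }
  pack(P, p, c);
  return out;
}

// [[Rcpp::export]]
List tspe_forward_cpp(NumericVector params, arma::mat Ea, arma::mat Eb, List cfg,
                      Nullable<NumericVector> maskA = R_NilValue,
                      Nullable<NumericVector> maskB = R_NilValue) {
  enable_ftz();
  Cfg c = read_cfg(cfg);
  if ((int)Ea.n_cols != c.d || (int)Eb.n_cols != c.d)
    stop("token dimension (%d / %d) does not match d_model (%d)",
         (int)Ea.n_cols, (int)Eb.n_cols, c.d);
  if ((size_t)params.size() != n_params(c)) stop("parameter vector length mismatch");
  Params P = unpack(REAL(params), c);
  vec mA, mB;
  if (maskA.isNotNull()) mA = as<vec>(maskA.get());
  if (maskB.isNotNull()) mB = as<vec>(maskB.get());
  FwdCache F;
  model_fwd(P, c, Ea, Eb, mA, mB, 0.0, nullptr, F);
  arma::uvec keep = mB.n_elem ? arma::find(mB > 0.5)
                              : arma::regspace<arma::uvec>(0, Eb.n_rows - 1);
  mat X = F.dec_out.rows(keep).t();        // d_model x n_b_real
  return List::create(_["X"] = X, _["s"] = F.s, _["y_pool"] = F.ypool,
                      _["logit"] = F.logit, _["prob"] = F.prob);
}

// [[Rcpp::export]]
List tspe_loss_grad_cpp(NumericVector params, List Ea_list, List Eb_list,
                        NumericVector labels, List cfg, double dropout, int seed) {
  enable_ftz();
  Cfg c = read_cfg(cfg);
  if ((size_t)params.size() != n_params(c)) stop("parameter vector length mismatch");
  int n = Ea_list.size();
  if (Eb_list.size() != n || labels.size() != n) stop("batch size mismatch");
  Params P = unpack(REAL(params), c);
  Params G = zero_like(c);
  SplitMix64 rng((uint64_t)seed * 0x9e3779b97f4a7c15ull + 1ull);
  SplitMix64* rp = dropout > 0.0 ? &rng : nullptr;
  double loss = 0.0;
  NumericVector logits(n);
  vec nomask;
  for (int i = 0; i < n; ++i) {
    mat Ea = as<mat>(Ea_list[i]);
    mat Eb = as<mat>(Eb_list[i]);
    double y = labels[i];
    FwdCache F;
    model_fwd(P, c, Ea, Eb, nomask, nomask, dropout, rp, F);
    double l = F.logit;
    logits[i] = l;
    // numerically stable BCE-with-logits
    loss += std::max(l, 0.0) - l * y + std::log1p(std::exp(-std::fabs(l)));
    model_bwd(P, c, G, F, (F.prob - y) / n);
  }
  loss /= n;
  NumericVector gflat((R_xlen_t)n_params(c));
  pack(G, REAL(gflat), c);
  return List::create(_["loss"] = loss, _["grad"] = gflat, _["logits"] = logits);
}

// [[Rcpp::export]]
void tspe_adam_cpp(NumericVector params, NumericVector grad,
                   NumericVector m, NumericVector v, int t,
                   double lr, double beta1, double beta2, double eps) {
  enable_ftz();
  R_xlen_t n = params.size();
  if (grad.size() != n || m.size() != n || v.size() != n) stop("adam state length mismatch");
  double* p = REAL(params); double* g = REAL(grad);
  double* mm = REAL(m); double* vv = REAL(v);
  double bc1 = 1.0 - std::pow(beta1, (double)t);
  double bc2 = 1.0 - std::pow(beta2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
}
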