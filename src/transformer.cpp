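// Encoder-only causal transformer over pixel sequences: forward pass,
// teacher-forced NLL gradient (backprop through attention, layer norm and the
// feed-forward blocks), and incremental ancestral sampling with a key/value
// cache. Post-norm sublayers: A = norm(H + mha(H)); H' = norm(A + fc(A)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;

static const double LN_EPS = 1e-5;

struct TFConfig {
  int L, d, nheads, p, r, ff, dk;
};

struct TFLayer {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, ln1g, ln1b, ln2g, ln2b;
};

struct TFParams {
  mat Wx, Ws, WE, headW;
  rowvec headb;
  std::vector<TFLayer> layers;
};

static TFConfig parse_cfg(const List& cfg) {
  TFConfig c;
  c.L = as<int>(cfg["L"]);
  c.d = as<int>(cfg["d"]);
  c.nheads = as<int>(cfg["n_heads"]);
  c.p = as<int>(cfg["p"]);
  c.r = as<int>(cfg["r"]);
  c.ff = as<int>(cfg["ff_width"]);
  if (c.d % c.nheads != 0) stop("d must be divisible by n_heads");
  c.dk = c.d / c.nheads;
  return c;
}

static TFLayer parse_layer(const List& ll) {
  TFLayer ly;
  ly.Wq = as<mat>(ll["Wq"]); ly.bq = as<rowvec>(ll["bq"]);
  ly.Wk = as<mat>(ll["Wk"]); ly.bk = as<rowvec>(ll["bk"]);
  ly.Wv = as<mat>(ll["Wv"]); ly.bv = as<rowvec>(ll["bv"]);
  ly.Wo = as<mat>(ll["Wo"]); ly.bo = as<rowvec>(ll["bo"]);
  ly.ln1g = as<rowvec>(ll["ln1_g"]); ly.ln1b = as<rowvec>(ll["ln1_b"]);
  ly.W1 = as<mat>(ll["W1"]); ly.b1 = as<rowvec>(ll["b1"]);
  ly.W2 = as<mat>(ll["W2"]); ly.b2 = as<rowvec>(ll["b2"]);
  ly.ln2g = as<rowvec>(ll["ln2_g"]); ly.ln2b = as<rowvec>(ll["ln2_b"]);
  return ly;
}

static TFParams parse_params(const List& pl, const TFConfig& c) {
  TFParams P;
  P.Wx = as<mat>(pl["Wx"]);
  P.Ws = as<mat>(pl["Ws"]);
  P.WE = as<mat>(pl["WE"]);
  P.headW = as<mat>(pl["head_W"]);
  P.headb = as<rowvec>(pl["head_b"]);
  List Ls = pl["layers"];
  if ((int)Ls.size() != c.L) stop("params$layers length does not match config L");
  for (int l = 0; l < c.L; ++l) P.layers.push_back(parse_layer(List(Ls[l])));
  return P;
}

static TFLayer zero_layer_like(const TFLayer& ly) {
  TFLayer g;
  g.Wq = arma::zeros<mat>(ly.Wq.n_rows, ly.Wq.n_cols); g.bq = arma::zeros<rowvec>(ly.bq.n_elem);
  g.Wk = arma::zeros<mat>(ly.Wk.n_rows, ly.Wk.n_cols); g.bk = arma::zeros<rowvec>(ly.bk.n_elem);
  g.Wv = arma::zeros<mat>(ly.Wv.n_rows, ly.Wv.n_cols); g.bv = arma::zeros<rowvec>(ly.bv.n_elem);
  g.Wo = arma::zeros<mat>(ly.Wo.n_rows, ly.Wo.n_cols); g.bo = arma::zeros<rowvec>(ly.bo.n_elem);
  g.ln1g = arma::zeros<rowvec>(ly.ln1g.n_elem); g.ln1b = arma::zeros<rowvec>(ly.ln1b.n_elem);
  g.W1 = arma::zeros<mat>(ly.W1.n_rows, ly.W1.n_cols); g.b1 = arma::zeros<rowvec>(ly.b1.n_elem);
  g.W2 = arma::zeros<mat>(ly.W2.n_rows, ly.W2.n_cols); g.b2 = arma::zeros<rowvec>(ly.b2.n_elem);
  g.ln2g = arma::zeros<rowvec>(ly.ln2g.n_elem); g.ln2b = arma::zeros<rowvec>(ly.ln2b.n_elem);
  return g;
}

// --- layer norm -------------------------------------------------------------

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b,
                  mat& Xhat, vec& istd) {
  const arma::uword q = X.n_rows;
  mat Y(q, X.n_cols);
  Xhat.set_size(q, X.n_cols);
  istd.set_size(q);
  for (arma::uword i = 0; i < q; ++i) {
    double mu = arma::mean(X.row(i));
    rowvec cent = X.row(i) - mu;
    double va = arma::mean(arma::square(cent));
    double is = 1.0 / std::sqrt(va + LN_EPS);
    istd(i) = is;
    Xhat.row(i) = cent * is;
    Y.row(i) = Xhat.row(i) % g + b;
  }
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& Xhat, const vec& istd,
                  const rowvec& g, rowvec& dg, rowvec& db) {
  const arma::uword q = dY.n_rows, d = dY.n_cols;
  mat dX(q, d);
  dg += arma::sum(dY % Xhat, 0);
  db += arma::sum(dY, 0);
  for (arma::uword i = 0; i < q; ++i) {
    rowvec dxh = dY.row(i) % g;
    double m1 = arma::mean(dxh);
    double m2 = arma::mean(dxh % Xhat.row(i));
    dX.row(i) = istd(i) * (dxh - m1 - Xhat.row(i) * m2);
  }
  return dX;
}

// --- attention layer forward/backward --------------------------------------

struct LCache {
  mat Hin, Q, K, V;
  arma::cube Ah;          // nheads slices, q x q attention weights
  mat Oc, U1, Xhat1, Aout, Z1, Rl, U2, Xhat2, Hout;
  vec istd1, istd2;
  mat m1, m2;             // dropout masks (already scaled), empty if unused
};

// allow(i, j) == 1 means query i may attend to key j
static mat masked_softmax_rows(mat S, const umat& allow) {
  const arma::uword q = S.n_rows, k = S.n_cols;
  for (arma::uword i = 0; i < q; ++i) {
    double mx = -arma::datum::inf;
    for (arma::uword j = 0; j < k; ++j)
      if (allow(i, j) && S(i, j) > mx) mx = S(i, j);
    if (!std::isfinite(mx)) { S.row(i).zeros(); continue; }
    double tot = 0.0;
    for (arma::uword j = 0; j < k; ++j) {
      if (allow(i, j)) { S(i, j) = std::exp(S(i, j) - mx); tot += S(i, j); }
      else S(i, j) = 0.0;
    }
    S.row(i) /= tot;
  }
  return S;
}

static mat layer_fwd(const mat& Hin, const TFLayer& ly, const TFConfig& c,
                     const umat& allow, double pdrop, LCache& cc) {
  const arma::uword q = Hin.n_rows;
  cc.Hin = Hin;
  cc.Q = Hin * ly.Wq; cc.Q.each_row() += ly.bq;
  cc.K = Hin * ly.Wk; cc.K.each_row() += ly.bk;
  cc.V = Hin * ly.Wv; cc.V.each_row() += ly.bv;
  cc.Ah.set_size(q, q, c.nheads);
  cc.Oc.set_size(q, c.d);
  const double scale = 1.0 / std::sqrt((double)c.dk);
  for (int h = 0; h < c.nheads; ++h) {
    arma::span hs(h * c.dk, (h + 1) * c.dk - 1);
    mat S = cc.Q.cols(hs) * cc.K.cols(hs).t() * scale;
    cc.Ah.slice(h) = masked_softmax_rows(S, allow);
    cc.Oc.cols(hs) = cc.Ah.slice(h) * cc.V.cols(hs);
  }
  mat O = cc.Oc * ly.Wo;
  O.each_row() += ly.bo;
  if (pdrop > 0) {
    cc.m1.set_size(q, c.d);
    for (arma::uword i = 0; i < cc.m1.n_elem; ++i)
      cc.m1(i) = (unif_rand() < pdrop) ? 0.0 : 1.0 / (1.0 - pdrop);
    O %= cc.m1;
  }
  cc.U1 = Hin + O;
  cc.Aout = ln_fwd(cc.U1, ly.ln1g, ly.ln1b, cc.Xhat1, cc.istd1);
  cc.Z1 = cc.Aout * ly.W1;
  cc.Z1.each_row() += ly.b1;
  cc.Rl = cc.Z1 % arma::conv_to<mat>::from(cc.Z1 > 0);
  mat F = cc.Rl * ly.W2;
  F.each_row() += ly.b2;
  if (pdrop > 0) {
    cc.m2.set_size(q, c.d);
    for (arma::uword i = 0; i < cc.m2.n_elem; ++i)
      cc.m2(i) = (unif_rand() < pdrop) ? 0.0 : 1.0 / (1.0 - pdrop);
    F %= cc.m2;
  }
  cc.U2 = cc.Aout + F;
  cc.Hout = ln_fwd(cc.U2, ly.ln2g, ly.ln2b, cc.Xhat2, cc.istd2);
  return cc.Hout;
}

static mat layer_bwd(const mat& dHout, const TFLayer& ly, const TFConfig& c,
                     const LCache& cc, TFLayer& g) {
  const double scale = 1.0 / std::sqrt((double)c.dk);
  mat dU2 = ln_bwd(dHout, cc.Xhat2, cc.istd2, ly.ln2g, g.ln2g, g.ln2b);
  mat dAout = dU2;
  mat dF = dU2;
  if (!cc.m2.is_empty()) dF %= cc.m2;
  g.W2 += cc.Rl.t() * dF;
  g.b2 += arma::sum(dF, 0);
  mat dRl = dF * ly.W2.t();
  mat dZ1 = dRl % arma::conv_to<mat>::from(cc.Z1 > 0);
  g.W1 += cc.Aout.t() * dZ1;
  g.b1 += arma::sum(dZ1, 0);
  dAout += dZ1 * ly.W1.t();
  mat dU1 = ln_bwd(dAout, cc.Xhat1, cc.istd1, ly.ln1g, g.ln1g, g.ln1b);
  mat dHin = dU1;
  mat dO = dU1;
  if (!cc.m1.is_empty()) dO %= cc.m1;
  g.Wo += cc.Oc.t() * dO;
  g.bo += arma::sum(dO, 0);
  mat dOc = dO * ly.Wo.t();
  mat dQ(dHout.n_rows, c.d), dK(dHout.n_rows, c.d), dV(dHout.n_rows, c.d);
  for (int h = 0; h < c.nheads; ++h) {
    arma::span hs(h * c.dk, (h + 1) * c.dk - 1);
    const mat& Ah = cc.Ah.slice(h);
    mat dOh = dOc.cols(hs);
    mat dAh = dOh * cc.V.cols(hs).t();
    dV.cols(hs) = Ah.t() * dOh;
    vec rs = arma::sum(dAh % Ah, 1);
    mat tmp = dAh;
    tmp.each_col() -= rs;
    mat dS = Ah % tmp;
    dQ.cols(hs) = dS * cc.K.cols(hs) * scale;
    dK.cols(hs) = dS.t() * cc.Q.cols(hs) * scale;
  }
  g.Wq += cc.Hin.t() * dQ; g.bq += arma::sum(dQ, 0); dHin += dQ * ly.Wq.t();
  g.Wk += cc.Hin.t() * dK; g.bk += arma::sum(dK, 0); dHin += dK * ly.Wk.t();
  g.Wv += cc.Hin.t() * dV; g.bv += arma::sum(dV, 0); dHin += dV * ly.Wv.t();
  return dHin;
}

static umat causal_allow(int q) {
  umat allow(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j <= i; ++j) allow(i, j) = 1;
  return allow;
}

// H0 for one teacher-forced image: row 0 = Ws[n] + WE[0], row t = Wx[x_{t-1}] + WE[t]
static mat build_h0(const TFParams& P, const int* x, int r, int nidx) {
  mat H0(r, P.WE.n_cols);
  H0.row(0) = P.Ws.row(nidx) + P.WE.row(0);
  for (int t = 1; t < r; ++t)
    H0.row(t) = P.Wx.row(x[t - 1]) + P.WE.row(t);
  return H0;
}

// [[Rcpp::export]]
arma::mat cpp_encoder_forward(const List& params, const List& config,
                              const arma::mat& H0, const arma::umat& allow) {
  TFConfig c = parse_cfg(config);
  TFParams P = parse_params(params, c);
  if ((int)H0.n_cols != c.d) stop("H0 has %d columns, expected d = %d", (int)H0.n_cols, c.d);
  if (allow.n_rows != H0.n_rows || allow.n_cols != H0.n_rows)
    stop("mask must be q x q with q = nrow(H0)");
  mat H = H0;
  LCache cc;
  for (int l = 0; l < c.L; ++l) H = layer_fwd(H, P.layers[l], c, allow, 0.0, cc);
  return H;
}

// Teacher-forced mean per-pixel NLL and gradients over a minibatch.
// X: B x r matrix of 0-based intensities; nidx: 0-based rows of Ws.
// [[Rcpp::export]]
List cpp_tf_batch_grad(const List& params, const List& config,
                       const IntegerMatrix& X, const IntegerVector& nidx,
                       double dropout) {
  RNGScope scope;
  TFConfig c = parse_cfg(config);
  TFParams P = parse_params(params, c);
  const int B = X.nrow(), r = X.ncol();
  if (r != c.r) stop("images have %d pixels, model expects r = %d", r, c.r);
  if (nidx.size() != B) stop("nidx length must equal nrow(X)");

  TFParams G;
  G.Wx = arma::zeros<mat>(P.Wx.n_rows, P.Wx.n_cols);
  G.Ws = arma::zeros<mat>(P.Ws.n_rows, P.Ws.n_cols);
  G.WE = arma::zeros<mat>(P.WE.n_rows, P.WE.n_cols);
  G.headW = arma::zeros<mat>(P.headW.n_rows, P.headW.n_cols);
  G.headb = arma::zeros<rowvec>(P.headb.n_elem);
  for (int l = 0; l < c.L; ++l) G.layers.push_back(zero_layer_like(P.layers[l]));

  umat allow = causal_allow(r);
  std::vector<LCache> caches(c.L);
  double total = 0.0;
  const double invN = 1.0 / ((double)B * (double)r);
  std::vector<int> xb(r);

  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < r; ++t) {
      xb[t] = X(b, t);
      if (xb[t] < 0 || xb[t] >= c.p) stop("pixel intensity out of range [0, p)");
    }
    int ni = nidx[b];
    if (ni < 0 || ni >= (int)P.Ws.n_rows) stop("numerosity index out of range of Ws");
    mat H = build_h0(P, xb.data(), r, ni);
    for (int l = 0; l < c.L; ++l) H = layer_fwd(H, P.layers[l], c, allow, dropout, caches[l]);
    mat logits = H * P.headW;
    logits.each_row() += P.headb;
    // rows of dlogits = (softmax - onehot) * invN
    mat dlogits(r, c.p);
    for (int t = 0; t < r; ++t) {
      rowvec lg = logits.row(t);
      double mx = lg.max();
      rowvec e = arma::exp(lg - mx);
      double Z = arma::accu(e);
      total += (mx + std::log(Z) - lg(xb[t]));
      dlogits.row(t) = (e / Z) * invN;
      dlogits(t, xb[t]) -= invN;
    }
    G.headW += H.t() * dlogits;
    G.headb += arma::sum(dlogits, 0);
    mat dH = dlogits * P.headW.t();
    for (int l = c.L - 1; l >= 0; --l) dH = layer_bwd(dH, P.layers[l], c, caches[l], G.layers[l]);
    // embedding grads
    G.Ws.row(ni) += dH.row(0);
    G.WE.row(0) += dH.row(0);
    for (int t = 1; t < r; ++t) {
      G.Wx.row(xb[t - 1]) += dH.row(t);
      G.WE.row(t) += dH.row(t);
    }
  }

  List lgl(c.L);
  for (int l = 0; l < c.L; ++l) {
    const TFLayer& g = G.layers[l];
    lgl[l] = List::create(
      _["Wq"] = g.Wq, _["bq"] = g.bq, _["Wk"] = g.Wk, _["bk"] = g.bk,
      _["Wv"] = g.Wv, _["bv"] = g.bv, _["Wo"] = g.Wo, _["bo"] = g.bo,
      _["ln1_g"] = g.ln1g, _["ln1_b"] = g.ln1b,
      _["W1"] = g.W1, _["b1"] = g.b1, _["W2"] = g.W2, _["b2"] = g.b2,
      _["ln2_g"] = g.ln2g, _["ln2_b"] = g.ln2b);
  }
  List grads = List::create(
    _["Wx"] = G.Wx, _["Ws"] = G.Ws, _["WE"] = G.WE,
    _["layers"] = lgl, _["head_W"] = G.headW, _["head_b"] = G.headb);
  return List::create(_["loss"] = total * invN, _["grads"] = grads);
}

// Mean per-pixel NLL (dropout off), no gradients.
// [[Rcpp::export]]
double cpp_tf_eval_nll(const List& params, const List& config,
                       const IntegerMatrix& X, const IntegerVector& nidx) {
  TFConfig c = parse_cfg(config);
  TFParams P = parse_params(params, c);
  const int B = X.nrow(), r = X.ncol();
  if (r != c.r) stop("images have %d pixels, model expects r = %d", r, c.r);
  umat allow = causal_allow(r);
  LCache cc;
  double total = 0.0;
  std::vector<int> xb(r);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < r; ++t) xb[t] = X(b, t);
    mat H = build_h0(P, xb.data(), r, nidx[b]);
    for (int l = 0; l < c.L; ++l) H = layer_fwd(H, P.layers[l], c, allow, 0.0, cc);
    mat logits = H * P.headW;
    logits.each_row() += P.headb;
    for (int t = 0; t < r; ++t) {
      rowvec lg = logits.row(t);
      double mx = lg.max();
      total += mx + std::log(arma::accu(arma::exp(lg - mx))) - lg(xb[t]);
    }
  }
  return total / ((double)B * (double)r);
}

// --- incremental sampling with a key/value cache ----------------------------

// One forward step for the newest position given per-layer K/V caches holding
// the first `t` positions. h: 1 x d embedding of the new position.
static rowvec kv_step(rowvec h, const TFParams& P, const TFConfig& c,
                      std::vector<mat>& Kc, std::vector<mat>& Vc, int t) {
  const double scale = 1.0 / std::sqrt((double)c.dk);
  for (int l = 0; l < c.L; ++l) {
    const TFLayer& ly = P.layers[l];
    rowvec qv = h * ly.Wq + ly.bq;
    Kc[l].row(t) = h * ly.Wk + ly.bk;
    Vc[l].row(t) = h * ly.Wv + ly.bv;
    rowvec Oc(c.d);
    for (int hh = 0; hh < c.nheads; ++hh) {
      arma::span hs(hh * c.dk, (hh + 1) * c.dk - 1);
      rowvec s = qv.cols(hs) * Kc[l].submat(0, hs.a, t, hs.b).t() * scale;
      s -= s.max();
      rowvec e = arma::exp(s);
      e /= arma::accu(e);
      Oc.cols(hs) = e * Vc[l].submat(0, hs.a, t, hs.b);
    }
    rowvec O = Oc * ly.Wo + ly.bo;
    rowvec U1 = h + O;
    double mu = arma::mean(U1);
    rowvec cent = U1 - mu;
    rowvec A = (cent / std::sqrt(arma::mean(arma::square(cent)) + LN_EPS)) % ly.ln1g + ly.ln1b;
    rowvec Z1 = A * ly.W1 + ly.b1;
    Z1 %= arma::conv_to<rowvec>::from(Z1 > 0);
    rowvec F = Z1 * ly.W2 + ly.b2;
    rowvec U2 = A + F;
    mu = arma::mean(U2);
    cent = U2 - mu;
    h = (cent / std::sqrt(arma::mean(arma::square(cent)) + LN_EPS)) % ly.ln2g + ly.ln2b;
  }
  return h;
}

// Ancestral sampling of `count` images of `nsteps` pixels each from a single
// conditioning seed. Uses R's RNG: one uniform draw per pixel (inverse CDF in
// intensity order), so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_tf_sample(const List& params, const List& config,
                            const arma::rowvec& sos, int count, int nsteps) {
  RNGScope scope;
  TFConfig c = parse_cfg(config);
  TFParams P = parse_params(params, c);
  if ((int)sos.n_elem != c.d) stop("SoS vector length must equal d");
  if (nsteps < 1 || nsteps > c.r) stop("nsteps must be in [1, r]");
  IntegerMatrix out(count, nsteps);
  std::vector<mat> Kc(c.L), Vc(c.L);
  for (int l = 0; l < c.L; ++l) { Kc[l].set_size(nsteps, c.d); Vc[l].set_size(nsteps, c.d); }
  for (int b = 0; b < count; ++b) {
    rowvec h = sos + P.WE.row(0);
    for (int t = 0; t < nsteps; ++t) {
      rowvec top = kv_step(h, P, c, Kc, Vc, t);
      rowvec lg = top * P.headW + P.headb;
      lg -= lg.max();
      rowvec pr = arma::exp(lg);
      pr /= arma::accu(pr);
      double u = unif_rand();
      double cum = 0.0;
      int xi = c.p - 1;
      for (int k = 0; k < c.p; ++k) {
        cum += pr(k);
        if (u < cum) { xi = k; break; }
      }
      out(b, t) = xi;
      if (t + 1 < nsteps) h = P.Wx.row(xi) + P.WE.row(t + 1);
    }
  }
  return out;
}
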