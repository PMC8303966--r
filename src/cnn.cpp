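// Compact convolutional classifier used as the numerosity counter for the
// non-uniform dot family. Blocks of 3x3 (pad 1) convolution + per-channel
// batch normalization + optional identity skip + ReLU, optional 2x2 max
// pooling; global average pooling and a linear softmax head. Trained with
// cross-entropy; batch statistics are used during training and running
// statistics at inference, as in standard residual networks.
//
// Activations are stored as C x (B*H*W) matrices, column index b*H*W + y*W + x
// (row-major rasters, matching the stimulus flattening used elsewhere).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;

static const double BN_EPS = 1e-5;

struct CNNConfig {
  std::vector<int> channels;
  std::vector<bool> pool, skip;
  int n_classes, H, W;
  bool avg_pool;
};

static CNNConfig parse_cnn_cfg(const List& cfg) {
  CNNConfig c;
  IntegerVector ch = cfg["channels"];
  LogicalVector po = cfg["pool"], sk = cfg["skip"];
  if (ch.size() != po.size() || ch.size() != sk.size())
    stop("channels, pool and skip must have equal length");
  for (int i = 0; i < ch.size(); ++i) {
    c.channels.push_back(ch[i]);
    c.pool.push_back(po[i]);
    c.skip.push_back(sk[i]);
  }
  c.n_classes = as<int>(cfg["n_classes"]);
  c.H = as<int>(cfg["height"]);
  c.W = as<int>(cfg["width"]);
  c.avg_pool = cfg.containsElementNamed("avg_pool") ?
    as<bool>(cfg["avg_pool"]) : false;
  return c;
}

static mat im2col3(const mat& A, int B, int H, int W) {
  const int C = A.n_rows, HW = H * W;
  mat cols(C * 9, (arma::uword)B * HW, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        const arma::uword j = off + (arma::uword)y * W + x;
        for (int ky = -1; ky <= 1; ++ky) {
          const int yy = y + ky;
          if (yy < 0 || yy >= H) continue;
          for (int kx = -1; kx <= 1; ++kx) {
            const int xx = x + kx;
            if (xx < 0 || xx >= W) continue;
            const arma::uword src = off + (arma::uword)yy * W + xx;
            const int kidx = (ky + 1) * 3 + (kx + 1);
            for (int cch = 0; cch < C; ++cch)
              cols(cch * 9 + kidx, j) = A(cch, src);
          }
        }
      }
    }
  }
  return cols;
}

static mat col2im3(const mat& dcols, int B, int H, int W, int C) {
  const int HW = H * W;
  mat dA(C, (arma::uword)B * HW, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        const arma::uword j = off + (arma::uword)y * W + x;
        for (int ky = -1; ky <= 1; ++ky) {
          const int yy = y + ky;
          if (yy < 0 || yy >= H) continue;
          for (int kx = -1; kx <= 1; ++kx) {
            const int xx = x + kx;
            if (xx < 0 || xx >= W) continue;
            const arma::uword src = off + (arma::uword)yy * W + xx;
            const int kidx = (ky + 1) * 3 + (kx + 1);
            for (int cch = 0; cch < C; ++cch)
              dA(cch, src) += dcols(cch * 9 + kidx, j);
          }
        }
      }
    }
  }
  return dA;
}

// 2x2 average pooling (sum-preserving up to the 1/4 factor): keeps the
// total activation mass that a count readout depends on.
static mat avgpool_fwd(const mat& A, int B, int H, int W) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  mat out(C, (arma::uword)B * HWo);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW, offo = (arma::uword)b * HWo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const arma::uword jo = offo + (arma::uword)y * Wo + x;
        const arma::uword j00 = off + (arma::uword)(2 * y) * W + 2 * x;
        for (int cch = 0; cch < C; ++cch)
          out(cch, jo) = 0.25 * (A(cch, j00) + A(cch, j00 + 1) +
                                 A(cch, j00 + W) + A(cch, j00 + W + 1));
      }
    }
  }
  return out;
}

static mat avgpool_bwd(const mat& dO, int B, int H, int W) {
  const int C = dO.n_rows, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  mat dA(C, (arma::uword)B * HW, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW, offo = (arma::uword)b * HWo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const arma::uword jo = offo + (arma::uword)y * Wo + x;
        const arma::uword j00 = off + (arma::uword)(2 * y) * W + 2 * x;
        for (int cch = 0; cch < C; ++cch) {
          double v = 0.25 * dO(cch, jo);
          dA(cch, j00) += v; dA(cch, j00 + 1) += v;
          dA(cch, j00 + W) += v; dA(cch, j00 + W + 1) += v;
        }
      }
    }
  }
  return dA;
}

static mat maxpool_fwd(const mat& A, int B, int H, int W, umat& arg) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  mat out(C, (arma::uword)B * HWo);
  arg.set_size(C, (arma::uword)B * HWo);
  for (int b = 0; b < B; ++b) {
    const arma::uword off = (arma::uword)b * HW, offo = (arma::uword)b * HWo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const arma::uword jo = offo + (arma::uword)y * Wo + x;
        const arma::uword j00 = off + (arma::uword)(2 * y) * W + 2 * x;
        const arma::uword idx[4] = {j00, j00 + 1, j00 + W, j00 + W + 1};
        for (int cch = 0; cch < C; ++cch) {
          double best = A(cch, idx[0]);
          arma::uword bi = idx[0];
          for (int k = 1; k < 4; ++k)
            if (A(cch, idx[k]) > best) { best = A(cch, idx[k]); bi = idx[k]; }
          out(cch, jo) = best;
          arg(cch, jo) = bi;
        }
      }
    }
  }
  return out;
}

struct BlockCache {
  mat Ain, cols, Z, Xhat, Zn, R;  // input, im2col, conv out, bn-normalized,
                                  // post-bn (+skip) pre-relu, post-relu
  vec istd;                       // per-channel inverse std (training batch)
  umat poolarg;
  int H, W;                       // spatial size at block input
};

// Forward through all blocks; returns features (B x C_last) after GAP.
// If `train` is true uses batch statistics and fills caches/updated stats;
// otherwise uses the supplied running statistics.
static mat cnn_forward(const mat& X, const CNNConfig& c, const List& params,
                       const List& stats, int B, bool train, double momentum,
                       std::vector<BlockCache>* caches,
                       std::vector<vec>* new_rm, std::vector<vec>* new_rv) {
  List convW = params["conv_W"];
  List bng = params["bn_g"], bnb = params["bn_b"];
  List bnrm = stats["bn_rm"], bnrv = stats["bn_rv"];
  mat A = X;  // 1 x B*HW on entry (in_channels = 1)
  int H = c.H, W = c.W;
  for (size_t l = 0; l < c.channels.size(); ++l) {
    BlockCache cc;
    cc.H = H; cc.W = W;
    cc.Ain = A;
    cc.cols = im2col3(A, B, H, W);
    mat Wc = as<mat>(convW[l]);
    mat Z = Wc * cc.cols;   // no conv bias: batch norm absorbs any offset
    cc.Z = Z;
    // batch norm per channel over batch x spatial
    vec g = as<vec>(bng[l]), be = as<vec>(bnb[l]);
    mat Xhat(Z.n_rows, Z.n_cols);
    vec istd(Z.n_rows);
    if (train) {
      vec mu = arma::mean(Z, 1);
      mat cent = Z.each_col() - mu;
      vec va = arma::mean(arma::square(cent), 1);
      istd = 1.0 / arma::sqrt(va + BN_EPS);
      Xhat = cent.each_col() % istd;
      if (new_rm) {
        vec rm = as<vec>(bnrm[l]), rv = as<vec>(bnrv[l]);
        (*new_rm)[l] = (1 - momentum) * rm + momentum * mu;
        (*new_rv)[l] = (1 - momentum) * rv + momentum * va;
      }
    } else {
      vec rm = as<vec>(bnrm[l]), rv = as<vec>(bnrv[l]);
      istd = 1.0 / arma::sqrt(rv + BN_EPS);
      Xhat = (Z.each_col() - rm).each_col() % istd;
    }
    cc.Xhat = Xhat;
    cc.istd = istd;
    mat Zn = (Xhat.each_col() % g).each_col() + be;
    if (c.skip[l]) {
      if (Zn.n_rows != A.n_rows)
        stop("skip connection requires matching channel counts");
      Zn += A;
    }
    cc.Zn = Zn;
    mat R = Zn % arma::conv_to<mat>::from(Zn > 0);
    cc.R = R;
    if (c.pool[l]) {
      A = c.avg_pool ? avgpool_fwd(R, B, H, W)
                     : maxpool_fwd(R, B, H, W, cc.poolarg);
      H /= 2; W /= 2;
    } else {
      A = R;
    }
    if (caches) (*caches).push_back(std::move(cc));
  }
  // global average pool -> B x C_last
  const int HW = H * W, C = A.n_rows;
  mat feat(B, C);
  for (int b = 0; b < B; ++b)
    feat.row(b) = arma::mean(A.cols((arma::uword)b * HW,
                                    (arma::uword)(b + 1) * HW - 1), 1).t();
  return feat;
}

static mat reshape_batch(const arma::mat& Ximg) {
  mat X = Ximg.t();
  X.reshape(1, Ximg.n_rows * Ximg.n_cols);
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_cnn_probs(const List& params, const List& stats,
                        const List& config, const arma::mat& Ximg) {
  CNNConfig c = parse_cnn_cfg(config);
  const int B = Ximg.n_rows;
  if ((int)Ximg.n_cols != c.H * c.W) stop("images have wrong pixel count");
  mat X = reshape_batch(Ximg);
  mat feat = cnn_forward(X, c, params, stats, B, false, 0.0, nullptr,
                         nullptr, nullptr);
  mat logits = feat * as<mat>(params["fc_W"]);
  logits.each_row() += as<rowvec>(params["fc_b"]);
  for (int b = 0; b < B; ++b) {
    rowvec lg = logits.row(b);
    lg -= lg.max();
    rowvec e = arma::exp(lg);
    logits.row(b) = e / arma::accu(e);
  }
  return logits;
}

// [[Rcpp::export]]
List cpp_cnn_grad(const List& params, const List& stats, const List& config,
                  const arma::mat& Ximg, const IntegerVector& y,
                  double momentum) {
  CNNConfig c = parse_cnn_cfg(config);
  const int B = Ximg.n_rows;
  if ((int)Ximg.n_cols != c.H * c.W) stop("images have wrong pixel count");
  if (y.size() != B) stop("labels must match batch size");
  const int nb = c.channels.size();
  mat X = reshape_batch(Ximg);
  std::vector<BlockCache> caches;
  std::vector<vec> new_rm(nb), new_rv(nb);
  mat feat = cnn_forward(X, c, params, stats, B, true, momentum, &caches,
                         &new_rm, &new_rv);
  mat fcW = as<mat>(params["fc_W"]);
  rowvec fcb = as<rowvec>(params["fc_b"]);
  mat logits = feat * fcW;
  logits.each_row() += fcb;

  double loss = 0.0;
  mat dlogits(B, c.n_classes);
  for (int b = 0; b < B; ++b) {
    if (y[b] < 0 || y[b] >= c.n_classes) stop("label out of range");
    rowvec lg = logits.row(b);
    double mx = lg.max();
    rowvec e = arma::exp(lg - mx);
    double Z = arma::accu(e);
    loss += mx + std::log(Z) - lg(y[b]);
    dlogits.row(b) = e / Z / B;
    dlogits(b, y[b]) -= 1.0 / B;
  }
  loss /= B;

  mat dfcW = feat.t() * dlogits;
  rowvec dfcb = arma::sum(dlogits, 0);
  mat dfeat = dlogits * fcW.t();

  // backward through GAP into the last activation map
  int H = c.H, W = c.W;
  for (int l = 0; l < nb; ++l) if (c.pool[l]) { H /= 2; W /= 2; }
  const int HWl = H * W, Cl = c.channels[nb - 1];
  mat dA(Cl, (arma::uword)B * HWl);
  for (int b = 0; b < B; ++b)
    for (int cch = 0; cch < Cl; ++cch)
      dA.submat(cch, (arma::uword)b * HWl, cch,
                (arma::uword)(b + 1) * HWl - 1).fill(dfeat(b, cch) / HWl);

  List convW = params["conv_W"];
  List bng = params["bn_g"];
  List dconvW(nb), dbng(nb), dbnb(nb);
  for (int l = nb - 1; l >= 0; --l) {
    const BlockCache& cc = caches[l];
    mat dR;
    if (c.pool[l]) {
      if (c.avg_pool) {
        dR = avgpool_bwd(dA, B, cc.H, cc.W);
      } else {
        dR = arma::zeros<mat>(cc.R.n_rows, cc.R.n_cols);
        for (arma::uword j = 0; j < dA.n_cols; ++j)
          for (arma::uword cch = 0; cch < dA.n_rows; ++cch)
            dR(cch, cc.poolarg(cch, j)) += dA(cch, j);
      }
    } else {
      dR = dA;
    }
    mat dZn = dR % arma::conv_to<mat>::from(cc.Zn > 0);
    mat dSkip;
    if (c.skip[l]) dSkip = dZn;  // identity branch gradient
    // batch-norm backward (batch statistics)
    vec g = as<vec>(bng[l]);
    dbng[l] = vec(arma::sum(dZn % cc.Xhat, 1));
    dbnb[l] = vec(arma::sum(dZn, 1));
    mat dxh = dZn.each_col() % g;
    vec m1 = arma::mean(dxh, 1);
    vec m2 = arma::mean(dxh % cc.Xhat, 1);
    mat dZ = ((dxh.each_col() - m1) - (cc.Xhat.each_col() % m2));
    dZ.each_col() %= cc.istd;
    mat Wc = as<mat>(convW[l]);
    dconvW[l] = mat(dZ * cc.cols.t());
    mat dcols = Wc.t() * dZ;
    dA = col2im3(dcols, B, cc.H, cc.W, cc.Ain.n_rows);
    if (c.skip[l]) dA += dSkip;
  }

  List grads = List::create(
    _["conv_W"] = dconvW, _["bn_g"] = dbng, _["bn_b"] = dbnb,
    _["fc_W"] = dfcW, _["fc_b"] = dfcb);
  List rm(nb), rv(nb);
  for (int l = 0; l < nb; ++l) { rm[l] = new_rm[l]; rv[l] = new_rv[l]; }
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["stats"] = List::create(_["bn_rm"] = rm,
                                                _["bn_rv"] = rv));
}

// Forward-only pass in training mode that refreshes the BN running
// statistics for the current weights ("precise BN" calibration).
// [[Rcpp::export]]
List cpp_cnn_calibrate(const List& params, const List& stats,
                       const List& config, const arma::mat& Ximg,
                       double momentum) {
  CNNConfig c = parse_cnn_cfg(config);
  const int B = Ximg.n_rows;
  if ((int)Ximg.n_cols != c.H * c.W) stop("images have wrong pixel count");
  const int nb = c.channels.size();
  mat X = reshape_batch(Ximg);
  std::vector<vec> new_rm(nb), new_rv(nb);
  cnn_forward(X, c, params, stats, B, true, momentum, nullptr,
              &new_rm, &new_rv);
  List rm(nb), rv(nb);
  for (int l = 0; l < nb; ++l) { rm[l] = new_rm[l]; rv[l] = new_rv[l]; }
  return List::create(_["bn_rm"] = rm, _["bn_rv"] = rv);
}
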