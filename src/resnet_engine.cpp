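// Fused single-precision training engine for the ResNet-18 classifier.
//
// The R code owns the network as a nested list of double-precision
// parameter matrices (see R/nnmodel.R for the reference layer-by-layer
// implementation; the two paths compute the same forward/backward maps and
// are cross-checked in the test suite). This engine runs one whole
// minibatch — forward pass, softmax cross-entropy, backward pass and the
// SGD-with-momentum update — in 32-bit arithmetic with BLAS sgemm, writing
// the updated parameters, velocities and batch-norm running statistics
// back into the R structures in place.
//
// Activation layout matches the R side: a matrix with N*H*W rows (image
// slowest, then column, then row) and C columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static fmat to_f(const NumericMatrix& m) {
  fmat f(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = f.memptr();
  for (R_xlen_t i = 0; i < m.size(); ++i) dst[i] = (float)src[i];
  return f;
}

static fvec vec_f(const NumericVector& v) {
  fvec f(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) f[i] = (float)v[i];
  return f;
}

static void im2col_f(const fmat& x, int H, int W, int N, int kh, int kw,
                     int stride, int pad, fmat& col) {
  const int C = x.n_cols;
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  col.zeros((arma::uword)N * OH * OW, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    for (int ki = 0; ki < kw; ++ki) {
      for (int kj = 0; kj < kh; ++kj) {
        float* cc = col.colptr((arma::uword)c * kh * kw + ki * kh + kj);
        for (int n = 0; n < N; ++n) {
          const size_t xoff = (size_t)n * H * W;
          const size_t coff = (size_t)n * OH * OW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride + ki - pad;
            if (iw < 0 || iw >= W) continue;
            const float* xsrc = xc + xoff + (size_t)iw * H;
            float* cdst = cc + coff + (size_t)ow * OH;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride + kj - pad;
              if (ih >= 0 && ih < H) cdst[oh] = xsrc[ih];
            }
          }
        }
      }
    }
  }
}

static void col2im_f(const fmat& col, int H, int W, int C, int N, int kh,
                     int kw, int stride, int pad, fmat& x) {
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  x.zeros((arma::uword)N * H * W, C);
  for (int c = 0; c < C; ++c) {
    float* xc = x.colptr(c);
    for (int ki = 0; ki < kw; ++ki) {
      for (int kj = 0; kj < kh; ++kj) {
        const float* cc = col.colptr((arma::uword)c * kh * kw + ki * kh + kj);
        for (int n = 0; n < N; ++n) {
          const size_t xoff = (size_t)n * H * W;
          const size_t coff = (size_t)n * OH * OW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride + ki - pad;
            if (iw < 0 || iw >= W) continue;
            const float* csrc = cc + coff + (size_t)ow * OH;
            float* xdst = xc + xoff + (size_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride + kj - pad;
              if (ih >= 0 && ih < H) xdst[ih] += csrc[oh];
            }
          }
        }
      }
    }
  }
}

// ---- layer wrappers around the R parameter lists -------------------------

struct ConvCache {
  fmat col;      // only kept when training
  int H, W, N, OH, OW;
};

struct Conv {
  List lay;      // the R list: W, kh, kw, stride, pad, cin, cout
  fmat Wf;
  int kh, kw, stride, pad, cin, cout;
  explicit Conv(List l) : lay(l) {
    Wf = to_f(as<NumericMatrix>(l["W"]));
    kh = as<int>(l["kh"]); kw = as<int>(l["kw"]);
    stride = as<int>(l["stride"]); pad = as<int>(l["pad"]);
    cin = as<int>(l["cin"]); cout = as<int>(l["cout"]);
  }
  fmat forward(const fmat& x, int H, int W, int N, bool keep, ConvCache& cc) {
    cc.H = H; cc.W = W; cc.N = N;
    cc.OH = out_dim(H, kh, stride, pad);
    cc.OW = out_dim(W, kw, stride, pad);
    im2col_f(x, H, W, N, kh, kw, stride, pad, cc.col);
    fmat y = cc.col * Wf;
    if (!keep) cc.col.reset();
    return y;
  }
  // returns dx; accumulates dW into gW
  fmat backward(const ConvCache& cc, const fmat& dy, fmat& gW) {
    gW = cc.col.t() * dy;
    fmat dcol = dy * Wf.t();
    fmat dx;
    col2im_f(dcol, cc.H, cc.W, cin, cc.N, kh, kw, stride, pad, dx);
    return dx;
  }
};

struct BNCache {
  fmat xhat;
  fvec inv;
};

struct BN {
  List lay;      // gamma, beta, rmean, rvar, momentum, eps
  fvec gamma, beta;
  explicit BN(List l) : lay(l) {
    gamma = vec_f(as<NumericVector>(l["gamma"]));
    beta = vec_f(as<NumericVector>(l["beta"]));
  }
  fmat forward(const fmat& x, bool training, BNCache& cache) {
    const int C = x.n_cols;
    const double eps = as<double>(lay["eps"]);
    fvec mean(C), inv(C);
    if (training) {
      const double mom = as<double>(lay["momentum"]);
      NumericVector rmean = lay["rmean"], rvar = lay["rvar"];
      for (int c = 0; c < C; ++c) {
        const double mu = arma::mean(
          arma::conv_to<arma::vec>::from(x.col(c)));
        double v = 0;
        const float* xc = x.colptr(c);
        for (arma::uword i = 0; i < x.n_rows; ++i) {
          const double d = xc[i] - mu;
          v += d * d;
        }
        v /= x.n_rows;
        mean[c] = (float)mu;
        inv[c] = (float)(1.0 / std::sqrt(v + eps));
        rmean[c] = (1 - mom) * rmean[c] + mom * mu;   // in place
        rvar[c] = (1 - mom) * rvar[c] + mom * v;
      }
    } else {
      NumericVector rmean = lay["rmean"], rvar = lay["rvar"];
      for (int c = 0; c < C; ++c) {
        mean[c] = (float)rmean[c];
        inv[c] = (float)(1.0 / std::sqrt(rvar[c] + eps));
      }
    }
    cache.inv = inv;
    cache.xhat.set_size(arma::size(x));
    fmat y(arma::size(x));
    for (int c = 0; c < C; ++c) {
      const float m = mean[c], s = inv[c], g = gamma[c], b = beta[c];
      const float* xc = x.colptr(c);
      float* hc = cache.xhat.colptr(c);
      float* yc = y.colptr(c);
      for (arma::uword i = 0; i < x.n_rows; ++i) {
        hc[i] = (xc[i] - m) * s;
        yc[i] = hc[i] * g + b;
      }
    }
    return y;
  }
  fmat backward(const BNCache& cache, const fmat& dy, fvec& dgamma,
                fvec& dbeta) {
    const int C = dy.n_cols;
    const arma::uword M = dy.n_rows;
    dgamma.set_size(C); dbeta.set_size(C);
    fmat dx(arma::size(dy));
    for (int c = 0; c < C; ++c) {
      const float* dc = dy.colptr(c);
      const float* hc = cache.xhat.colptr(c);
      double sg = 0, sb = 0;
      for (arma::uword i = 0; i < M; ++i) {
        sg += (double)dc[i] * hc[i];
        sb += dc[i];
      }
      dgamma[c] = (float)sg; dbeta[c] = (float)sb;
      const float g = gamma[c];
      const float t1 = (float)(sb / M) * g;
      const float t2 = (float)(sg / M) * g;
      const float s = cache.inv[c];
      float* oc = dx.colptr(c);
      for (arma::uword i = 0; i < M; ++i)
        oc[i] = (dc[i] * g - t1 - hc[i] * t2) * s;
    }
    return dx;
  }
};

static fmat relu(const fmat& x) { return arma::max(x, fmat(arma::size(x), arma::fill::zeros)); }

// ---- SGD update written back into the R structures -----------------------

static void upd(NumericMatrix theta, NumericMatrix v, const float* g,
                double lr, double mu) {
  double* th = theta.begin();
  double* vv = v.begin();
  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    vv[i] = mu * vv[i] + lr * (double)g[i];
    th[i] -= vv[i];
  }
}

static void upd_vec(NumericVector theta, NumericVector v, const fvec& g,
                    double lr, double mu) {
  for (R_xlen_t i = 0; i < theta.size(); ++i) {
    v[i] = mu * v[i] + lr * (double)g[i];
    theta[i] -= v[i];
  }
}

// ---- block forward/backward ----------------------------------------------

struct BlockCache {
  ConvCache c1, c2, cp;
  BNCache b1, b2, bp;
  fmat r1mask_in;   // pre-relu of inner activation (we store the relu output)
  fmat r1;          // relu output (needed as conv2 input grad mask source)
  fmat x_in;        // kept only if needed? not kept; proj uses col cache
  bool has_proj;
};

struct Block {
  Conv conv1, conv2;
  BN bn1, bn2;
  bool has_proj;
  Conv* proj_conv;
  BN* proj_bn;
  List lay;
  explicit Block(List l)
    : conv1(as<List>(l["conv1"])), conv2(as<List>(l["conv2"])),
      bn1(as<List>(l["bn1"])), bn2(as<List>(l["bn2"])), lay(l) {
    has_proj = l.containsElementNamed("proj_conv") &&
      !Rf_isNull(l["proj_conv"]);
    proj_conv = has_proj ? new Conv(as<List>(l["proj_conv"])) : NULL;
    proj_bn = has_proj ? new BN(as<List>(l["proj_bn"])) : NULL;
  }
  ~Block() { delete proj_conv; delete proj_bn; }

  // y = x + f(x); the surrounding network applies the inter-block ReLU
  fmat forward(const fmat& x, int H, int W, int N, bool training, bool keep,
               BlockCache& bc, int& OH, int& OW) {
    bc.has_proj = has_proj;
    fmat h = conv1.forward(x, H, W, N, keep, bc.c1);
    h = bn1.forward(h, training, bc.b1);
    if (!training && !keep) { bc.b1.xhat.reset(); }
    h = relu(h);
    if (keep) bc.r1 = h;
    OH = bc.c1.OH; OW = bc.c1.OW;
    fmat y = conv2.forward(h, OH, OW, N, keep, bc.c2);
    y = bn2.forward(y, training, bc.b2);
    if (!training && !keep) { bc.b2.xhat.reset(); }
    if (has_proj) {
      fmat p = proj_conv->forward(x, H, W, N, keep, bc.cp);
      p = proj_bn->forward(p, training, bc.bp);
      if (!training && !keep) { bc.bp.xhat.reset(); }
      y += p;
    } else {
      y += x;
    }
    return y;
  }

  // dy -> dx, updating all block parameters in place
  fmat backward(BlockCache& bc, const fmat& dy, double lr, double mu,
                List vel) {
    fvec dg, db;
    fmat gW;
    fmat dh = bn2.backward(bc.b2, dy, dg, db);
    upd_vec(as<List>(lay["bn2"])["gamma"], as<List>(vel["bn2"])["gamma"],
            dg, lr, mu);
    upd_vec(as<List>(lay["bn2"])["beta"], as<List>(vel["bn2"])["beta"],
            db, lr, mu);
    fmat dr1 = conv2.backward(bc.c2, dh, gW);
    upd(as<List>(lay["conv2"])["W"], as<List>(vel["conv2"])["W"],
        gW.memptr(), lr, mu);
    // relu mask from the stored relu output
    dr1 %= arma::conv_to<fmat>::from(bc.r1 > 0);
    fmat db1 = bn1.backward(bc.b1, dr1, dg, db);
    upd_vec(as<List>(lay["bn1"])["gamma"], as<List>(vel["bn1"])["gamma"],
            dg, lr, mu);
    upd_vec(as<List>(lay["bn1"])["beta"], as<List>(vel["bn1"])["beta"],
            db, lr, mu);
    fmat dx = conv1.backward(bc.c1, db1, gW);
    upd(as<List>(lay["conv1"])["W"], as<List>(vel["conv1"])["W"],
        gW.memptr(), lr, mu);
    if (has_proj) {
      fmat dp = proj_bn->backward(bc.bp, dy, dg, db);
      upd_vec(as<List>(lay["proj_bn"])["gamma"],
              as<List>(vel["proj_bn"])["gamma"], dg, lr, mu);
      upd_vec(as<List>(lay["proj_bn"])["beta"],
              as<List>(vel["proj_bn"])["beta"], db, lr, mu);
      fmat dxp = proj_conv->backward(bc.cp, dp, gW);
      upd(as<List>(lay["proj_conv"])["W"], as<List>(vel["proj_conv"])["W"],
          gW.memptr(), lr, mu);
      dx += dxp;
    } else {
      dx += dy;
    }
    return dx;
  }
};

// ---- max pooling ---------------------------------------------------------

static fmat maxpool_f(const fmat& x, int H, int W, int N, int k, int stride,
                      int pad, arma::umat& argmax, int& OH, int& OW) {
  const int C = x.n_cols;
  OH = out_dim(H, k, stride, pad);
  OW = out_dim(W, k, stride, pad);
  fmat y((arma::uword)N * OH * OW, C);
  argmax.set_size((arma::uword)N * OH * OW, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    float* yc = y.colptr(c);
    arma::uword* ac = argmax.colptr(c);
    for (int n = 0; n < N; ++n) {
      const size_t xoff = (size_t)n * H * W;
      const size_t yoff = (size_t)n * OH * OW;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          float best = -std::numeric_limits<float>::infinity();
          size_t besti = 0;
          for (int ki = 0; ki < k; ++ki) {
            const int iw = ow * stride + ki - pad;
            if (iw < 0 || iw >= W) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int ih = oh * stride + kj - pad;
              if (ih < 0 || ih >= H) continue;
              const size_t idx = xoff + (size_t)iw * H + ih;
              if (xc[idx] > best) { best = xc[idx]; besti = idx; }
            }
          }
          yc[yoff + (size_t)ow * OH + oh] = best;
          ac[yoff + (size_t)ow * OH + oh] = besti;
        }
      }
    }
  }
  return y;
}

// ---- whole-network passes ------------------------------------------------

struct NetRefs {
  Conv stem_conv;
  BN stem_bn;
  std::vector<std::vector<Block*> > stages;
  fmat fcW;
  fvec fcb;
  List net;
  explicit NetRefs(List n)
    : stem_conv(as<List>(as<List>(n["stem"])["conv"])),
      stem_bn(as<List>(as<List>(n["stem"])["bn"])), net(n) {
    List sts = n["stages"];
    stages.resize(sts.size());
    for (int s = 0; s < sts.size(); ++s) {
      List st = sts[s];
      for (int b = 0; b < st.size(); ++b)
        stages[s].push_back(new Block(as<List>(st[b])));
    }
    List fc = n["fc"];
    fcW = to_f(as<NumericMatrix>(fc["W"]));
    fcb = vec_f(as<NumericVector>(fc["b"]));
  }
  ~NetRefs() {
    for (size_t s = 0; s < stages.size(); ++s)
      for (size_t b = 0; b < stages[s].size(); ++b) delete stages[s][b];
  }
};

struct FwdState {
  ConvCache stem_c;
  BNCache stem_b;
  fmat stem_r;
  arma::umat pool_arg;
  int pool_in_rows, pool_H, pool_W;
  std::vector<std::vector<BlockCache> > bcs;
  std::vector<std::vector<fmat> > relu_out;
  fmat pooled;
  int H, W, N, HW_last;
};

static fmat forward_all(NetRefs& nr, const fmat& x0, int H, int W, int N,
                        bool training, bool keep, FwdState& fs) {
  fs.H = H; fs.W = W; fs.N = N;
  fmat h = nr.stem_conv.forward(x0, H, W, N, keep, fs.stem_c);
  h = nr.stem_bn.forward(h, training, fs.stem_b);
  if (!training && !keep) fs.stem_b.xhat.reset();
  h = relu(h);
  if (keep) fs.stem_r = h;
  int curH = fs.stem_c.OH, curW = fs.stem_c.OW;
  fs.pool_in_rows = h.n_rows; fs.pool_H = curH; fs.pool_W = curW;
  int OH, OW;
  h = maxpool_f(h, curH, curW, N, 3, 2, 1, fs.pool_arg, OH, OW);
  if (!keep) fs.pool_arg.reset();
  curH = OH; curW = OW;
  fs.bcs.resize(nr.stages.size());
  fs.relu_out.resize(nr.stages.size());
  for (size_t s = 0; s < nr.stages.size(); ++s) {
    fs.bcs[s].resize(nr.stages[s].size());
    fs.relu_out[s].resize(nr.stages[s].size());
    for (size_t b = 0; b < nr.stages[s].size(); ++b) {
      fmat y = nr.stages[s][b]->forward(h, curH, curW, N, training, keep,
                                        fs.bcs[s][b], OH, OW);
      curH = OH; curW = OW;
      h = relu(y);
      if (keep) fs.relu_out[s][b] = h;
    }
  }
  const int HW = curH * curW;
  fs.HW_last = HW;
  fmat pooled(N, h.n_cols);
  for (arma::uword c = 0; c < h.n_cols; ++c) {
    const float* hc = h.colptr(c);
    for (int n = 0; n < N; ++n) {
      double acc = 0;
      const float* p = hc + (size_t)n * HW;
      for (int i = 0; i < HW; ++i) acc += p[i];
      pooled(n, c) = (float)(acc / HW);
    }
  }
  if (keep) fs.pooled = pooled;
  fmat scores = pooled * nr.fcW;
  scores.each_row() += nr.fcb.t();
  return scores;
}

// [[Rcpp::export]]
NumericMatrix cpp_net_eval(List net, NumericMatrix x, int H, int W, int N) {
  NetRefs nr(net);
  FwdState fs;
  fmat scores = forward_all(nr, to_f(x), H, W, N, false, false, fs);
  NumericMatrix out(scores.n_rows, scores.n_cols);
  for (arma::uword j = 0; j < scores.n_cols; ++j)
    for (arma::uword i = 0; i < scores.n_rows; ++i)
      out(i, j) = scores(i, j);
  return out;
}

// One training step on one minibatch: forward (training-mode batch norm,
// running stats updated in place), softmax cross-entropy, backward, and
// in-place SGD-with-momentum update of every parameter. Returns the batch
// loss and the (pre-update) predictions.
// [[Rcpp::export]]
List cpp_train_batch(List net, List vel, NumericMatrix x,
                     IntegerVector labels, int H, int W, int N,
                     double lr, double momentum) {
  NetRefs nr(net);
  FwdState fs;
  fmat scores = forward_all(nr, to_f(x), H, W, N, true, true, fs);
  const int K = scores.n_cols;
  // softmax cross-entropy in double for the reduction
  fmat d(arma::size(scores));
  double loss = 0;
  IntegerVector preds(N);
  for (int n = 0; n < N; ++n) {
    double m = scores(n, 0);
    int am = 0;
    for (int k = 1; k < K; ++k)
      if (scores(n, k) > m) { m = scores(n, k); am = k; }
    preds[n] = am;
    double z = 0;
    for (int k = 0; k < K; ++k) z += std::exp((double)scores(n, k) - m);
    for (int k = 0; k < K; ++k) {
      const double p = std::exp((double)scores(n, k) - m) / z;
      d(n, k) = (float)(p - (labels[n] == k ? 1.0 : 0.0)) / N;
    }
    const double pl =
      std::exp((double)scores(n, labels[n]) - m) / z;
    loss -= std::log(std::max(pl, 1e-12));
  }
  loss /= N;
  if (!std::isfinite(loss)) stop("non-finite training loss");
  // head backward + update
  List fc = net["fc"], fcv = vel["fc"];
  fmat gW = fs.pooled.t() * d;
  fvec gb(K);
  for (int k = 0; k < K; ++k) gb[k] = arma::accu(d.col(k));
  fmat dpooled = d * nr.fcW.t();
  upd(as<NumericMatrix>(fc["W"]), as<NumericMatrix>(fcv["W"]), gW.memptr(),
      lr, momentum);
  upd_vec(as<NumericVector>(fc["b"]), as<NumericVector>(fcv["b"]), gb,
          lr, momentum);
  // broadcast GAP gradient
  const int HW = fs.HW_last;
  fmat dh((arma::uword)N * HW, dpooled.n_cols);
  for (arma::uword c = 0; c < dpooled.n_cols; ++c) {
    float* dc = dh.colptr(c);
    for (int n = 0; n < N; ++n) {
      const float val = dpooled(n, c) / HW;
      float* p = dc + (size_t)n * HW;
      for (int i = 0; i < HW; ++i) p[i] = val;
    }
  }
  // stages in reverse
  List sts = net["stages"], stsv = vel["stages"];
  for (int s = (int)nr.stages.size() - 1; s >= 0; --s) {
    List stv = stsv[s];
    for (int b = (int)nr.stages[s].size() - 1; b >= 0; --b) {
      dh %= arma::conv_to<fmat>::from(fs.relu_out[s][b] > 0);
      dh = nr.stages[s][b]->backward(fs.bcs[s][b], dh, lr, momentum,
                                     as<List>(stv[b]));
    }
  }
  // stem
  {
    fmat dpool((arma::uword)fs.pool_in_rows, dh.n_cols,
               arma::fill::zeros);
    for (arma::uword c = 0; c < dh.n_cols; ++c) {
      const float* sc = dh.colptr(c);
      const arma::uword* ac = fs.pool_arg.colptr(c);
      float* oc = dpool.colptr(c);
      for (arma::uword r = 0; r < dh.n_rows; ++r) oc[ac[r]] += sc[r];
    }
    dpool %= arma::conv_to<fmat>::from(fs.stem_r > 0);
    fvec dg, db;
    fmat dsc = nr.stem_bn.backward(fs.stem_b, dpool, dg, db);
    List stem = net["stem"], stemv = vel["stem"];
    upd_vec(as<List>(stem["bn"])["gamma"], as<List>(stemv["bn"])["gamma"],
            dg, lr, momentum);
    upd_vec(as<List>(stem["bn"])["beta"], as<List>(stemv["bn"])["beta"],
            db, lr, momentum);
    fmat gWs;
    // dX of the stem is not needed
    gWs = fs.stem_c.col.t() * dsc;
    upd(as<List>(stem["conv"])["W"], as<List>(stemv["conv"])["W"],
        gWs.memptr(), lr, momentum);
  }
  return List::create(_["loss"] = loss, _["preds"] = preds);
}
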