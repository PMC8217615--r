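#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Batched activations are stored as a dense matrix with
//   rows = N * H * W   (image index slowest, then column, then row fastest)
//   cols = C           (channels)
// so element (h, w, c, n) lives at mat(n*H*W + w*H + h, c), 0-based.
// This layout keeps channel-wise ops (batch norm, ReLU) as plain column
// operations in R and turns convolution into one BLAS gemm per layer.

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericMatrix x, int H, int W, int N,
                           int kh, int kw, int stride, int pad) {
  const int C = x.ncol();
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  NumericMatrix col((R_xlen_t)N * OH * OW, (R_xlen_t)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int ki = 0; ki < kw; ++ki) {
      for (int kj = 0; kj < kh; ++kj) {
        const R_xlen_t jcol = (R_xlen_t)c * kh * kw + (R_xlen_t)ki * kh + kj;
        double* cc = &col(0, jcol);
        for (int n = 0; n < N; ++n) {
          const R_xlen_t xoff = (R_xlen_t)n * H * W;
          const R_xlen_t coff = (R_xlen_t)n * OH * OW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride + ki - pad;
            double* cdst = cc + coff + (R_xlen_t)ow * OH;
            if (iw < 0 || iw >= W) continue;  // col stays zero
            const double* xsrc = xc + xoff + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride + kj - pad;
              if (ih >= 0 && ih < H) cdst[oh] = xsrc[ih];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericMatrix col2im_batch(NumericMatrix col, int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad) {
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  NumericMatrix x((R_xlen_t)N * H * W, C);
  for (int c = 0; c < C; ++c) {
    double* xc = &x(0, c);
    for (int ki = 0; ki < kw; ++ki) {
      for (int kj = 0; kj < kh; ++kj) {
        const R_xlen_t jcol = (R_xlen_t)c * kh * kw + (R_xlen_t)ki * kh + kj;
        const double* cc = &col(0, jcol);
        for (int n = 0; n < N; ++n) {
          const R_xlen_t xoff = (R_xlen_t)n * H * W;
          const R_xlen_t coff = (R_xlen_t)n * OH * OW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride + ki - pad;
            if (iw < 0 || iw >= W) continue;
            const double* csrc = cc + coff + (R_xlen_t)ow * OH;
            double* xdst = xc + xoff + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride + kj - pad;
              if (ih >= 0 && ih < H) xdst[ih] += csrc[oh];
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling; returns pooled matrix plus 1-based argmax row indices so the
// backward pass is a pure scatter-add.
// [[Rcpp::export]]
List maxpool_forward(NumericMatrix x, int H, int W, int N,
                     int k, int stride, int pad) {
  const int C = x.ncol();
  const int OH = out_dim(H, k, stride, pad);
  const int OW = out_dim(W, k, stride, pad);
  NumericMatrix y((R_xlen_t)N * OH * OW, C);
  IntegerMatrix arg((R_xlen_t)N * OH * OW, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xoff = (R_xlen_t)n * H * W;
      const R_xlen_t yoff = (R_xlen_t)n * OH * OW;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int ki = 0; ki < k; ++ki) {
            const int iw = ow * stride + ki - pad;
            if (iw < 0 || iw >= W) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int ih = oh * stride + kj - pad;
              if (ih < 0 || ih >= H) continue;
              const R_xlen_t idx = xoff + (R_xlen_t)iw * H + ih;
              if (xc[idx] > best) { best = xc[idx]; besti = idx; }
            }
          }
          y(yoff + (R_xlen_t)ow * OH + oh, c) = best;
          arg(yoff + (R_xlen_t)ow * OH + oh, c) = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool_backward(NumericMatrix dy, IntegerMatrix arg,
                               int in_rows) {
  const int C = dy.ncol();
  NumericMatrix dx(in_rows, C);
  for (int c = 0; c < C; ++c) {
    for (R_xlen_t r = 0; r < dy.nrow(); ++r) {
      dx(arg(r, c) - 1, c) += dy(r, c);
    }
  }
  return dx;
}

// Connected-component labeling of a logical raster (H x W, column-major).
// Components are numbered 1..K in raster-scan (row-by-row) order of their
// first pixel; connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix bin, int connectivity) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!bin(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (bin(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Single-precision summation demos: the compensated recursion carried out in
// genuine float arithmetic, against the naive running sum.
// [[Rcpp::export]]
double sum_float_naive(NumericVector x) {
  float s = 0.0f;
  for (R_xlen_t i = 0; i < x.size(); ++i) s += (float)x[i];
  return (double)s;
}

// [[Rcpp::export]]
double sum_float_kahan(NumericVector x) {
  float s = 0.0f, rres = 0.0f;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const float t = s;
    const float u = (float)x[i] + rres;
    s = t + u;
    rres = u - (s - t);
  }
  return (double)s;
}

// One-pass column-wise kernels used by batch norm (avoids materializing
// sweep() temporaries on N*H*W-row activation matrices).

// xhat = (x - mean[c]) * inv[c]
// [[Rcpp::export]]
NumericMatrix col_standardize(NumericMatrix x, NumericVector mean,
                              NumericVector inv) {
  NumericMatrix y(x.nrow(), x.ncol());
  for (int c = 0; c < x.ncol(); ++c) {
    const double m = mean[c], s = inv[c];
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (R_xlen_t i = 0; i < x.nrow(); ++i) yc[i] = (xc[i] - m) * s;
  }
  return y;
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericMatrix col_affine(NumericMatrix x, NumericVector a, NumericVector b) {
  NumericMatrix y(x.nrow(), x.ncol());
  for (int c = 0; c < x.ncol(); ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (R_xlen_t i = 0; i < x.nrow(); ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}

// dx = (dxhat - t1[c] - xhat * t2[c]) * inv[c]
// [[Rcpp::export]]
NumericMatrix bn_backward_dx(NumericMatrix dxhat, NumericMatrix xhat,
                             NumericVector t1, NumericVector t2,
                             NumericVector inv) {
  NumericMatrix dx(dxhat.nrow(), dxhat.ncol());
  for (int c = 0; c < dxhat.ncol(); ++c) {
    const double a = t1[c], b = t2[c], s = inv[c];
    const double* dc = &dxhat(0, c);
    const double* hc = &xhat(0, c);
    double* oc = &dx(0, c);
    for (R_xlen_t i = 0; i < dxhat.nrow(); ++i)
      oc[i] = (dc[i] - a - hc[i] * b) * s;
  }
  return dx;
}
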