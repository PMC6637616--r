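// Compiled kernels for the convolutional classifier: im2col-based
// convolution, overlapping max-pooling and local response normalization,
// each with its backward pass.  Array layout follows R's column-major
// (H, W, C, N) convention; convolution weights are a (kh*kw*C) x K matrix
// whose row order matches im2col's column order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;


static NumericVector make4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W,
                             int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int stride, int pad, int outH, int outW, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int col = c * kh * kw + dj * kh + di;
        double* Mcol = M.colptr(col);
        for (int ow = 0; ow < outW; ++ow) {
          int iw = ow * stride + dj - pad;
          bool wok = (iw >= 0 && iw < W);
          for (int oh = 0; oh < outH; ++oh) {
            int ih = oh * stride + di - pad;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xc[(size_t)iw * H + ih];
            Mcol[(size_t)ow * outH + oh] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int C, int kh,
                       int kw, int stride, int pad, int outH, int outW,
                       double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int col = c * kh * kw + dj * kh + di;
        const double* Mcol = M.colptr(col);
        for (int ow = 0; ow < outW; ++ow) {
          int iw = ow * stride + dj - pad;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            int ih = oh * stride + di - pad;
            if (ih < 0 || ih >= H) continue;
            xc[(size_t)iw * H + ih] += Mcol[(size_t)ow * outH + oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = "cppConvForward")]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix w,
                               NumericVector bias, int kh, int kw,
                               int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (w.nrow() != kh * kw * C) stop("weight rows must equal kh*kw*C");
  int K = w.ncol();
  int outH = (H + 2 * pad - kh) / stride + 1;
  int outW = (W + 2 * pad - kw) / stride + 1;
  if (outH < 1 || outW < 1) stop("spatial size collapsed below kernel");
  arma::mat Wm(w.begin(), w.nrow(), K, false);
  NumericVector out = make4(outH, outW, K, N);
  arma::mat M(outH * outW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           outH, outW, M);
    arma::mat O = M * Wm;  // (outH*outW) x K
    double* op = out.begin() + (size_t)outH * outW * K * n;
    for (int k = 0; k < K; ++k) {
      const double* Ok = O.colptr(k);
      double bk = bias[k];
      double* od = op + (size_t)outH * outW * k;
      for (int p = 0; p < outH * outW; ++p) od[p] = Ok[p] + bk;
    }
  }
  return out;
}

// [[Rcpp::export(name = "cppConvBackward")]]
List cpp_conv_backward(NumericVector x, NumericMatrix w, NumericVector dout,
                       int kh, int kw, int stride, int pad, bool need_dx) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int K = w.ncol();
  int outH = (H + 2 * pad - kh) / stride + 1;
  int outW = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), w.nrow(), K, false);
  arma::mat dW(w.nrow(), K, arma::fill::zeros);
  arma::vec db(K, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = make4(H, W, C, N);
  arma::mat M(outH * outW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           outH, outW, M);
    arma::mat dO((double*)dout.begin() + (size_t)outH * outW * K * n,
                 outH * outW, K, false);
    dW += M.t() * dO;
    db += arma::sum(dO, 0).t();
    if (need_dx) {
      arma::mat dM = dO * Wm.t();
      col2im_add(dM, H, W, C, kh, kw, stride, pad, outH, outW,
                 dx.begin() + (size_t)H * W * C * n);
    }
  }
  NumericMatrix dWr(w.nrow(), K);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(K);
  std::copy(db.begin(), db.end(), dbr.begin());
  if (need_dx) return List::create(_["dw"] = dWr, _["db"] = dbr,
                                   _["dx"] = dx);
  return List::create(_["dw"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export(name = "cppMaxPoolForward")]]
List cpp_maxpool_forward(NumericVector x, int p, int s) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int outH = (H - p) / s + 1;
  int outW = (W - p) / s + 1;
  if (outH < 1 || outW < 1) stop("spatial size collapsed below pool window");
  NumericVector out = make4(outH, outW, C, N);
  IntegerVector amax(out.size());  // linear index into the (H, W) plane
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < outW; ++ow) {
        for (int oh = 0; oh < outH; ++oh) {
          double best = -1e300; int bidx = 0;
          for (int dj = 0; dj < p; ++dj) {
            int iw = ow * s + dj;
            for (int di = 0; di < p; ++di) {
              int ih = oh * s + di;
              double v = plane[(size_t)iw * H + ih];
              if (v > best) { best = v; bidx = iw * H + ih; }
            }
          }
          out[(size_t)outH * outW * (c + (size_t)C * n) +
              (size_t)ow * outH + oh] = best;
          amax[q++] = bidx;
        }
      }
    }
  }
  // amax is ordered (oh, ow, c, n) to match `out`
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = "cppMaxPoolBackward")]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector amax,
                                   IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector d = dout.attr("dim");
  int outH = d[0], outW = d[1];
  NumericVector dx = make4(H, W, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dplane =
        dout.begin() + (size_t)outH * outW * (c + (size_t)C * n);
      for (int ow = 0; ow < outW; ++ow)
        for (int oh = 0; oh < outH; ++oh)
          plane[amax[q++]] += dplane[(size_t)ow * outH + oh];
    }
  }
  return dx;
}

// [[Rcpp::export(name = "cppLrnForward")]]
List cpp_lrn_forward(NumericVector x, int nwin, double k, double alpha,
                     double beta) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector out = make4(H, W, C, N);
  NumericVector denom = make4(H, W, C, N);
  int half = nwin / 2;
  size_t planeSz = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + planeSz * C * n;
    double* on = out.begin() + planeSz * C * n;
    double* dn = denom.begin() + planeSz * C * n;
    for (size_t pix = 0; pix < planeSz; ++pix) {
      for (int c = 0; c < C; ++c) {
        double acc = 0.0;
        int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
        for (int j = lo; j <= hi; ++j) {
          double v = xn[planeSz * j + pix];
          acc += v * v;
        }
        double den = k + alpha * acc;
        dn[planeSz * c + pix] = den;
        on[planeSz * c + pix] = xn[planeSz * c + pix] * std::pow(den, -beta);
      }
    }
  }
  return List::create(_["out"] = out, _["denom"] = denom);
}

// [[Rcpp::export(name = "cppLrnBackward")]]
NumericVector cpp_lrn_backward(NumericVector x, NumericVector out,
                               NumericVector denom, NumericVector dout,
                               int nwin, double alpha, double beta) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector dx = make4(H, W, C, N);
  int half = nwin / 2;
  size_t planeSz = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + planeSz * C * n;
    const double* on = out.begin() + planeSz * C * n;
    const double* dn = denom.begin() + planeSz * C * n;
    const double* gn = dout.begin() + planeSz * C * n;
    double* dxn = dx.begin() + planeSz * C * n;
    for (size_t pix = 0; pix < planeSz; ++pix) {
      for (int c = 0; c < C; ++c) {
        double den = dn[planeSz * c + pix];
        double grad = gn[planeSz * c + pix] * std::pow(den, -beta);
        double acc = 0.0;
        int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
        for (int j = lo; j <= hi; ++j) {
          size_t idx = planeSz * j + pix;
          acc += gn[idx] * on[idx] / dn[idx];
        }
        dxn[planeSz * c + pix] =
          grad - 2.0 * alpha * beta * xn[planeSz * c + pix] * acc;
      }
    }
  }
  return dx;
}
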