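#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused elementwise/rowwise kernels for the encoder's hot paths. These are
// numerically identical to the plain matrix-algebra formulations; they only
// avoid R-level temporaries.

// [[Rcpp::export(name = ".softmax_rows_cpp")]]
NumericMatrix softmax_rows_cpp(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix y(n, k);
  for (int i = 0; i < n; ++i) {
    double m = x(i, 0);
    for (int j = 1; j < k; ++j) if (x(i, j) > m) m = x(i, j);
    double s = 0.0;
    for (int j = 0; j < k; ++j) { double e = std::exp(x(i, j) - m); y(i, j) = e; s += e; }
    const double inv = 1.0 / s;
    for (int j = 0; j < k; ++j) y(i, j) *= inv;
  }
  return y;
}

// gradient through a rowwise softmax: dS = A * (dA - rowSums(A * dA))
// [[Rcpp::export(name = ".softmax_bwd_cpp")]]
NumericMatrix softmax_bwd_cpp(NumericMatrix A, NumericMatrix dA) {
  const int n = A.nrow(), k = A.ncol();
  NumericMatrix dS(n, k);
  for (int i = 0; i < n; ++i) {
    double dot = 0.0;
    for (int j = 0; j < k; ++j) dot += A(i, j) * dA(i, j);
    for (int j = 0; j < k; ++j) dS(i, j) = A(i, j) * (dA(i, j) - dot);
  }
  return dS;
}

// [[Rcpp::export(name = ".log_softmax_cpp")]]
NumericMatrix log_softmax_cpp(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix y(n, k);
  for (int i = 0; i < n; ++i) {
    double m = x(i, 0);
    for (int j = 1; j < k; ++j) if (x(i, j) > m) m = x(i, j);
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(x(i, j) - m);
    const double lse = m + std::log(s);
    for (int j = 0; j < k; ++j) y(i, j) = x(i, j) - lse;
  }
  return y;
}

// [[Rcpp::export(name = ".silu_fwd_cpp")]]
List silu_fwd_cpp(NumericMatrix x) {
  const R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol()), s(x.nrow(), x.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    const double sg = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sg;
    y[i] = x[i] * sg;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export(name = ".silu_bwd_cpp")]]
NumericMatrix silu_bwd_cpp(NumericMatrix dy, NumericMatrix s, NumericMatrix x) {
  const R_xlen_t n = dy.size();
  NumericMatrix dx(dy.nrow(), dy.ncol());
  for (R_xlen_t i = 0; i < n; ++i)
    dx[i] = dy[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  return dx;
}

// [[Rcpp::export(name = ".gelu_fwd_cpp")]]
NumericMatrix gelu_fwd_cpp(NumericMatrix x) {
  const R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol());
  for (R_xlen_t i = 0; i < n; ++i)
    y[i] = x[i] * R::pnorm(x[i], 0.0, 1.0, 1, 0);
  return y;
}

// [[Rcpp::export(name = ".gelu_bwd_cpp")]]
NumericMatrix gelu_bwd_cpp(NumericMatrix dy, NumericMatrix x) {
  const R_xlen_t n = dy.size();
  NumericMatrix dx(dy.nrow(), dy.ncol());
  for (R_xlen_t i = 0; i < n; ++i)
    dx[i] = dy[i] * (R::pnorm(x[i], 0.0, 1.0, 1, 0) +
                     x[i] * R::dnorm(x[i], 0.0, 1.0, 0));
  return dx;
}

// layer norm over rows: returns y, xhat, inv (1/sd)
// [[Rcpp::export(name = ".ln_fwd_cpp")]]
List ln_fwd_cpp(NumericMatrix x, NumericVector g, NumericVector be,
                double eps) {
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix y(n, k), xhat(n, k);
  NumericVector inv(n);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0;
    for (int j = 0; j < k; ++j) mu += x(i, j);
    mu /= k;
    double v = 0.0;
    for (int j = 0; j < k; ++j) { double d = x(i, j) - mu; v += d * d; }
    const double iv = 1.0 / std::sqrt(v / k + eps);
    inv[i] = iv;
    for (int j = 0; j < k; ++j) {
      const double xh = (x(i, j) - mu) * iv;
      xhat(i, j) = xh;
      y(i, j) = xh * g[j] + be[j];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".ln_bwd_cpp")]]
List ln_bwd_cpp(NumericMatrix dy, NumericMatrix xhat, NumericVector inv,
                NumericVector g) {
  const int n = dy.nrow(), k = dy.ncol();
  NumericMatrix dx(n, k);
  NumericVector dg(k), dbe(k);
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int j = 0; j < k; ++j) {
      const double dxh = dy(i, j) * g[j];
      m1 += dxh;
      m2 += dxh * xhat(i, j);
      dg[j] += dy(i, j) * xhat(i, j);
      dbe[j] += dy(i, j);
    }
    m1 /= k; m2 /= k;
    for (int j = 0; j < k; ++j)
      dx(i, j) = (dy(i, j) * g[j] - m1 - xhat(i, j) * m2) * inv[i];
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["dbe"] = dbe);
}

// depthwise 1D conv forward: x (Lp x C, already padded), weight k x C.
// [[Rcpp::export(name = ".dw_fwd_cpp")]]
NumericMatrix dw_fwd_cpp(NumericMatrix xp, NumericMatrix W, NumericVector b,
                         int Lout, int stride) {
  const int C = xp.ncol(), k = W.nrow();
  NumericMatrix y(Lout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &xp(0, c);
    double* yc = &y(0, c);
    for (int t = 0; t < Lout; ++t) {
      double acc = b[c];
      const double* xs = xc + (size_t)t * stride;
      for (int j = 0; j < k; ++j) acc += xs[j] * W(j, c);
      yc[t] = acc;
    }
  }
  return y;
}

// returns dxp (padded-input gradient), dW, db
// [[Rcpp::export(name = ".dw_bwd_cpp")]]
List dw_bwd_cpp(NumericMatrix dy, NumericMatrix xp, NumericMatrix W,
                int stride) {
  const int C = xp.ncol(), k = W.nrow(), Lout = dy.nrow();
  NumericMatrix dxp(xp.nrow(), C), dW(k, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &xp(0, c);
    double* dxc = &dxp(0, c);
    for (int t = 0; t < Lout; ++t) {
      const double d = dy(t, c);
      db[c] += d;
      const size_t off = (size_t)t * stride;
      for (int j = 0; j < k; ++j) {
        dW(j, c) += d * xc[off + j];
        dxc[off + j] += d * W(j, c);
      }
    }
  }
  return List::create(_["dxp"] = dxp, _["dW"] = dW, _["db"] = db);
}

// GLU forward over T x 2C input
// [[Rcpp::export(name = ".glu_fwd_cpp")]]
List glu_fwd_cpp(NumericMatrix x) {
  const int n = x.nrow(), C = x.ncol() / 2;
  NumericMatrix y(n, C), s(n, C);
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < n; ++i) {
      const double sg = 1.0 / (1.0 + std::exp(-x(i, C + j)));
      s(i, j) = sg;
      y(i, j) = x(i, j) * sg;
    }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export(name = ".glu_bwd_cpp")]]
NumericMatrix glu_bwd_cpp(NumericMatrix dy, NumericMatrix a, NumericMatrix s) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, 2 * C);
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < n; ++i) {
      const double d = dy(i, j), sg = s(i, j);
      dx(i, j) = d * sg;
      dx(i, C + j) = d * a(i, j) * sg * (1.0 - sg);
    }
  return dx;
}

// Segmented depthwise conv over B equal-length chunks stacked rowwise.
// x: (B*Tin) x C (unpadded); zero padding `pad` is applied per segment.
// Output: (B*Lout) x C with Lout = (Tin + 2*pad - k)/stride + 1.
// [[Rcpp::export(name = ".dw_fwd_seg_cpp")]]
NumericMatrix dw_fwd_seg_cpp(NumericMatrix x, NumericMatrix W, NumericVector b,
                             int B, int Tin, int pad, int stride) {
  const int C = x.ncol(), k = W.nrow();
  const int Lout = (Tin + 2 * pad - k) / stride + 1;
  NumericMatrix y(B * Lout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int s = 0; s < B; ++s) {
      const double* xs = xc + (size_t)s * Tin;
      double* ys = yc + (size_t)s * Lout;
      for (int t = 0; t < Lout; ++t) {
        double acc = b[c];
        const int start = t * stride - pad;
        const int j0 = start < 0 ? -start : 0;
        const int j1 = (start + k > Tin) ? (Tin - start) : k;
        for (int j = j0; j < j1; ++j) acc += xs[start + j] * W(j, c);
        ys[t] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dw_bwd_seg_cpp")]]
List dw_bwd_seg_cpp(NumericMatrix dy, NumericMatrix x, NumericMatrix W,
                    int B, int Tin, int pad, int stride) {
  const int C = x.ncol(), k = W.nrow();
  const int Lout = dy.nrow() / B;
  NumericMatrix dx(x.nrow(), C), dW(k, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* dyc = &dy(0, c);
    double* dxc = &dx(0, c);
    for (int s = 0; s < B; ++s) {
      const double* xs = xc + (size_t)s * Tin;
      const double* dys = dyc + (size_t)s * Lout;
      double* dxs = dxc + (size_t)s * Tin;
      for (int t = 0; t < Lout; ++t) {
        const double d = dys[t];
        db[c] += d;
        const int start = t * stride - pad;
        const int j0 = start < 0 ? -start : 0;
        const int j1 = (start + k > Tin) ? (Tin - start) : k;
        for (int j = j0; j < j1; ++j) {
          dW(j, c) += d * xs[start + j];
          dxs[start + j] += d * W(j, c);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
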