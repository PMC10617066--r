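// 1D convolution kernels for the separable CNN.
// Activations are column-major arrays [channels, length, samples];
// all convolutions use 'same' zero padding, stride 1.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// depthwise: y[c,t,s] = sum_k w[c,k] * x[c, t+k-P, s]
// [[Rcpp::export]]
NumericVector dw_fwd_cpp(NumericVector x, NumericMatrix w,
                         int M, int L, int n) {
  const int D = w.ncol(), P = (D - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(M) * L * n);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int s = 0; s < n; ++s) {
    const double* xs = px + static_cast<size_t>(s) * M * L;
    double* os = po + static_cast<size_t>(s) * M * L;
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      for (int t = t0; t < t1; ++t) {
        const double* xc = xs + static_cast<size_t>(t + off) * M;
        double* oc = os + static_cast<size_t>(t) * M;
        for (int c = 0; c < M; ++c) oc[c] += w(c, k) * xc[c];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(M, L * n);
  return out;
}

// [[Rcpp::export]]
List dw_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                int M, int L, int n) {
  const int D = w.ncol(), P = (D - 1) / 2;
  NumericVector dx(static_cast<R_xlen_t>(M) * L * n);
  NumericMatrix dw(M, D);
  const double* px = REAL(x);
  const double* pdy = REAL(dy);
  double* pdx = REAL(dx);
  for (int s = 0; s < n; ++s) {
    const size_t base = static_cast<size_t>(s) * M * L;
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      for (int t = t0; t < t1; ++t) {
        const double* xc = px + base + static_cast<size_t>(t + off) * M;
        const double* dyc = pdy + base + static_cast<size_t>(t) * M;
        double* dxc = pdx + base + static_cast<size_t>(t + off) * M;
        for (int c = 0; c < M; ++c) {
          dw(c, k) += xc[c] * dyc[c];
          dxc[c] += w(c, k) * dyc[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(M, L * n);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// standard conv: y[o,t,s] = b[o] + sum_{m,k} w[o,m,k] * x[m, t+k-P, s]
// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int M, int L, int n, int N, int D) {
  const int P = (D - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(N) * L * n);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pb = REAL(b);
  double* po = REAL(out);
  for (int s = 0; s < n; ++s) {
    const double* xs = px + static_cast<size_t>(s) * M * L;
    double* os = po + static_cast<size_t>(s) * N * L;
    for (int t = 0; t < L; ++t)
      for (int o = 0; o < N; ++o) os[static_cast<size_t>(t) * N + o] = pb[o];
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      const double* wk = pw + static_cast<size_t>(k) * N * M;
      for (int t = t0; t < t1; ++t) {
        const double* xc = xs + static_cast<size_t>(t + off) * M;
        double* oc = os + static_cast<size_t>(t) * N;
        for (int m = 0; m < M; ++m) {
          const double xv = xc[m];
          const double* wm = wk + static_cast<size_t>(m) * N;
          for (int o = 0; o < N; ++o) oc[o] += wm[o] * xv;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, L * n);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                  int M, int L, int n, int N, int D) {
  const int P = (D - 1) / 2;
  NumericVector dx(static_cast<R_xlen_t>(M) * L * n);
  NumericVector dw(static_cast<R_xlen_t>(N) * M * D);
  NumericVector db(N);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pdy = REAL(dy);
  double* pdx = REAL(dx);
  double* pdw = REAL(dw);
  double* pdb = REAL(db);
  for (int s = 0; s < n; ++s) {
    const double* xs = px + static_cast<size_t>(s) * M * L;
    const double* dys = pdy + static_cast<size_t>(s) * N * L;
    double* dxs = pdx + static_cast<size_t>(s) * M * L;
    for (int t = 0; t < L; ++t) {
      const double* dyc = dys + static_cast<size_t>(t) * N;
      for (int o = 0; o < N; ++o) pdb[o] += dyc[o];
    }
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      const double* wk = pw + static_cast<size_t>(k) * N * M;
      double* dwk = pdw + static_cast<size_t>(k) * N * M;
      for (int t = t0; t < t1; ++t) {
        const double* xc = xs + static_cast<size_t>(t + off) * M;
        const double* dyc = dys + static_cast<size_t>(t) * N;
        double* dxc = dxs + static_cast<size_t>(t + off) * M;
        for (int m = 0; m < M; ++m) {
          const double xv = xc[m];
          const double* wm = wk + static_cast<size_t>(m) * N;
          double* dwm = dwk + static_cast<size_t>(m) * N;
          double acc = 0.0;
          for (int o = 0; o < N; ++o) {
            dwm[o] += dyc[o] * xv;
            acc += wm[o] * dyc[o];
          }
          dxc[m] += acc;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(M, L * n);
  dw.attr("dim") = IntegerVector::create(N, M, D);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  const double* px = REAL(x);
  double* po = REAL(out);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// zero dy where the forward pre-activation (or activation) ref was <= 0
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector ref) {
  NumericVector out(dy.size());
  const double* pd = REAL(dy);
  const double* pr = REAL(ref);
  double* po = REAL(out);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = pr[i] > 0 ? pd[i] : 0.0;
  out.attr("dim") = dy.attr("dim");
  return out;
}

// global average pool over length: [C, L, n] (flattened) -> [C, n]
// [[Rcpp::export]]
NumericMatrix gap_fwd_cpp(NumericVector x, int C, int L, int n) {
  NumericMatrix out(C, n);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int s = 0; s < n; ++s) {
    double* os = po + static_cast<size_t>(s) * C;
    const double* xs = px + static_cast<size_t>(s) * C * L;
    for (int t = 0; t < L; ++t) {
      const double* xc = xs + static_cast<size_t>(t) * C;
      for (int c = 0; c < C; ++c) os[c] += xc[c];
    }
    for (int c = 0; c < C; ++c) os[c] /= L;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gap_bwd_cpp(NumericMatrix df, int L) {
  const int C = df.nrow(), n = df.ncol();
  NumericVector out(static_cast<R_xlen_t>(C) * L * n);
  const double* pd = REAL(df);
  double* po = REAL(out);
  for (int s = 0; s < n; ++s) {
    const double* ds = pd + static_cast<size_t>(s) * C;
    double* os = po + static_cast<size_t>(s) * C * L;
    for (int t = 0; t < L; ++t) {
      double* oc = os + static_cast<size_t>(t) * C;
      for (int c = 0; c < C; ++c) oc[c] = ds[c] / L;
    }
  }
  out.attr("dim") = IntegerVector::create(C, L * n);
  return out;
}
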