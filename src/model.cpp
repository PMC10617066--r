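// Full forward/backward passes of the residual separable CNN, operating on
// a persistent workspace so the per-epoch cost is pure arithmetic (no R
// allocations for the activation tensors).
#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {

struct CnnWS {
  int L = 0, n = 0, stem_ch = 0, stem_k = 0, hidden = 0, n_blocks = 0;
  std::vector<int> blk_ch, blk_k;
  // forward caches
  std::vector<double> x, stem_z, h0;
  std::vector<std::vector<double>> t1, u1, a1, t2, res, hout;
  std::vector<double> f, gz, g, yhat;
  // backward scratch (max channels x L*n)
  std::vector<double> s1, s2, s3;
};

inline void dw_fwd_raw(const double* x, const double* w, double* out,
                       int M, int L, int n, int D) {
  const int P = (D - 1) / 2;
  std::memset(out, 0, sizeof(double) * (size_t)M * L * n);
  for (int s = 0; s < n; ++s) {
    const double* xs = x + (size_t)s * M * L;
    double* os = out + (size_t)s * M * L;
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      const double* wc = w + (size_t)k * M;
      for (int t = lo; t < hi; ++t) {
        const double* xc = xs + (size_t)(t + off) * M;
        double* oc = os + (size_t)t * M;
        for (int c = 0; c < M; ++c) oc[c] += wc[c] * xc[c];
      }
    }
  }
}

// accumulate dW and write dX for the depthwise layer
inline void dw_bwd_raw(const double* x, const double* w, const double* dy,
                       double* dx, double* dwg, int M, int L, int n, int D) {
  const int P = (D - 1) / 2;
  std::memset(dx, 0, sizeof(double) * (size_t)M * L * n);
  for (int s = 0; s < n; ++s) {
    const size_t base = (size_t)s * M * L;
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      const double* wc = w + (size_t)k * M;
      double* dwc = dwg + (size_t)k * M;
      for (int t = lo; t < hi; ++t) {
        const double* xc = x + base + (size_t)(t + off) * M;
        const double* dyc = dy + base + (size_t)t * M;
        double* dxc = dx + base + (size_t)(t + off) * M;
        for (int c = 0; c < M; ++c) {
          dwc[c] += xc[c] * dyc[c];
          dxc[c] += wc[c] * dyc[c];
        }
      }
    }
  }
}

// y[o,p] = b[o] + sum_m w[o,m] x[m,p]  (1x1 conv over P = L*n positions)
inline void pw_fwd_raw(const double* x, const double* w, const double* b,
                       double* out, int M, int N, size_t P) {
  for (size_t p = 0; p < P; ++p) {
    double* oc = out + p * N;
    for (int o = 0; o < N; ++o) oc[o] = b[o];
    const double* xc = x + p * M;
    for (int m = 0; m < M; ++m) {
      const double xv = xc[m];
      const double* wm = w + (size_t)m * N;
      for (int o = 0; o < N; ++o) oc[o] += wm[o] * xv;
    }
  }
}

// accumulate into out (no bias) -- used for the skip projection's dx
inline void pw_bwd_raw(const double* x, const double* w, const double* dy,
                       double* dx, double* dwg, double* dbg,
                       int M, int N, size_t P, bool accumulate_dx) {
  if (!accumulate_dx && dx) std::memset(dx, 0, sizeof(double) * P * M);
  for (size_t p = 0; p < P; ++p) {
    const double* dyc = dy + p * N;
    const double* xc = x + p * M;
    for (int o = 0; o < N; ++o) dbg[o] += dyc[o];
    for (int m = 0; m < M; ++m) {
      const double xv = xc[m];
      const double* wm = w + (size_t)m * N;
      double* dwm = dwg + (size_t)m * N;
      double acc = 0.0;
      for (int o = 0; o < N; ++o) {
        dwm[o] += dyc[o] * xv;
        acc += wm[o] * dyc[o];
      }
      if (dx) dx[p * M + m] += acc;
    }
  }
}

inline void conv_fwd_raw(const double* x, const double* w, const double* b,
                         double* out, int M, int L, int n, int N, int D) {
  const int P = (D - 1) / 2;
  for (int s = 0; s < n; ++s) {
    const double* xs = x + (size_t)s * M * L;
    double* os = out + (size_t)s * N * L;
    for (int t = 0; t < L; ++t)
      for (int o = 0; o < N; ++o) os[(size_t)t * N + o] = b[o];
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      const double* wk = w + (size_t)k * N * M;
      for (int t = lo; t < hi; ++t) {
        const double* xc = xs + (size_t)(t + off) * M;
        double* oc = os + (size_t)t * N;
        for (int m = 0; m < M; ++m) {
          const double xv = xc[m];
          const double* wm = wk + (size_t)m * N;
          for (int o = 0; o < N; ++o) oc[o] += wm[o] * xv;
        }
      }
    }
  }
}

inline void conv_bwd_raw(const double* x, const double* dy,
                         double* dwg, double* dbg,
                         int M, int L, int n, int N, int D) {
  const int P = (D - 1) / 2;
  for (int s = 0; s < n; ++s) {
    const double* xs = x + (size_t)s * M * L;
    const double* dys = dy + (size_t)s * N * L;
    for (int t = 0; t < L; ++t) {
      const double* dyc = dys + (size_t)t * N;
      for (int o = 0; o < N; ++o) dbg[o] += dyc[o];
    }
    for (int k = 0; k < D; ++k) {
      const int off = k - P;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      double* dwk = dwg + (size_t)k * N * M;
      for (int t = lo; t < hi; ++t) {
        const double* xc = xs + (size_t)(t + off) * M;
        const double* dyc = dys + (size_t)t * N;
        for (int m = 0; m < M; ++m) {
          const double xv = xc[m];
          double* dwm = dwk + (size_t)m * N;
          for (int o = 0; o < N; ++o) dwm[o] += dyc[o] * xv;
        }
      }
    }
  }
}

inline void relu_raw(const double* x, double* out, size_t len) {
  for (size_t i = 0; i < len; ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
}

inline void relu_mask_raw(double* dy, const double* ref, size_t len) {
  for (size_t i = 0; i < len; ++i) if (ref[i] <= 0) dy[i] = 0.0;
}

const double* pget(const List& params, const char* name) {
  return REAL((SEXP)params[name]);
}

std::string bname(int b, const char* field) {
  char t[32];
  std::snprintf(t, sizeof(t), "b%d_%s", b + 1, field);
  return std::string(t);
}

const double* bget(const List& params, int b, const char* field) {
  return REAL((SEXP)params[bname(b, field)]);
}

}  // namespace

// [[Rcpp::export]]
SEXP cnn_ws_new(int L, int n, int stem_ch, int stem_k,
                IntegerVector blk_ch, IntegerVector blk_k, int hidden) {
  CnnWS* ws = new CnnWS();
  ws->L = L; ws->n = n; ws->stem_ch = stem_ch; ws->stem_k = stem_k;
  ws->hidden = hidden; ws->n_blocks = blk_ch.size();
  ws->blk_ch.assign(blk_ch.begin(), blk_ch.end());
  ws->blk_k.assign(blk_k.begin(), blk_k.end());
  const size_t pos = (size_t)L * n;
  ws->x.resize(pos);
  ws->stem_z.resize(pos * stem_ch);
  ws->h0.resize(pos * stem_ch);
  int in_ch = stem_ch, max_ch = stem_ch;
  ws->t1.resize(ws->n_blocks); ws->u1.resize(ws->n_blocks);
  ws->a1.resize(ws->n_blocks); ws->t2.resize(ws->n_blocks);
  ws->res.resize(ws->n_blocks); ws->hout.resize(ws->n_blocks);
  for (int b = 0; b < ws->n_blocks; ++b) {
    const int out_ch = ws->blk_ch[b];
    ws->t1[b].resize(pos * in_ch);
    ws->u1[b].resize(pos * out_ch);
    ws->a1[b].resize(pos * out_ch);
    ws->t2[b].resize(pos * out_ch);
    ws->res[b].resize(pos * out_ch);
    ws->hout[b].resize(pos * out_ch);
    max_ch = std::max(max_ch, out_ch);
    in_ch = out_ch;
  }
  ws->f.resize((size_t)in_ch * n);
  ws->gz.resize((size_t)hidden * n);
  ws->g.resize((size_t)hidden * n);
  ws->yhat.resize(n);
  ws->s1.resize(pos * max_ch);
  ws->s2.resize(pos * max_ch);
  ws->s3.resize(pos * max_ch);
  return XPtr<CnnWS>(ws, true);
}

// [[Rcpp::export]]
NumericVector cnn_forward_ws(SEXP ws_ptr, List params, NumericVector x) {
  XPtr<CnnWS> ws(ws_ptr);
  const int L = ws->L, n = ws->n;
  const size_t pos = (size_t)L * n;
  std::copy(x.begin(), x.end(), ws->x.begin());
  conv_fwd_raw(ws->x.data(), pget(params, "stem_w"), pget(params, "stem_b"),
               ws->stem_z.data(), 1, L, n, ws->stem_ch, ws->stem_k);
  relu_raw(ws->stem_z.data(), ws->h0.data(), pos * ws->stem_ch);
  const double* h = ws->h0.data();
  int in_ch = ws->stem_ch;
  for (int b = 0; b < ws->n_blocks; ++b) {
    const int out_ch = ws->blk_ch[b], D = ws->blk_k[b];
    dw_fwd_raw(h, bget(params, b, "dw1"), ws->t1[b].data(), in_ch, L, n, D);
    pw_fwd_raw(ws->t1[b].data(), bget(params, b, "pw1"),
               bget(params, b, "pb1"), ws->u1[b].data(), in_ch, out_ch, pos);
    relu_raw(ws->u1[b].data(), ws->a1[b].data(), pos * out_ch);
    dw_fwd_raw(ws->a1[b].data(), bget(params, b, "dw2"), ws->t2[b].data(),
               out_ch, L, n, D);
    pw_fwd_raw(ws->t2[b].data(), bget(params, b, "pw2"),
               bget(params, b, "pb2"), ws->res[b].data(), out_ch, out_ch, pos);
    if (in_ch != out_ch) {
      // skip projection added on top of the branch output
      pw_fwd_raw(h, bget(params, b, "proj_w"), bget(params, b, "proj_b"),
                 ws->s1.data(), in_ch, out_ch, pos);
      double* r = ws->res[b].data();
      const double* sk = ws->s1.data();
      for (size_t i = 0; i < pos * out_ch; ++i) r[i] += sk[i];
    } else {
      double* r = ws->res[b].data();
      for (size_t i = 0; i < pos * out_ch; ++i) r[i] += h[i];
    }
    relu_raw(ws->res[b].data(), ws->hout[b].data(), pos * out_ch);
    h = ws->hout[b].data();
    in_ch = out_ch;
  }
  // global average pool over length
  const int C = in_ch;
  std::fill(ws->f.begin(), ws->f.end(), 0.0);
  for (int s = 0; s < n; ++s) {
    double* fs = ws->f.data() + (size_t)s * C;
    const double* hs = h + (size_t)s * C * L;
    for (int t = 0; t < L; ++t) {
      const double* hc = hs + (size_t)t * C;
      for (int c = 0; c < C; ++c) fs[c] += hc[c];
    }
    for (int c = 0; c < C; ++c) fs[c] /= L;
  }
  // dense head
  const int H = ws->hidden;
  const double* w1 = pget(params, "head1_w");
  const double* b1 = pget(params, "head1_b");
  const double* w2 = pget(params, "head2_w");
  const double b2 = pget(params, "head2_b")[0];
  NumericVector yhat(n);
  for (int s = 0; s < n; ++s) {
    const double* fs = ws->f.data() + (size_t)s * C;
    double* gzs = ws->gz.data() + (size_t)s * H;
    double* gs = ws->g.data() + (size_t)s * H;
    for (int hh = 0; hh < H; ++hh) gzs[hh] = b1[hh];
    for (int c = 0; c < C; ++c) {
      const double fv = fs[c];
      const double* wc = w1 + (size_t)c * H;
      for (int hh = 0; hh < H; ++hh) gzs[hh] += wc[hh] * fv;
    }
    double acc = b2;
    for (int hh = 0; hh < H; ++hh) {
      gs[hh] = gzs[hh] > 0 ? gzs[hh] : 0.0;
      acc += w2[hh] * gs[hh];
    }
    ws->yhat[s] = acc;
    yhat[s] = acc;
  }
  return yhat;
}

// [[Rcpp::export]]
List cnn_backward_ws(SEXP ws_ptr, List params, NumericVector dyhat) {
  XPtr<CnnWS> ws(ws_ptr);
  const int L = ws->L, n = ws->n, H = ws->hidden;
  const size_t pos = (size_t)L * n;
  const int C = ws->n_blocks > 0 ? ws->blk_ch[ws->n_blocks - 1] : ws->stem_ch;

  List grads;
  // head
  NumericMatrix d_w2(1, H), d_w1(H, C);
  NumericVector d_b1(H), d_b2(1);
  const double* w2 = pget(params, "head2_w");
  const double* w1 = pget(params, "head1_w");
  std::vector<double> dg((size_t)H * n), df((size_t)C * n, 0.0);
  for (int s = 0; s < n; ++s) {
    const double dy = dyhat[s];
    d_b2[0] += dy;
    const double* gs = ws->g.data() + (size_t)s * H;
    const double* gzs = ws->gz.data() + (size_t)s * H;
    double* dgs = dg.data() + (size_t)s * H;
    for (int hh = 0; hh < H; ++hh) {
      d_w2(0, hh) += dy * gs[hh];
      dgs[hh] = gzs[hh] > 0 ? w2[hh] * dy : 0.0;
      d_b1[hh] += dgs[hh];
    }
    const double* fs = ws->f.data() + (size_t)s * C;
    double* dfs = df.data() + (size_t)s * C;
    for (int c = 0; c < C; ++c) {
      const double* wc = w1 + (size_t)c * H;
      double acc = 0.0;
      for (int hh = 0; hh < H; ++hh) {
        d_w1(hh, c) += dgs[hh] * fs[c];
        acc += wc[hh] * dgs[hh];
      }
      dfs[c] = acc;
    }
  }
  grads["head1_w"] = d_w1; grads["head1_b"] = d_b1;
  grads["head2_w"] = d_w2; grads["head2_b"] = d_b2;

  // GAP backward into s1
  double* dh = ws->s1.data();
  for (int s = 0; s < n; ++s) {
    const double* dfs = df.data() + (size_t)s * C;
    double* ds = dh + (size_t)s * C * L;
    for (int t = 0; t < L; ++t) {
      double* dc = ds + (size_t)t * C;
      for (int c = 0; c < C; ++c) dc[c] = dfs[c] / L;
    }
  }

  for (int b = ws->n_blocks - 1; b >= 0; --b) {
    const int out_ch = ws->blk_ch[b], D = ws->blk_k[b];
    const int in_ch = b == 0 ? ws->stem_ch : ws->blk_ch[b - 1];
    const double* h_in = b == 0 ? ws->h0.data() : ws->hout[b - 1].data();
    // dh (s1) -> dres, masked by the post-add pre-activation
    relu_mask_raw(dh, ws->res[b].data(), pos * out_ch);
    // skip path first: contributes dh_in into s3
    if (in_ch != out_ch) {
      NumericMatrix d_pj(out_ch, in_ch);
      NumericVector d_pjb(out_ch);
      pw_bwd_raw(h_in, bget(params, b, "proj_w"), dh, ws->s3.data(),
                 REAL(d_pj), REAL(d_pjb), in_ch, out_ch, pos, false);
      grads[bname(b, "proj_w")] = d_pj;
      grads[bname(b, "proj_b")] = d_pjb;
    } else {
      std::memcpy(ws->s3.data(), dh, sizeof(double) * pos * out_ch);
    }
    // branch: pw2 -> dw2 -> relu -> pw1 -> dw1
    NumericMatrix d_pw2(out_ch, out_ch), d_dw2(out_ch, D);
    NumericVector d_pb2(out_ch);
    pw_bwd_raw(ws->t2[b].data(), bget(params, b, "pw2"), dh, ws->s2.data(),
               REAL(d_pw2), REAL(d_pb2), out_ch, out_ch, pos, false);
    grads[bname(b, "pw2")] = d_pw2;
    grads[bname(b, "pb2")] = d_pb2;
    dw_bwd_raw(ws->a1[b].data(), bget(params, b, "dw2"), ws->s2.data(),
               ws->s1.data(), REAL(d_dw2), out_ch, L, n, D);
    grads[bname(b, "dw2")] = d_dw2;
    relu_mask_raw(ws->s1.data(), ws->u1[b].data(), pos * out_ch);
    NumericMatrix d_pw1(out_ch, in_ch), d_dw1(in_ch, D);
    NumericVector d_pb1(out_ch);
    pw_bwd_raw(ws->t1[b].data(), bget(params, b, "pw1"), ws->s1.data(),
               ws->s2.data(), REAL(d_pw1), REAL(d_pb1), in_ch, out_ch, pos,
               false);
    grads[bname(b, "pw1")] = d_pw1;
    grads[bname(b, "pb1")] = d_pb1;
    dw_bwd_raw(h_in, bget(params, b, "dw1"), ws->s2.data(), ws->s1.data(),
               REAL(d_dw1), in_ch, L, n, D);
    grads[bname(b, "dw1")] = d_dw1;
    // total dh_in = branch dx (s1) + skip dx (s3)
    double* a = ws->s1.data();
    const double* sk = ws->s3.data();
    for (size_t i = 0; i < pos * in_ch; ++i) a[i] += sk[i];
    dh = ws->s1.data();
  }

  // stem
  relu_mask_raw(dh, ws->stem_z.data(), pos * ws->stem_ch);
  NumericVector d_stem_w((R_xlen_t)ws->stem_ch * ws->stem_k);
  NumericVector d_stem_b(ws->stem_ch);
  conv_bwd_raw(ws->x.data(), dh, REAL(d_stem_w), REAL(d_stem_b),
               1, L, n, ws->stem_ch, ws->stem_k);
  d_stem_w.attr("dim") = IntegerVector::create(ws->stem_ch, 1, ws->stem_k);
  grads["stem_w"] = d_stem_w; grads["stem_b"] = d_stem_b;
  return grads;
}
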