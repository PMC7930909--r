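#include <Rcpp.h>
using namespace Rcpp;

// Array layout conventions (column-major R arrays):
//   activations x : dim (N, C, H, W), element (n,c,h,w) at n + N*(c + C*(h + H*w))
//   kernels     w : dim (Cout, Cin, KH, KW)
//   pool index maps: 0-based flat index h + H*w into the (H, W) plane of the
//   pre-pool array, one per pooled output cell.

static inline void get_dim4(const RObject &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  int dx[4], dw[4];
  get_dim4(x, dx); get_dim4(w, dw);
  const int N = dx[0], Ci = dx[1], H = dx[2], W = dx[3];
  const int Co = dw[0], Kh = dw[2], Kw = dw[3];
  if (dw[1] != Ci) stop("conv2d: input has %d channels but kernel expects %d", Ci, dw[1]);
  const int Ho = (H + 2 * pad - Kh) / stride + 1;
  const int Wo = (W + 2 * pad - Kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  NumericVector out(N * Co * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  std::vector<double> b(Co, 0.0);
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    for (int c = 0; c < Co; ++c) b[c] = bv[c];
  }
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int co = 0; co < Co; ++co)
        for (int n = 0; n < N; ++n) {
          double acc = b[co];
          for (int kw = 0; kw < Kw; ++kw) {
            int win = wo * stride - pad + kw;
            if (win < 0 || win >= W) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              int hin = ho * stride - pad + kh;
              if (hin < 0 || hin >= H) continue;
              for (int ci = 0; ci < Ci; ++ci)
                acc += px[n + N * (ci + Ci * (hin + H * win))] *
                       pw[co + Co * (ci + dw[1] * (kh + Kh * kw))];
            }
          }
          po[n + N * (co + Co * (ho + Ho * wo))] = acc;
        }
  return out;
}

// Adjoint of cpp_conv2d_fwd with respect to its input (transpose convolution).
// g: (N, Cout, Ho, Wo); returns (N, Cin, H, W).
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector g, NumericVector w,
                                  int stride, int pad, int H, int W) {
  int dg[4], dw[4];
  get_dim4(g, dg); get_dim4(w, dw);
  const int N = dg[0], Co = dg[1], Ho = dg[2], Wo = dg[3];
  const int Ci = dw[1], Kh = dw[2], Kw = dw[3];
  if (dw[0] != Co) stop("conv2d adjoint: kernel/output channel mismatch");
  NumericVector out(N * Ci * H * W);
  out.attr("dim") = IntegerVector::create(N, Ci, H, W);
  const double *pg = g.begin(), *pw = w.begin();
  double *po = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int co = 0; co < Co; ++co)
        for (int n = 0; n < N; ++n) {
          double gv = pg[n + N * (co + Co * (ho + Ho * wo))];
          if (gv == 0.0) continue;
          for (int kw = 0; kw < Kw; ++kw) {
            int win = wo * stride - pad + kw;
            if (win < 0 || win >= W) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              int hin = ho * stride - pad + kh;
              if (hin < 0 || hin >= H) continue;
              for (int ci = 0; ci < Ci; ++ci)
                po[n + N * (ci + Ci * (hin + H * win))] +=
                    gv * pw[co + Co * (ci + Ci * (kh + Kh * kw))];
            }
          }
        }
  return out;
}

// Gradient of <g, conv(x, w)> with respect to w.
// x: (N, Cin, H, W); g: (N, Cout, Ho, Wo); returns (Cout, Cin, Kh, Kw).
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_weight(NumericVector x, NumericVector g,
                                    int stride, int pad, int Kh, int Kw) {
  int dx[4], dg[4];
  get_dim4(x, dx); get_dim4(g, dg);
  const int N = dx[0], Ci = dx[1], H = dx[2], W = dx[3];
  const int Co = dg[1], Ho = dg[2], Wo = dg[3];
  if (dg[0] != N) stop("conv2d weight grad: batch mismatch");
  NumericVector out(Co * Ci * Kh * Kw);
  out.attr("dim") = IntegerVector::create(Co, Ci, Kh, Kw);
  const double *px = x.begin(), *pg = g.begin();
  double *po = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int co = 0; co < Co; ++co)
        for (int n = 0; n < N; ++n) {
          double gv = pg[n + N * (co + Co * (ho + Ho * wo))];
          if (gv == 0.0) continue;
          for (int kw = 0; kw < Kw; ++kw) {
            int win = wo * stride - pad + kw;
            if (win < 0 || win >= W) continue;
            for (int kh = 0; kh < Kh; ++kh) {
              int hin = ho * stride - pad + kh;
              if (hin < 0 || hin >= H) continue;
              for (int ci = 0; ci < Ci; ++ci)
                po[co + Co * (ci + Ci * (kh + Kh * kw))] +=
                    gv * px[n + N * (ci + Ci * (hin + H * win))];
            }
          }
        }
  return out;
}

// Max pooling with recorded argmax indices. Ties resolve to the first
// position in (h fastest, then w) scan order, deterministically.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int window, int stride) {
  int dx[4];
  get_dim4(x, dx);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int Hp = (H - window) / stride + 1;
  const int Wp = (W - window) / stride + 1;
  if (Hp <= 0 || Wp <= 0) stop("maxpool: non-positive output size");
  NumericVector val(N * C * Hp * Wp);
  IntegerVector idx(N * C * Hp * Wp);
  val.attr("dim") = IntegerVector::create(N, C, Hp, Wp);
  idx.attr("dim") = IntegerVector::create(N, C, Hp, Wp);
  const double *px = x.begin();
  double *pv = val.begin();
  int *pi = idx.begin();
  for (int wp = 0; wp < Wp; ++wp)
    for (int hp = 0; hp < Hp; ++hp)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          int bidx = -1;
          for (int dw = 0; dw < window; ++dw) {
            int wpos = wp * stride + dw;
            for (int dh = 0; dh < window; ++dh) {
              int hpos = hp * stride + dh;
              double v = px[n + N * (c + C * (hpos + H * wpos))];
              if (v > best) { best = v; bidx = hpos + H * wpos; }
            }
          }
          int o = n + N * (c + C * (hp + Hp * wp));
          pv[o] = best;
          pi[o] = bidx;
        }
  return List::create(_["values"] = val, _["idx"] = idx);
}

// Scatter pooled values back to the pre-pool plane at the recorded argmax
// positions (inverse pooling P^{-1}); accumulates on collision.
// [[Rcpp::export]]
NumericVector cpp_unpool(NumericVector g, IntegerVector idx, int H, int W) {
  int dg[4];
  get_dim4(g, dg);
  const int N = dg[0], C = dg[1], Hp = dg[2], Wp = dg[3];
  NumericVector out(N * C * H * W);
  out.attr("dim") = IntegerVector::create(N, C, H, W);
  const double *pg = g.begin();
  const int *pi = idx.begin();
  double *po = out.begin();
  for (int wp = 0; wp < Wp; ++wp)
    for (int hp = 0; hp < Hp; ++hp)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          int o = n + N * (c + C * (hp + Hp * wp));
          int plane = pi[o];
          po[n + N * (c + C * plane)] += pg[o];
        }
  return out;
}

// Gather from the pre-pool plane at the recorded argmax positions
// (adjoint of cpp_unpool; equals max pooling when indices match argmax).
// [[Rcpp::export]]
NumericVector cpp_pool_gather(NumericVector x, IntegerVector idx) {
  int dx[4], di[4];
  get_dim4(x, dx); get_dim4(idx, di);
  const int N = dx[0], C = dx[1];
  const int Hp = di[2], Wp = di[3];
  NumericVector out(N * C * Hp * Wp);
  out.attr("dim") = IntegerVector::create(N, C, Hp, Wp);
  const double *px = x.begin();
  const int *pi = idx.begin();
  double *po = out.begin();
  for (int wp = 0; wp < Wp; ++wp)
    for (int hp = 0; hp < Hp; ++hp)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          int o = n + N * (c + C * (hp + Hp * wp));
          po[o] = px[n + N * (c + C * pi[o])];
        }
  return out;
}
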