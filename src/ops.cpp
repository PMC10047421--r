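// Low-level numeric kernels for the segmentation network.
// Tensor layout everywhere: column-major R array (H, W, C, N).
// Weight layout: (kh, kw, C_in, C_out); both flatten directly to the
// im2col row order a + kh*(b + kw*c), so no permutation copies are needed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;
using arma::mat;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int d, int p,
                   int Ho, int Wo, mat& col) {
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + b * d;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * s - p + a * d;
            col(r, oh + Ho * ow) =
              (ih >= 0 && ih < H && iw >= 0 && iw < W)
                ? x[ih + (size_t)H * (iw + (size_t)W * c)] : 0.0;
          }
        }
      }
}

static void col2im_acc(const mat& col, double* dx, int H, int W, int C,
                       int kh, int kw, int s, int d, int p,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * (b + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + b * d;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * s - p + a * d;
            if (ih < 0 || ih >= H) continue;
            dx[ih + (size_t)H * (iw + (size_t)W * c)] += col(r, oh + Ho * ow);
          }
        }
      }
}

static void out_size(int H, int W, int kh, int kw, int s, int d, int p,
                     int& Ho, int& Wo) {
  Ho = (H + 2 * p - d * (kh - 1) - 1) / s + 1;
  Wo = (W + 2 * p - d * (kw - 1) - 1) / s + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output size would be < 1");
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector bias,
                       int stride, int dilation, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("channel mismatch in conv_fwd");
  int Ho, Wo;
  out_size(H, W, kh, kw, stride, dilation, pad, Ho, Wo);
  const int K = kh * kw * C;

  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  const mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, stride, dilation, pad, Ho, Wo, col);
    mat Y(y.begin() + (size_t)n * Ho * Wo * Co, (size_t)Ho * Wo, Co, false, true);
    Y = col.t() * Wm;
    for (int c = 0; c < Co; ++c) Y.col(c) += bias[c];
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
              int stride, int dilation, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho, Wo;
  out_size(H, W, kh, kw, stride, dilation, pad, Ho, Wo);
  const int K = kh * kw * C;

  NumericVector dx((R_xlen_t)H * W * C * N), dw((R_xlen_t)K * Co), db(Co);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;

  mat dWm(dw.begin(), K, Co, false, true);
  const mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, stride, dilation, pad, Ho, Wo, col);
    const mat G(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Co,
                (size_t)Ho * Wo, Co, false, true);
    dWm += col * G;
    for (int c = 0; c < Co; ++c) db[c] += arma::accu(G.col(c));
    mat dcol = Wm * G.t();
    col2im_acc(dcol, dx.begin() + (size_t)n * H * W * C, H, W, C,
               kh, kw, stride, dilation, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; returns pooled values and 1-based argmax
// indices into the flattened input (for the backward scatter).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf; size_t bi = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const size_t i = base + (2 * oh + a) + (size_t)H * (2 * ow + b);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          const size_t oo = (size_t)(oh + Ho * (ow + (size_t)Wo * (c + (size_t)C * n)));
          y[oo] = best;
          idx[oo] = (int)(bi + 1);
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) dx[idx[i] - 1] += gy[i];
  return dx;
}

// Connected-component labelling of a binary matrix (4- or 8-connectivity),
// BFS flood fill; labels are 1..n in scan order of the first pixel seen.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix m, int connectivity) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.clear();
      stack.push_back(i + H * j);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int k = 0; k < nd; ++k) {
          const int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (m(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  return lab;
}
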