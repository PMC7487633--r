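// Low-level numerical kernels for the patch-based U-Net and the
// caliber-measurement skeletonization. Tensors are R arrays in
// (H, W, C, N) column-major layout; convolutions use zero ("same")
// padding via im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector make4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat im2col(const double* x, int H, int W, int C, int k) {
  // columns indexed by output pixel (h + H*w), rows by (kh + k*kw + k*k*c)
  const int pad = k / 2;
  arma::mat cols(k * k * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) {
            cols(r, h + H * w) = xc[(h + kh - pad) + (size_t)H * iw];
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of im2col-layout gradients back onto the input image
static inline void col2im_add(arma::mat& cols, double* dx, int H, int W, int C,
                              int k) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) {
            xc[(h + kh - pad) + (size_t)H * iw] += cols(r, h + H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and weights");
  arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
  arma::vec bv(b.begin(), Cout, false, true);
  NumericVector y = make4d(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k);
    arma::mat out = Wm.t() * cols;               // (Cout x HW)
    out.each_col() += bv;
    // transpose into (H, W, Cout) layout
    double* yp = y.begin() + (size_t)H * W * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < H * W; ++p) yp[p + (size_t)H * W * c] = out(c, p);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(k, k, C, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)H * W * Cout * n;
    arma::mat dyn(Cout, H * W);
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < H * W; ++p) dyn(c, p) = dyp[p + (size_t)H * W * c];
    arma::mat cols = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k);
    dWm += cols * dyn.t();
    dbv += arma::sum(dyn, 1);
    arma::mat dcols = Wm * dyn;                  // (kkC x HW)
    col2im_add(dcols, dx.begin() + (size_t)H * W * C * n, H, W, C, k);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2 (H and W must be even)
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx = make4i(Ho, Wo, C, N);  // flat index into x plane
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = (2 * h) + H * (2 * w);
          double bv = xp[best];
          const int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                               2 * h + 1 + H * (2 * w + 1)};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          yp[h + Ho * w] = bv;
          ip[h + Ho * w] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = make4d(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int p = 0; p < Ho * Wo; ++p) dxp[ip[p]] += dyp[p];
    }
  return dx;
}

// transposed 2x2 convolution, stride 2 ("up-convolution")
// w has dim (2, 2, Cin, Cout)
// [[Rcpp::export]]
NumericVector upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  NumericVector y = make4d(2 * H, 2 * W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(H * W, C);
    const double* xp = x.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) X(p, c) = xp[p + (size_t)H * W * c];
    double* yp = y.begin() + (size_t)4 * H * W * Cout * n;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            Wsub(c, co) = w[di + 2 * dj + 4 * (c + (size_t)C * co)];
        arma::mat Ysub = X * Wsub;  // (HW x Cout)
        for (int co = 0; co < Cout; ++co)
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              yp[(2 * h + di) + 2 * H * (2 * wcol + dj) +
                 (size_t)4 * H * W * co] = Ysub(h + H * wcol, co) + b[co];
      }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(2, 2, C, Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(H * W, C);
    const double* xp = x.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) X(p, c) = xp[p + (size_t)H * W * c];
    const double* dyp = dy.begin() + (size_t)4 * H * W * Cout * n;
    arma::mat dX(H * W, C, arma::fill::zeros);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            Wsub(c, co) = w[di + 2 * dj + 4 * (c + (size_t)C * co)];
        arma::mat dYsub(H * W, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              dYsub(h + H * wcol, co) =
                  dyp[(2 * h + di) + 2 * H * (2 * wcol + dj) +
                      (size_t)4 * H * W * co];
        dX += dYsub * Wsub.t();
        arma::mat dWsub = X.t() * dYsub;  // (C x Cout)
        for (int co = 0; co < Cout; ++co) {
          for (int c = 0; c < C; ++c)
            dw[di + 2 * dj + 4 * (c + (size_t)C * co)] += dWsub(c, co);
        }
      }
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int p = 0; p < 4 * H * W; ++p) s += dyp[p + (size_t)4 * H * W * co];
      db[co] += s;
    }
    double* dxp = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < H * W; ++p) dxp[p + (size_t)H * W * c] = dX(p, c);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Guo-Hall binary thinning (two-subiteration); m is a 0/1 integer matrix.
// Chosen over Zhang-Suen because the latter annihilates thin diagonal
// structures entirely, which retinal vessels at ~45 degrees become.
// [[Rcpp::export]]
IntegerMatrix thin_binary(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix img(clone(m));
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (!img(r, c)) continue;
          const int p2 = P(r - 1, c), p3 = P(r - 1, c + 1), p4 = P(r, c + 1),
                    p5 = P(r + 1, c + 1), p6 = P(r + 1, c), p7 = P(r + 1, c - 1),
                    p8 = P(r, c - 1), p9 = P(r - 1, c - 1);
          const int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          if (C != 1) continue;
          const int n1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          const int n2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          const int n = n1 < n2 ? n1 : n2;
          if (n < 2 || n > 3) continue;
          const int e = pass == 0 ? ((p6 | p7 | (!p9)) & p8)
                                  : ((p2 | p3 | (!p5)) & p4);
          if (e != 0) continue;
          kill.emplace_back(r, c);
        }
      for (auto& rc : kill) img(rc.first, rc.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
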