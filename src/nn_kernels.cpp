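#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors cross the R/C++ boundary as dense arrays in (H, W, C, N) layout,
// which is column-major contiguous per channel: a (c, n) slice is an H x W
// arma::mat view without copying. Kernels are (kh, kw, Cin, Cout); flattened
// column-major that is a (kh*kw*Cin) x Cout matrix, so convolution reduces to
// im2col + GEMM. Stride is fixed at 1 with "same" zero padding (odd kernels).

static void im2col_same(const double* x, int H, int W, int C,
                        int kh, int kw, arma::mat& X) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  X.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + j - pw;
          if (iw < 0 || iw >= W) continue;
          const double* src = xc + (std::size_t)H * iw;
          double* dst = X.memptr() + (std::size_t)X.n_rows * H * w + r;
          for (int h = 0; h < H; ++h) {
            const int ih = h + i - ph;
            if (ih < 0 || ih >= H) continue;
            dst[(std::size_t)X.n_rows * h] = src[ih];
          }
        }
      }
    }
  }
}

static void col2im_same(const arma::mat& Xc, int H, int W, int C,
                        int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + j - pw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + i - ph;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (std::size_t)H * iw] += Xc(r, h + (std::size_t)H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernels must have odd spatial size");

  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (std::size_t)kh * kw * Cin, Cout, false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector out((std::size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat X((std::size_t)kh * kw * Cin, (std::size_t)H * W);

  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, X);
    arma::mat Y = Wm.t() * X;           // Cout x (H*W)
    Y.each_col() += bv;
    // row o of Y is channel o in column-major (H, W) order
    arma::mat Yt = Y.t();               // (H*W) x Cout
    std::copy(Yt.memptr(), Yt.memptr() + Yt.n_elem,
              out.begin() + (std::size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];

  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (std::size_t)kh * kw * Cin, Cout, false, true);

  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW((std::size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat X((std::size_t)kh * kw * Cin, (std::size_t)H * W);

  for (int n = 0; n < N; ++n) {
    // dY as (H*W) x Cout view of this sample's gradient
    const arma::mat dYt(const_cast<double*>(dy.begin()) +
                        (std::size_t)H * W * Cout * n,
                        (std::size_t)H * W, Cout, false, true);
    im2col_same(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, X);
    dW += X * dYt;
    db += arma::sum(dYt, 0).t();
    arma::mat dXc = Wm * dYt.t();       // (kh*kw*Cin) x (H*W)
    col2im_same(dXc, H, W, C, kh, kw,
                dx.begin() + (std::size_t)H * W * C * n);
  }

  NumericVector dWr(dW.memptr(), dW.memptr() + dW.n_elem);
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".avgpool_forward")]]
NumericVector avgpool_forward(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % k || W % k) stop("spatial size not divisible by pool factor");
  const int Ho = H / k, Wo = W / k;
  const double inv = 1.0 / ((double)k * k);

  NumericVector out((std::size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* yo = out.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double s = 0.0;
          for (int dw = 0; dw < k; ++dw)
            for (int dh = 0; dh < k; ++dh)
              s += xi[(h * k + dh) + (std::size_t)H * (w * k + dw)];
          yo[h + (std::size_t)Ho * w] = s * inv;
        }
    }
  return out;
}

// [[Rcpp::export(name = ".avgpool_backward")]]
NumericVector avgpool_backward(NumericVector dy, int k) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho * k, W = Wo * k;
  const double inv = 1.0 / ((double)k * k);

  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gi = dy.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      double* go = dx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double g = gi[h + (std::size_t)Ho * w] * inv;
          for (int dw = 0; dw < k; ++dw)
            for (int dh = 0; dh < k; ++dh)
              go[(h * k + dh) + (std::size_t)H * (w * k + dw)] = g;
        }
    }
  return dx;
}
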