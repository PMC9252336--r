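#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D convolution kernels for the residual network.
// Layout conventions (R column-major arrays):
//   activations x : (H, W, C, N)
//   weights     w : (k, k, Cin, Cout)
// im2col column index p = ho + Ho * wo; row index kk = i + k*j + k*k*c.

static void im2col(const double *x, int H, int W, int C,
                   int k, int stride, int pad,
                   int Ho, int Wo, arma::mat &col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        int p = ho + Ho * wo;
        for (int j = 0; j < k; ++j) {
          int ww = w0 + j;
          if (ww < 0 || ww >= W) continue;
          for (int i = 0; i < k; ++i) {
            int hh = h0 + i;
            if (hh < 0 || hh >= H) continue;
            col(i + k * j + k * k * c, p) = xc[hh + (size_t)H * ww];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &col, int H, int W, int C,
                   int k, int stride, int pad,
                   int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        int p = ho + Ho * wo;
        for (int j = 0; j < k; ++j) {
          int ww = w0 + j;
          if (ww < 0 || ww >= W) continue;
          for (int i = 0; i < k; ++i) {
            int hh = h0 + i;
            if (hh < 0 || hh >= H) continue;
            xc[hh + (size_t)H * ww] += col(i + k * j + k * k * c, p);
          }
        }
      }
    }
  }
}

// weight array -> (Cout x K) matrix, K = k*k*Cin, column kk as in im2col
static arma::mat weight_mat(const NumericVector &w, int k, int Cin, int Cout) {
  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          Wm(co, i + k * j + k * k * c) =
            w[i + (size_t)k * (j + (size_t)k * (c + (size_t)Cin * co))];
  return Wm;
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int K = k * k * Cin, P = Ho * Wo;

  arma::mat Wm = weight_mat(w, k, Cin, Cout);
  arma::mat col(K, P);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat Y = Wm * col;               // Cout x P
    double *o = REAL(out) + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double bc = b[co];
      for (int p = 0; p < P; ++p) o[p + (size_t)P * co] = Y(co, p) + bc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int K = k * k * Cin, P = Ho * Wo;

  arma::mat Wm = weight_mat(w, k, Cin, Cout);
  arma::mat col(K, P), dWm(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;

  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat dY(Cout, P);
    const double *d = REAL(dy) + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < P; ++p) dY(co, p) = d[p + (size_t)P * co];
    dWm += dY * col.t();
    db += arma::sum(dY, 1);
    arma::mat dcol = Wm.t() * dY;          // K x P
    col2im(dcol, H, W, C, k, stride, pad, Ho, Wo,
           REAL(dx) + (size_t)H * W * C * n);
  }

  NumericVector dw((size_t)k * k * Cin * Cout);
  dw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          dw[i + (size_t)k * (j + (size_t)k * (c + (size_t)Cin * co))] =
            dWm(co, i + k * j + k * k * c);

  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = db(co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}
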