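// Minimal CNN building blocks (3x3 same-padding convolution via im2col +
// GEMM, 2x2 max pooling, batch normalization) for the phenotype classifier.
// Batches are stored as arma::cube(H, W, C * N) with slice index c + C*n,
// which matches the memory layout of an R array dim = c(H, W, C, N).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// whole-batch im2col, transposed layout: Cols is (H*W*N) x (C*9);
// column index f = c*9 + (dr+1)*3 + (dc+1); row index h + H*(w + W*n).
// Contiguous h-runs make both fill and scatter cache-friendly, and the
// convolution becomes a single large GEMM per layer.
static void im2col3_batch(const arma::cube& X, int C, int N,
                          arma::mat& cols) {
  const int H = X.n_rows, W = X.n_cols;
  cols.zeros();
  for (int c = 0; c < C; ++c)
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        const int f = c * 9 + (dr + 1) * 3 + (dc + 1);
        double* dst0 = cols.colptr(f);
        const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
        for (int n = 0; n < N; ++n) {
          const arma::mat& S = X.slice(c + C * n);
          for (int w = 0; w < W; ++w) {
            const int w2 = w + dc;
            if (w2 < 0 || w2 >= W) continue;
            const double* src = S.colptr(w2) + (h0 + dr);
            double* dst = dst0 + h0 + H * (w + (long)W * n);
            std::memcpy(dst, src, sizeof(double) * (h1 - h0));
          }
        }
      }
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& X, const arma::mat& Wm,
                        const arma::vec& b, int C, int N) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_rows;
  arma::mat cols((long)H * W * N, C * 9);
  im2col3_batch(X, C, N, cols);
  arma::mat out = cols * Wm.t(); // (HWN) x Cout
  arma::cube Y(H, W, Cout * N);
  const long HW = (long)H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* src = out.colptr(co);
    for (int n = 0; n < N; ++n) {
      std::memcpy(Y.slice(co + Cout * n).memptr(), src + HW * n,
                  sizeof(double) * HW);
    }
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      Y.slice(co + Cout * n) += b[co];
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& X, const arma::mat& Wm,
                  const arma::cube& dY, int C, int N) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_rows;
  const long HW = (long)H * W;
  arma::mat cols(HW * N, C * 9);
  im2col3_batch(X, C, N, cols);
  arma::mat dYm(HW * N, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = dYm.colptr(co);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + HW * n, dY.slice(co + Cout * n).memptr(),
                  sizeof(double) * HW);
  }
  arma::mat dW = dYm.t() * cols;      // Cout x (C*9)
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dcols = dYm * Wm;         // (HWN) x (C*9)
  arma::cube dX(H, W, C * N, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        const int f = c * 9 + (dr + 1) * 3 + (dc + 1);
        const double* src0 = dcols.colptr(f);
        const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
        for (int n = 0; n < N; ++n) {
          arma::mat& D = dX.slice(c + C * n);
          for (int w = 0; w < W; ++w) {
            const int w2 = w + dc;
            if (w2 < 0 || w2 >= W) continue;
            double* dst = D.colptr(w2) + (h0 + dr);
            const double* src = src0 + h0 + H * (w + (long)W * n);
            for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
          }
        }
      }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export]]
List cpp_pool_fwd(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube Y(Ho, Wo, S);
  arma::ucube amax(Ho, Wo, S);
  for (int s = 0; s < S; ++s) {
    const arma::mat& A = X.slice(s);
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = A(2 * h, 2 * w);
        unsigned int bi = 2 * h + H * (2 * w);
        for (int dh = 0; dh < 2; ++dh)
          for (int dw = 0; dw < 2; ++dw) {
            const double v = A(2 * h + dh, 2 * w + dw);
            if (v > best) {
              best = v;
              bi = (2 * h + dh) + H * (2 * w + dw);
            }
          }
        Y(h, w, s) = best;
        amax(h, w, s) = bi;
      }
  }
  return List::create(Named("Y") = Y, Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::cube cpp_pool_bwd(const arma::cube& dY, const arma::ucube& amax, int H,
                        int W) {
  const int S = dY.n_slices;
  arma::cube dX(H, W, S, arma::fill::zeros);
  const int Ho = dY.n_rows, Wo = dY.n_cols;
  for (int s = 0; s < S; ++s)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        dX.slice(s)(amax(h, w, s)) += dY(h, w, s);
  return dX;
}

// [[Rcpp::export]]
List cpp_bn_fwd(const arma::cube& X, const arma::vec& gamma,
                const arma::vec& beta, int C, int N, bool training,
                const arma::vec& running_mean, const arma::vec& running_var,
                double momentum, double eps) {
  const int H = X.n_rows, W = X.n_cols;
  arma::cube Y(H, W, C * N), xhat(H, W, C * N);
  arma::vec mean(C), var(C), invstd(C);
  arma::vec new_rm = running_mean, new_rv = running_var;
  const double m = (double)H * W * N;
  for (int c = 0; c < C; ++c) {
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const arma::mat& S = X.slice(c + C * n);
        s += arma::accu(S);
        s2 += arma::accu(S % S);
      }
      mean[c] = s / m;
      var[c] = s2 / m - mean[c] * mean[c];
      if (var[c] < 0) var[c] = 0;
      new_rm[c] = momentum * running_mean[c] + (1 - momentum) * mean[c];
      new_rv[c] = momentum * running_var[c] + (1 - momentum) * var[c];
    } else {
      mean[c] = running_mean[c];
      var[c] = running_var[c];
    }
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      xhat.slice(c + C * n) = (X.slice(c + C * n) - mean[c]) * invstd[c];
      Y.slice(c + C * n) = gamma[c] * xhat.slice(c + C * n) + beta[c];
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = xhat,
                      Named("invstd") = invstd,
                      Named("running_mean") = new_rm,
                      Named("running_var") = new_rv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::cube& dY, const arma::cube& xhat,
                const arma::vec& gamma, const arma::vec& invstd, int C,
                int N) {
  const int H = dY.n_rows, W = dY.n_cols;
  arma::cube dX(H, W, C * N);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  const double m = (double)H * W * N;
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const arma::mat& D = dY.slice(c + C * n);
      sdy += arma::accu(D);
      sdyx += arma::accu(D % xhat.slice(c + C * n));
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double k = gamma[c] * invstd[c] / m;
    for (int n = 0; n < N; ++n)
      dX.slice(c + C * n) =
          k * (m * dY.slice(c + C * n) - sdy -
               xhat.slice(c + C * n) * sdyx);
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// flatten cube (H, W, C*N) -> matrix (H*W*C, N)
// [[Rcpp::export]]
arma::mat cpp_flatten(const arma::cube& X, int C, int N) {
  const int H = X.n_rows, W = X.n_cols;
  arma::mat out(H * W * C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      out.col(n).subvec(c * H * W, (c + 1) * H * W - 1) =
          arma::vectorise(X.slice(c + C * n));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_unflatten(const arma::mat& M, int H, int W, int C, int N) {
  arma::cube X(H, W, C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      X.slice(c + C * n) = arma::reshape(
          M.col(n).subvec(c * H * W, (c + 1) * H * W - 1), H, W);
  return X;
}

// nearest-neighbour + area-average rescale of a matrix to side x side
// (box sampling: each output pixel averages the covered input region)
// [[Rcpp::export]]
NumericMatrix cpp_rescale(const NumericMatrix& img, int out_r, int out_c) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_r, out_c);
  for (int oc = 0; oc < out_c; ++oc) {
    const double c0 = (double)oc * nc / out_c;
    const double c1 = (double)(oc + 1) * nc / out_c;
    int ci0 = (int)std::floor(c0), ci1 = (int)std::ceil(c1);
    ci1 = std::min(ci1, nc);
    for (int orr = 0; orr < out_r; ++orr) {
      const double r0 = (double)orr * nr / out_r;
      const double r1 = (double)(orr + 1) * nr / out_r;
      int ri0 = (int)std::floor(r0), ri1 = (int)std::ceil(r1);
      ri1 = std::min(ri1, nr);
      double s = 0.0, wsum = 0.0;
      for (int c = ci0; c < ci1; ++c) {
        const double wc =
            std::min(c1, (double)c + 1) - std::max(c0, (double)c);
        for (int r = ri0; r < ri1; ++r) {
          const double wr =
              std::min(r1, (double)r + 1) - std::max(r0, (double)r);
          s += wc * wr * img(r, c);
          wsum += wc * wr;
        }
      }
      out(orr, oc) = wsum > 0 ? s / wsum : 0.0;
    }
  }
  return out;
}
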