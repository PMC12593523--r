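// Low-level tensor kernels for the 3-D convolutional network.
//
// Activations are dense column-major arrays [H, W, B, C, N]
// (two grid axes, spectral axis, channels, batch); convolution weights are
// [k1, k2, k3, Cin, Cout].  Convolution is implemented as im2col + GEMM per
// sample; the backward passes recompute the im2col patch matrix instead of
// caching it, trading a little compute for memory.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long idx5(int h, int w, int b, int c, int n,
                        int H, int W, int B, int C) {
  return h + (long)H * (w + (long)W * (b + (long)B * (c + (long)C * n)));
}

// Output size along one axis for a strided, padded convolution
static inline int out_sz(int M, int pad, int k, int stride) {
  int v = (M + 2 * pad - k) / stride + 1;
  return v;
}

// Fill the im2col patch matrix for one sample.
// Xcol is [P, Q] with P = Ho*Wo*Bo (h fastest) and
// Q = k1*k2*k3*Cin (kh fastest, then kw, kb, ci) -- this ordering matches the
// column-major flattening of the weight array [k1,k2,k3,Cin,Cout].
static void im2col(const double* x, int n,
                   int H, int W, int B, int C,
                   int k1, int k2, int k3,
                   int p1, int p2, int p3,
                   int s1, int s2, int s3,
                   int Ho, int Wo, int Bo,
                   arma::mat& Xcol) {
  const long planeW = (long)H;            // stride of w index
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (long)H * W * B * (ci + (long)C * n);
    for (int kb = 0; kb < k3; ++kb) {
      for (int kw = 0; kw < k2; ++kw) {
        for (int kh = 0; kh < k1; ++kh) {
          long q = kh + (long)k1 * (kw + (long)k2 * (kb + (long)k3 * ci));
          double* col = Xcol.colptr(q);
          // valid ho range for stride-1 fast path
          int hoff = kh - p1;
          int h_lo = std::max(0, -hoff);
          int h_hi = std::min(Ho, H - hoff);
          for (int bo = 0; bo < Bo; ++bo) {
            int bi = bo * s3 - p3 + kb;
            bool bok = (bi >= 0 && bi < B);
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * s2 - p2 + kw;
              double* dst = col + (long)Ho * (wo + (long)Wo * bo);
              if (!bok || wi < 0 || wi >= W) {
                std::fill(dst, dst + Ho, 0.0);
                continue;
              }
              const double* src = xc + planeW * (wi + (long)W * bi);
              if (s1 == 1) {
                if (h_lo > 0) std::fill(dst, dst + std::min(h_lo, Ho), 0.0);
                if (h_hi > h_lo)
                  std::memcpy(dst + h_lo, src + h_lo + hoff,
                              (h_hi - h_lo) * sizeof(double));
                if (h_hi < Ho)
                  std::fill(dst + std::max(h_hi, 0), dst + Ho, 0.0);
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  int hi = ho * s1 - p1 + kh;
                  dst[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back onto the input gradient.
static void col2im(double* dx, const arma::mat& dXcol, int n,
                   int H, int W, int B, int C,
                   int k1, int k2, int k3,
                   int p1, int p2, int p3,
                   int s1, int s2, int s3,
                   int Ho, int Wo, int Bo) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (long)H * W * B * (ci + (long)C * n);
    for (int kb = 0; kb < k3; ++kb) {
      for (int kw = 0; kw < k2; ++kw) {
        for (int kh = 0; kh < k1; ++kh) {
          long q = kh + (long)k1 * (kw + (long)k2 * (kb + (long)k3 * ci));
          const double* col = dXcol.colptr(q);
          int hoff = kh - p1;
          int h_lo = std::max(0, -hoff);
          int h_hi = std::min(Ho, H - hoff);
          for (int bo = 0; bo < Bo; ++bo) {
            int bi = bo * s3 - p3 + kb;
            if (bi < 0 || bi >= B) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * s2 - p2 + kw;
              if (wi < 0 || wi >= W) continue;
              const double* src = col + (long)Ho * (wo + (long)Wo * bo);
              double* dst = xc + (long)H * (wi + (long)W * bi);
              if (s1 == 1) {
                for (int ho = h_lo; ho < h_hi; ++ho)
                  dst[ho + hoff] += src[ho];
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  int hi = ho * s1 - p1 + kh;
                  if (hi >= 0 && hi < H) dst[hi] += src[ho];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w,
                                 IntegerVector pad, IntegerVector stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], B = xd[2], C = xd[3], N = xd[4];
  int k1 = wd[0], k2 = wd[1], k3 = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: input has %d channels, weights expect %d", C, Cin);
  int Ho = out_sz(H, pad[0], k1, stride[0]);
  int Wo = out_sz(W, pad[1], k2, stride[1]);
  int Bo = out_sz(B, pad[2], k3, stride[2]);
  if (Ho < 1 || Wo < 1 || Bo < 1)
    stop("conv3d: kernel larger than padded input");
  long P = (long)Ho * Wo * Bo, Q = (long)k1 * k2 * k3 * Cin;
  NumericVector y((long)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Bo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), Q, Cout, false, true);
  arma::mat Xcol(P, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, H, W, B, C, k1, k2, k3,
           pad[0], pad[1], pad[2], stride[0], stride[1], stride[2],
           Ho, Wo, Bo, Xcol);
    arma::mat Y(y.begin() + (long)P * Cout * n, P, Cout, false, true);
    Y = Xcol * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         IntegerVector pad, IntegerVector stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], B = xd[2], C = xd[3], N = xd[4];
  int k1 = wd[0], k2 = wd[1], k3 = wd[2], Cin = wd[3], Cout = wd[4];
  int Ho = yd[0], Wo = yd[1], Bo = yd[2];
  long P = (long)Ho * Wo * Bo, Q = (long)k1 * k2 * k3 * Cin;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), Q, Cout, false, true);
  arma::mat dWm(dw.begin(), Q, Cout, false, true);
  arma::mat Xcol(P, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, H, W, B, C, k1, k2, k3,
           pad[0], pad[1], pad[2], stride[0], stride[1], stride[2],
           Ho, Wo, Bo, Xcol);
    arma::mat dY(const_cast<double*>(dy.begin()) + (long)P * Cout * n,
                 P, Cout, false, true);
    dWm += Xcol.t() * dY;
    arma::mat dXcol = dY * Wm.t();
    col2im(dx.begin(), dXcol, n, H, W, B, C, k1, k2, k3,
           pad[0], pad[1], pad[2], stride[0], stride[1], stride[2],
           Ho, Wo, Bo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Adaptive max pooling: each output cell (i) along an axis of size M pooled to
// size t covers input range [floor(i*M/t), ceil((i+1)*M/t)).  With t =
// floor(M/q) this realizes window-q pooling that also absorbs the remainder.
// [[Rcpp::export]]
List cpp_maxpool3d_forward(NumericVector x, IntegerVector tdim) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], B = xd[2], C = xd[3], N = xd[4];
  int Ho = tdim[0], Wo = tdim[1], Bo = tdim[2];
  NumericVector y((long)Ho * Wo * Bo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, Bo, C, N);
  idx.attr("dim") = y.attr("dim");
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int bo = 0; bo < Bo; ++bo) {
        int b0 = (int)((long)bo * B / Bo), b1 = (int)(((long)bo + 1) * B + Bo - 1) / Bo;
        for (int wo = 0; wo < Wo; ++wo) {
          int w0 = (int)((long)wo * W / Wo), w1 = (int)(((long)wo + 1) * W + Wo - 1) / Wo;
          for (int ho = 0; ho < Ho; ++ho, ++o) {
            int h0 = (int)((long)ho * H / Ho), h1 = (int)(((long)ho + 1) * H + Ho - 1) / Ho;
            double best = R_NegInf;
            long besti = -1;
            for (int b = b0; b < b1; ++b)
              for (int w2 = w0; w2 < w1; ++w2)
                for (int h = h0; h < h1; ++h) {
                  long i = idx5(h, w2, b, c, n, H, W, B, C);
                  if (x[i] > best) { best = x[i]; besti = i; }
                }
            y[o] = best;
            idx[o] = (int)(besti + 1);  // 1-based for R
          }
        }
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_backward(NumericVector dy, IntegerVector idx,
                                     IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (long o = 0; o < dy.size(); ++o) dx[idx[o] - 1] += dy[o];
  return dx;
}

// Nearest-neighbour upsampling to an explicit target shape (the decoder's
// "deconvolution" resize step; exact inverse bookkeeping for odd pooled axes).
// [[Rcpp::export]]
NumericVector cpp_upsample3d_forward(NumericVector x, IntegerVector tdim) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], B = xd[2], C = xd[3], N = xd[4];
  int Ho = tdim[0], Wo = tdim[1], Bo = tdim[2];
  NumericVector y((long)Ho * Wo * Bo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Bo, C, N);
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int bo = 0; bo < Bo; ++bo) {
        int b = (int)((long)bo * B / Bo);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = (int)((long)wo * W / Wo);
          for (int ho = 0; ho < Ho; ++ho, ++o)
            y[o] = x[idx5((int)((long)ho * H / Ho), w, b, c, n, H, W, B, C)];
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_backward(NumericVector dy, IntegerVector xdim) {
  IntegerVector yd = dy.attr("dim");
  int H = xdim[0], W = xdim[1], B = xdim[2], C = xdim[3], N = xdim[4];
  int Ho = yd[0], Wo = yd[1], Bo = yd[2];
  NumericVector dx((long)H * W * B * C * N);
  dx.attr("dim") = xdim;
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int bo = 0; bo < Bo; ++bo) {
        int b = (int)((long)bo * B / Bo);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = (int)((long)wo * W / Wo);
          for (int ho = 0; ho < Ho; ++ho, ++o)
            dx[idx5((int)((long)ho * H / Ho), w, b, c, n, H, W, B, C)] += dy[o];
        }
      }
  return dx;
}
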