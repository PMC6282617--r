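#include <Rcpp.h>
using namespace Rcpp;

// Image batches are column-major arrays of dim (H, W, C, N).
// im2col rows are indexed r = ho + Hout*(wo + Wout*n)  (ho fastest),
// columns c = kh + k*(kw + k*ci), so that matrix(W, k*k*Cin, Cout)
// built from an (k, k, Cin, Cout) weight array lines up directly.

// [[Rcpp::export]]
NumericMatrix im2col_hwcn(NumericVector x, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Hout * Wout * N, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Hout * Wout * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        double *pcol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *pim = px + ((R_xlen_t)n * C + ci) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride - pad + kw;
            double *prow = pcol + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            if (wi < 0 || wi >= W) continue;
            const double *pin = pim + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              prow[ho] = pin[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col_hwcn: accumulates column gradients back
// into an input-shaped (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector col2im_hwcn(NumericMatrix cols, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *po = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)Hout * Wout * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * ci);
        const double *pcol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          double *pim = px + ((R_xlen_t)n * C + ci) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            const double *prow = pcol + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
            double *pin = pim + (R_xlen_t)wi * H;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              pin[hi] += prow[ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Max pooling with argmax bookkeeping (used by the resnet50 stem).
// Returns list(y, argmax) where argmax holds 1-based linear indices
// into the input array.
// [[Rcpp::export]]
List maxpool_hwcn(NumericVector x, int H, int W, int C, int N,
                  int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Hout * Wout * C * N);
  IntegerVector amax((R_xlen_t)Hout * Wout * C * N);
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < C; ++ci) {
      const R_xlen_t base = ((R_xlen_t)n * C + ci) * H * W;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho, ++o) {
          double best = R_NegInf;
          R_xlen_t bidx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t idx = base + (R_xlen_t)wi * H + hi;
              if (px[idx] > best) { best = px[idx]; bidx = idx; }
            }
          }
          y[o] = best;
          amax[o] = (int)(bidx + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  amax.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}
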