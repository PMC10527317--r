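#include <Rcpp.h>
using namespace Rcpp;

// Volume layout: column-major (D, H, W, C). Patch matrix layout: rows are
// output positions with output-depth fastest, columns are kernel offsets with
// kernel-depth fastest then kernel-height, kernel-width, input channel. This
// matches reshaping an R weight array (kd, kh, kw, Cin, Cout) to a matrix
// with kd*kh*kw*Cin rows.

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector vol, IntegerVector dims, IntegerVector ksize,
                       IntegerVector stride, IntegerVector pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int kd = ksize[0], kh = ksize[1], kw = ksize[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int nrow = od * oh * ow;
  const int ncol = kd * kh * kw * C;
  NumericMatrix out(nrow, ncol);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int wk = 0; wk < kw; ++wk) {
      for (int hk = 0; hk < kh; ++hk) {
        for (int dk = 0; dk < kd; ++dk) {
          const int col = dk + kd * (hk + kh * (wk + kw * c));
          double *ocol = o + (R_xlen_t)col * nrow;
          for (int wo = 0; wo < ow; ++wo) {
            const int wi = wo * sw - pw + wk;
            const bool wok = (wi >= 0 && wi < W);
            for (int ho = 0; ho < oh; ++ho) {
              const int hi = ho * sh - ph + hk;
              const bool hok = wok && (hi >= 0 && hi < H);
              const int rbase = od * (ho + oh * wo);
              if (!hok) continue;
              const double *vbase = v + (R_xlen_t)hi * D + (R_xlen_t)wi * D * H
                + (R_xlen_t)c * D * H * W;
              for (int do_ = 0; do_ < od; ++do_) {
                const int di = do_ * sd - pd + dk;
                if (di < 0 || di >= D) continue;
                ocol[rbase + do_] = vbase[di];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix col, IntegerVector dims, IntegerVector ksize,
                       IntegerVector stride, IntegerVector pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int kd = ksize[0], kh = ksize[1], kw = ksize[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  const int nrow = od * oh * ow;
  NumericVector vol((R_xlen_t)D * H * W * C);
  double *v = vol.begin();
  const double *cm = col.begin();
  for (int c = 0; c < C; ++c) {
    for (int wk = 0; wk < kw; ++wk) {
      for (int hk = 0; hk < kh; ++hk) {
        for (int dk = 0; dk < kd; ++dk) {
          const int colix = dk + kd * (hk + kh * (wk + kw * c));
          const double *ccol = cm + (R_xlen_t)colix * nrow;
          for (int wo = 0; wo < ow; ++wo) {
            const int wi = wo * sw - pw + wk;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < oh; ++ho) {
              const int hi = ho * sh - ph + hk;
              if (hi < 0 || hi >= H) continue;
              const int rbase = od * (ho + oh * wo);
              double *vbase = v + (R_xlen_t)hi * D + (R_xlen_t)wi * D * H
                + (R_xlen_t)c * D * H * W;
              for (int do_ = 0; do_ < od; ++do_) {
                const int di = do_ * sd - pd + dk;
                if (di < 0 || di >= D) continue;
                vbase[di] += ccol[rbase + do_];
              }
            }
          }
        }
      }
    }
  }
  vol.attr("dim") = dims;
  return vol;
}

// Batched variants: x is (D,H,W,C,N); patch rows are grouped sample-major,
// giving one GEMM per convolution per minibatch.

// [[Rcpp::export]]
NumericMatrix im2col3d_batch(NumericVector vol, IntegerVector dims, IntegerVector ksize,
                             IntegerVector stride, IntegerVector pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], N = dims[4];
  const int od = (D + 2 * pad[0] - ksize[0]) / stride[0] + 1;
  const int oh = (H + 2 * pad[1] - ksize[1]) / stride[1] + 1;
  const int ow = (W + 2 * pad[2] - ksize[2]) / stride[2] + 1;
  const R_xlen_t osp = (R_xlen_t)od * oh * ow;
  const int ncol = ksize[0] * ksize[1] * ksize[2] * C;
  NumericMatrix out(osp * N, ncol);
  const R_xlen_t voln = (R_xlen_t)D * H * W * C;
  IntegerVector d4 = IntegerVector::create(D, H, W, C);
  for (int n = 0; n < N; ++n) {
    NumericVector sub(voln);
    std::copy(vol.begin() + n * voln, vol.begin() + (n + 1) * voln, sub.begin());
    NumericMatrix one = im2col3d(sub, d4, ksize, stride, pad);
    for (int c = 0; c < ncol; ++c) {
      std::copy(one.begin() + (R_xlen_t)c * osp,
                one.begin() + (R_xlen_t)(c + 1) * osp,
                out.begin() + (R_xlen_t)c * osp * N + (R_xlen_t)n * osp);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3d_batch(NumericMatrix col, IntegerVector dims, IntegerVector ksize,
                             IntegerVector stride, IntegerVector pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], N = dims[4];
  const int od = (D + 2 * pad[0] - ksize[0]) / stride[0] + 1;
  const int oh = (H + 2 * pad[1] - ksize[1]) / stride[1] + 1;
  const int ow = (W + 2 * pad[2] - ksize[2]) / stride[2] + 1;
  const R_xlen_t osp = (R_xlen_t)od * oh * ow;
  const int ncol = col.ncol();
  const R_xlen_t voln = (R_xlen_t)D * H * W * C;
  NumericVector out(voln * N);
  IntegerVector d4 = IntegerVector::create(D, H, W, C);
  for (int n = 0; n < N; ++n) {
    NumericMatrix one(osp, ncol);
    for (int c = 0; c < ncol; ++c) {
      std::copy(col.begin() + (R_xlen_t)c * osp * N + (R_xlen_t)n * osp,
                col.begin() + (R_xlen_t)c * osp * N + (R_xlen_t)(n + 1) * osp,
                one.begin() + (R_xlen_t)c * osp);
    }
    NumericVector sub = col2im3d(one, d4, ksize, stride, pad);
    std::copy(sub.begin(), sub.end(), out.begin() + n * voln);
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C, N);
  return out;
}
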