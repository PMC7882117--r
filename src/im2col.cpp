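#include <Rcpp.h>
using namespace Rcpp;

// im2col for (h, w, cin, n) arrays: rows ordered position-major within each
// image, images stacked; column order (di, dj, c) matches matrix(W, k*k*cin).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], cin = d[2], n = d[3];
  int oh = h - k + 1, ow = w - k + 1;
  int P = oh * ow;
  NumericMatrix M(P * n, k * k * cin);
  const double *px = x.begin();
  double *pm = M.begin();
  for (int c = 0; c < cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = di + k * dj + k * k * c;
        double *dst = pm + (R_xlen_t)col * P * n;
        for (int img = 0; img < n; ++img) {
          const double *src = px + (R_xlen_t)h * w * (c + (R_xlen_t)cin * img);
          double *out = dst + (R_xlen_t)img * P;
          for (int oj = 0; oj < ow; ++oj) {
            const double *colsrc = src + di + (R_xlen_t)h * (oj + dj);
            double *colout = out + (R_xlen_t)oj * oh;
            for (int oi = 0; oi < oh; ++oi) colout[oi] = colsrc[oi];
          }
        }
      }
    }
  }
  return M;
}

// adjoint of cpp_im2col: scatter-add column gradients back into (h,w,cin,n)
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int k, int h, int w, int cin,
                         int n) {
  int oh = h - k + 1, ow = w - k + 1;
  int P = oh * ow;
  NumericVector dx((R_xlen_t)h * w * cin * n);
  dx.attr("dim") = IntegerVector::create(h, w, cin, n);
  const double *pm = dM.begin();
  double *px = dx.begin();
  for (int c = 0; c < cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = di + k * dj + k * k * c;
        const double *src0 = pm + (R_xlen_t)col * P * n;
        for (int img = 0; img < n; ++img) {
          double *dst = px + (R_xlen_t)h * w * (c + (R_xlen_t)cin * img);
          const double *src = src0 + (R_xlen_t)img * P;
          for (int oj = 0; oj < ow; ++oj) {
            double *colout = dst + di + (R_xlen_t)h * (oj + dj);
            const double *colsrc = src + (R_xlen_t)oj * oh;
            for (int oi = 0; oi < oh; ++oi) colout[oi] += colsrc[oi];
          }
        }
      }
    }
  }
  return dx;
}

// (oh*ow*n, cout) matrix -> (oh, ow, cout, n) array
// [[Rcpp::export]]
NumericVector cpp_mat_to_feat(NumericMatrix Y, int oh, int ow, int cout,
                              int n) {
  NumericVector out((R_xlen_t)oh * ow * cout * n);
  out.attr("dim") = IntegerVector::create(oh, ow, cout, n);
  int P = oh * ow;
  const double *py = Y.begin();
  double *po = out.begin();
  for (int c = 0; c < cout; ++c) {
    const double *col = py + (R_xlen_t)c * P * n;
    for (int img = 0; img < n; ++img) {
      const double *src = col + (R_xlen_t)img * P;
      double *dst = po + (R_xlen_t)P * (c + (R_xlen_t)cout * img);
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  }
  return out;
}

// (oh, ow, cout, n) array -> (oh*ow*n, cout) matrix (inverse of above)
// [[Rcpp::export]]
NumericMatrix cpp_feat_to_mat(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int oh = d[0], ow = d[1], cout = d[2], n = d[3];
  int P = oh * ow;
  NumericMatrix M((R_xlen_t)P * n, cout);
  const double *px = x.begin();
  double *pm = M.begin();
  for (int c = 0; c < cout; ++c) {
    double *dst0 = pm + (R_xlen_t)c * P * n;
    for (int img = 0; img < n; ++img) {
      const double *src = px + (R_xlen_t)P * (c + (R_xlen_t)cout * img);
      double *dst = dst0 + (R_xlen_t)img * P;
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  }
  return M;
}
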