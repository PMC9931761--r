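// Fused numeric kernels for the forward model and the per-pixel
// Beer-Lambert chain. These are exact re-expressions of the staged R
// implementations (the test suite asserts equality); they exist to keep
// cohort-scale simulation and inversion inside interactive budgets.

#include <Rcpp.h>
using namespace Rcpp;

// Forward model: intensities for all four bands from a planted StO2
// field. S has length n (= T*H*W, time fastest); returns a T x 4 x H x W
// array with I = reference_t * 10^-(slope_b * S + const_b) + noise,
// clamped at 0. The reference may vary per frame (illumination);
// noise uses R's RNG (deterministic under set.seed).
// [[Rcpp::export(name = ".cppForwardBands")]]
NumericVector cppForwardBands(NumericVector S, NumericVector slope,
                              NumericVector konst, NumericVector reference,
                              double noise_sd, int T, int H, int W) {
  const R_xlen_t n = S.size();
  NumericVector out((R_xlen_t)T * 4 * H * W);
  out.attr("dim") = IntegerVector::create(T, 4, H, W);
  const double ln10 = M_LN10;
  RNGScope scope;
  for (int b = 0; b < 4; ++b) {
    const double sl = slope[b], ko = konst[b];
    // output layout: t + T*(b + 4*(h + H*w)); S layout: t + T*(h + H*w)
    for (R_xlen_t p = 0; p < n / T; ++p) {
      const R_xlen_t off_in = p * T;
      const R_xlen_t off_out = (R_xlen_t)T * (b + 4 * p);
      for (int t = 0; t < T; ++t) {
        const double ref_t = reference[reference.size() == 1 ? 0 : t];
        double v = ref_t * std::exp(-ln10 * (sl * S[off_in + t] + ko));
        if (noise_sd > 0) {
          v += norm_rand() * noise_sd;
          if (v < 0) v = 0;
        }
        out[off_out + t] = v;
      }
    }
  }
  return out;
}

// Fused absorbance -> 4x4 inversion -> StO2 for a T x 4 x H x W
// intensity array. inv is the 4x4 inverse of the design matrix
// [eps_hbo2 | eps_hb | eps_mel | 1] (column-major). Returns the T*H*W
// StO2 vector (clipped to [0,1], NaN where total hemoglobin <= 0).
// [[Rcpp::export(name = ".cppSto2Chain")]]
NumericVector cppSto2Chain(NumericVector I, NumericMatrix inv,
                           double reference, double floor_frac,
                           int T, int H, int W) {
  const R_xlen_t npix = (R_xlen_t)H * W;
  NumericVector out(Dimension((size_t)T, (size_t)H, (size_t)W));
  const double fl = floor_frac * reference;
  const double inv_ref = 1.0 / reference;
  const double i11 = inv(0, 0), i12 = inv(0, 1), i13 = inv(0, 2),
               i14 = inv(0, 3);
  const double i21 = inv(1, 0), i22 = inv(1, 1), i23 = inv(1, 2),
               i24 = inv(1, 3);
  for (R_xlen_t p = 0; p < npix; ++p) {
    const R_xlen_t base = (R_xlen_t)T * 4 * p;
    for (int t = 0; t < T; ++t) {
      double A[4];
      for (int b = 0; b < 4; ++b) {
        double v = I[base + (R_xlen_t)T * b + t];
        if (v < fl) v = fl;
        A[b] = -std::log10(v * inv_ref);
      }
      const double c1 = i11 * A[0] + i12 * A[1] + i13 * A[2] + i14 * A[3];
      const double c2 = i21 * A[0] + i22 * A[1] + i23 * A[2] + i24 * A[3];
      const double tot = c1 + c2;
      double s;
      if (tot <= 0) s = R_NaN;
      else {
        s = c1 / tot;
        if (s < 0) s = 0; else if (s > 1) s = 1;
      }
      out[p * T + t] = s;
    }
  }
  return out;
}
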