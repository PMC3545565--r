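#include <Rcpp.h>
using namespace Rcpp;

// Flat-structuring-element erosion/dilation with reflection padding, so the
// output has the same length as the input and edges see mirrored samples.
// se must be odd; half-width h = (se - 1) / 2.

static NumericVector morph_core(const NumericVector& x, int se, bool dilate) {
  int n = x.size();
  int h = (se - 1) / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = dilate ? R_NegInf : R_PosInf;
    for (int k = -h; k <= h; ++k) {
      int j = i + k;
      if (j < 0) j = -j;                 // reflect (no edge repeat)
      if (j >= n) j = 2 * (n - 1) - j;
      double v = x[j];
      if (dilate) { if (v > acc) acc = v; }
      else        { if (v < acc) acc = v; }
    }
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".morph_erode")]]
NumericVector morph_erode(NumericVector x, int se) {
  if (se < 1 || se % 2 == 0) stop("structuring element length must be odd and >= 1");
  if (se > x.size()) stop("structuring element longer than signal");
  return morph_core(x, se, false);
}

// [[Rcpp::export(name = ".morph_dilate")]]
NumericVector morph_dilate(NumericVector x, int se) {
  if (se < 1 || se % 2 == 0) stop("structuring element length must be odd and >= 1");
  if (se > x.size()) stop("structuring element longer than signal");
  return morph_core(x, se, true);
}
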