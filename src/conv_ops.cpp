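// Patch-matrix construction for 3x3 same-padded convolution and its
// adjoint. Block order matches OFFSETS3 in R/nn_layers.R: index k runs
// dy = -1,0,1 fastest, then dx = -1,0,1; within a block, channels.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int h, int w, int c) {
  NumericMatrix out(h * w, 9 * c);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int k = 0; k < 9; ++k) {
    int dy = (k % 3) - 1;
    int dx = (k / 3) - 1;
    for (int ch = 0; ch < c; ++ch) {
      double* col = op + (size_t)(k * c + ch) * (size_t)(h * w);
      const double* src = xp + (size_t)ch * (size_t)(h * w);
      for (int j = 0; j < w; ++j) {
        int js = j + dx;
        if (js < 0 || js >= w) {
          for (int i = 0; i < h; ++i) col[i + j * h] = 0.0;
          continue;
        }
        for (int i = 0; i < h; ++i) {
          int is = i + dy;
          col[i + j * h] = (is < 0 || is >= h) ? 0.0 : src[is + js * h];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix g, int h, int w, int c) {
  NumericVector out(h * w * c);
  double* op = out.begin();
  const double* gp = g.begin();
  for (int k = 0; k < 9; ++k) {
    int dy = (k % 3) - 1;
    int dx = (k / 3) - 1;
    for (int ch = 0; ch < c; ++ch) {
      const double* col = gp + (size_t)(k * c + ch) * (size_t)(h * w);
      double* dst = op + (size_t)ch * (size_t)(h * w);
      for (int j = 0; j < w; ++j) {
        int js = j + dx;
        if (js < 0 || js >= w) continue;
        for (int i = 0; i < h; ++i) {
          int is = i + dy;
          if (is < 0 || is >= h) continue;
          dst[is + js * h] += col[i + j * h];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, c);
  return out;
}
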