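// small numeric helpers on hot paths

#include <Rcpp.h>
using namespace Rcpp;

// row-wise argmax of (2 * m[i,j] - offset[j]), ties to the smallest j;
// this is the nearest-neighbour rule argmin_j ||q_i - c_j||^2 with
// m = Q C^T and offset_j = ||c_j||^2. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_argmax_rows(NumericMatrix m, NumericVector offset) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerVector out(nr);
  std::vector<double> best(nr, R_NegInf);
  std::vector<int> arg(nr, 1);
  for (int j = 0; j < nc; ++j) {
    const double off = offset[j];
    const double* col = &m(0, j);
    for (int i = 0; i < nr; ++i) {
      double v = 2.0 * col[i] - off;
      if (v > best[i]) { best[i] = v; arg[i] = j + 1; }
    }
  }
  for (int i = 0; i < nr; ++i) out[i] = arg[i];
  return out;
}

// GELU (tanh formulation) and its exact derivative, elementwise; dims and
// other attributes of the input are preserved.
// [[Rcpp::export]]
NumericVector cpp_gelu(NumericVector x) {
  static const double c = 0.7978845608028654;  // sqrt(2/pi)
  NumericVector out = clone(x);
  const int n = out.size();
  for (int i = 0; i < n; ++i) {
    double v = out[i];
    double t = std::tanh(c * (v + 0.044715 * v * v * v));
    out[i] = 0.5 * v * (1.0 + t);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_grad(NumericVector x) {
  static const double c = 0.7978845608028654;
  NumericVector out = clone(x);
  const int n = out.size();
  for (int i = 0; i < n; ++i) {
    double v = out[i];
    double t = std::tanh(c * (v + 0.044715 * v * v * v));
    out[i] = 0.5 * (1.0 + t) +
      0.5 * v * (1.0 - t * t) * c * (1.0 + 3.0 * 0.044715 * v * v);
  }
  return out;
}

// row-wise maximum of a matrix
// [[Rcpp::export]]
NumericVector cpp_row_max(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr, R_NegInf);
  for (int j = 0; j < nc; ++j) {
    const double* col = &m(0, j);
    for (int i = 0; i < nr; ++i)
      if (col[i] > out[i]) out[i] = col[i];
  }
  return out;
}
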