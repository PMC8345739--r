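#include <Rcpp.h>
using namespace Rcpp;

// First-order recursion out[k+1] = E[k] * out[k] + b[k], out[0] = 0.
// Inner loop of the exact piecewise-linear exponential convolution.
// [[Rcpp::export(name = ".exp_recur_cpp")]]
NumericVector exp_recur(NumericVector E, NumericVector b) {
  int n = E.size();
  NumericVector out(n + 1);
  out[0] = 0.0;
  for (int k = 0; k < n; ++k)
    out[k + 1] = E[k] * out[k] + b[k];
  return out;
}
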