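#include <Rcpp.h>
using namespace Rcpp;

// Causal direct-form I recursion
//   y[n] = sum_{k=0..M} b[k] x[n-k] - sum_{k=1..N} a[k] y[n-k]
// xh / yh carry the last M inputs and N outputs (most recent first) so a
// signal may be processed in chunks with bit-identical results.
// [[Rcpp::export]]
List iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                    NumericVector xh, NumericVector yh) {
  const int M = b.size() - 1;      // feed-forward order
  const int N = a.size();          // feedback order (a excludes leading 1)
  const int n = x.size();
  NumericVector y(n);
  std::vector<double> xhist(xh.begin(), xh.end());
  std::vector<double> yhist(yh.begin(), yh.end());
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i]))
      stop("non-finite input sample at position %d", i + 1);
    double acc = b[0] * x[i];
    for (int k = 1; k <= M; ++k) acc += b[k] * xhist[k - 1];
    for (int k = 1; k <= N; ++k) acc -= a[k - 1] * yhist[k - 1];
    // shift histories (most recent first)
    for (int k = M - 1; k > 0; --k) xhist[k] = xhist[k - 1];
    if (M > 0) xhist[0] = x[i];
    for (int k = N - 1; k > 0; --k) yhist[k] = yhist[k - 1];
    if (N > 0) yhist[0] = acc;
    y[i] = acc;
  }
  return List::create(_["y"] = y,
                      _["x_hist"] = NumericVector(xhist.begin(), xhist.end()),
                      _["y_hist"] = NumericVector(yhist.begin(), yhist.end()));
}
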