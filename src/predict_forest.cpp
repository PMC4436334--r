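#include <Rcpp.h>
using namespace Rcpp;

// Ensemble-mean prediction by direct traversal of a stored regression
// forest (child arrays, split variables, split values per tree; terminal
// nodes have child id 0 and carry the node prediction in the split-value
// slot; condition x[var] <= value descends left). Equivalence with the
// forest's own predict method is asserted in the test suite; this path
// exists because density prediction visits every pixel of every image.

// [[Rcpp::export(name = ".predictForestMean")]]
NumericVector predictForestMean(List childLeft, List childRight,
                                List splitVar, List splitVal,
                                NumericMatrix X) {
  const int nTrees = childLeft.size();
  const R_xlen_t n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < nTrees; ++t) {
    IntegerVector left = childLeft[t];
    IntegerVector right = childRight[t];
    IntegerVector var = splitVar[t];
    NumericVector val = splitVal[t];
    const int *lp = INTEGER(left);
    const int *rp = INTEGER(right);
    const int *vp = INTEGER(var);
    const double *sp = REAL(val);
    const double *xp = REAL(X);
    for (R_xlen_t i = 0; i < n; ++i) {
      int node = 0;
      while (lp[node] != 0) {
        const double x = xp[i + (R_xlen_t)vp[node] * n];
        node = (x <= sp[node]) ? lp[node] : rp[node];
      }
      out[i] += sp[node];
    }
  }
  const double inv = 1.0 / nTrees;
  for (R_xlen_t i = 0; i < n; ++i) out[i] *= inv;
  return out;
}
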