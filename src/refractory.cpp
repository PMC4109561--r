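#include <Rcpp.h>
using namespace Rcpp;

// Sequential refractory scan: keep a spike only if it falls at least
// `refractory` seconds after the last *kept* spike of the same group.
// `times` must be sorted non-decreasing within each group and groups must be
// contiguous (vector sorted by group, then time). The first spike of every
// group is always kept.
// [[Rcpp::export]]
LogicalVector refractory_keep_grouped(NumericVector times, IntegerVector group,
                                      double refractory) {
  R_xlen_t n = times.size();
  if (group.size() != n) stop("times and group must have equal length");
  LogicalVector keep(n);
  double last = R_NegInf;
  int cur = NA_INTEGER;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i == 0 || group[i] != cur) {
      cur = group[i];
      last = R_NegInf;
    }
    if (times[i] - last >= refractory) {
      keep[i] = true;
      last = times[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}
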