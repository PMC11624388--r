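#include <Rcpp.h>
using namespace Rcpp;

// Per-second proximity tally split by functional area.
// X, Y: T x n coordinate matrices (gap-free); A: T x n area codes
// (0 excluded, 1 resting, 2 feeding). A dyad-second counts for an area when
// both cows carry that area's code and their Euclidean distance is <= radius.
// [[Rcpp::export]]
List tally_contacts_cpp(NumericMatrix X, NumericMatrix Y,
                        IntegerMatrix A, double radius) {
  const int T = X.nrow(), n = X.ncol();
  const double r2 = radius * radius;
  IntegerMatrix rest(n, n), feed(n, n);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n - 1; ++i) {
      const int ai = A(t, i);
      if (ai == 0) continue;
      const double xi = X(t, i), yi = Y(t, i);
      for (int j = i + 1; j < n; ++j) {
        if (A(t, j) != ai) continue;
        const double dx = xi - X(t, j), dy = yi - Y(t, j);
        if (dx * dx + dy * dy <= r2) {
          if (ai == 1) { rest(i, j)++; } else { feed(i, j)++; }
        }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      rest(j, i) = rest(i, j);
      feed(j, i) = feed(i, j);
    }
  return List::create(rest, feed);
}
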