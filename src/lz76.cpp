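#include <Rcpp.h>
using namespace Rcpp;

// LZ76 exhaustive-history parse count (Kaspar & Schuster 1987).
// Counts the number of phrases in the self-delimiting parse where each new
// phrase is the longest substring reproducible from the existing history
// (overlapping copies allowed) plus one innovative symbol.
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(const IntegerVector& bits) {
  const int n = bits.size();
  if (n == 0) stop("empty sequence");
  for (int j = 0; j < n; ++j) {
    if (bits[j] != 0 && bits[j] != 1) stop("sequence must be binary (0/1)");
  }
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
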