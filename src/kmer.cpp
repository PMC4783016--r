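#include <Rcpp.h>
using namespace Rcpp;

// Common-word mass between two coded k-mer profiles: sum over shared codes of
// min(count_x, count_y).  Profiles carry strictly increasing code vectors, so
// a single merge pass suffices.
//
// d = 1 - shared / (min(L_x, L_y) - k + 1), clamped to [0, 1].  The
// denominator is the maximum possible number of words of the shorter
// sequence; words skipped for ambiguity codes reduce only the numerator.

// [[Rcpp::export(name = ".kmer_profile_distance_cpp")]]
double kmer_profile_distance_cpp(IntegerVector codes_x, IntegerVector counts_x,
                                 IntegerVector codes_y, IntegerVector counts_y,
                                 int len_x, int len_y, int k) {
  int denom = (len_x < len_y ? len_x : len_y) - k + 1;
  if (denom < 1) stop("k exceeds the shorter sequence length");
  double shared = 0;
  int i = 0, j = 0, nx = codes_x.size(), ny = codes_y.size();
  while (i < nx && j < ny) {
    int cx = codes_x[i], cy = codes_y[j];
    if (cx == cy) {
      shared += counts_x[i] < counts_y[j] ? counts_x[i] : counts_y[j];
      ++i; ++j;
    } else if (cx < cy) {
      ++i;
    } else {
      ++j;
    }
  }
  double d = 1.0 - shared / (double)denom;
  if (d < 0) d = 0;
  if (d > 1) d = 1;
  return d;
}
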