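#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// A column is "identical" only when both characters are equal AND unambiguous
// nucleotides; N-N or any IUPAC-code pair scores/counts as a mismatch.
static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline bool identical_col(char a, char b) {
  return a == b && is_acgt(a);
}

struct AlnStats {
  int identical;
  int counted;
  double distance;
};

// Column bookkeeping shared by the DP and the enumeration oracle: terminal
// columns are the leading/trailing gap runs of either string; with
// count_terminal = false they are excluded from the denominator.  An
// alignment whose counted region is empty (pure stagger of disjoint
// strings) is maximally dissimilar by convention: distance = 1.
static AlnStats column_stats(const std::string &ax, const std::string &ay,
                             bool count_terminal) {
  int L = (int)ax.size();
  int lead_x = 0, lead_y = 0, trail_x = 0, trail_y = 0;
  while (lead_x < L && ax[lead_x] == '-') ++lead_x;
  while (lead_y < L && ay[lead_y] == '-') ++lead_y;
  while (trail_x < L && ax[L - 1 - trail_x] == '-') ++trail_x;
  while (trail_y < L && ay[L - 1 - trail_y] == '-') ++trail_y;
  int lead = lead_x > lead_y ? lead_x : lead_y;
  int trail = trail_x > trail_y ? trail_x : trail_y;
  int from = count_terminal ? 0 : lead;
  int to = count_terminal ? L : L - trail;
  int identical = 0, counted = 0;
  for (int c = from; c < to; ++c) {
    ++counted;
    if (ax[c] != '-' && ay[c] != '-' && identical_col(ax[c], ay[c])) ++identical;
  }
  AlnStats st;
  st.identical = identical;
  st.counted = counted;
  st.distance = counted > 0 ? 1.0 - (double)identical / (double)counted : 1.0;
  if (st.distance < 0) st.distance = 0;
  if (st.distance > 1) st.distance = 1;
  return st;
}

// Coverage guard: an end-gap-free optimum between unrelated sequences can be
// a short spurious perfect overlap; if the counted overlap spans less than
// min_overlap_frac of the shorter sequence the pair is maximally dissimilar.
static inline double apply_overlap_guard(double distance, int counted,
                                         int min_len, double frac) {
  if (counted < std::ceil(frac * min_len)) return 1.0;
  return distance;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string x, std::string y, double match, double mismatch,
                  double gap, bool terminal_gaps_free, bool count_terminal_gaps,
                  double min_overlap_frac) {
  int n = (int)x.size(), m = (int)y.size();
  if (n < 1 || m < 1) stop("sequences must be non-empty");
  // H is (n+1) x (m+1), row-major
  std::vector<double> H((size_t)(n + 1) * (m + 1));
  for (int i = 0; i <= n; ++i)
    H[(size_t)i * (m + 1)] = terminal_gaps_free ? 0.0 : i * gap;
  for (int j = 0; j <= m; ++j)
    H[j] = terminal_gaps_free ? 0.0 : j * gap;
  for (int i = 1; i <= n; ++i) {
    const char xi = x[i - 1];
    double *row = &H[(size_t)i * (m + 1)];
    double *prev = &H[(size_t)(i - 1) * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double s = identical_col(xi, y[j - 1]) ? match : mismatch;
      double best = prev[j - 1] + s;           // diagonal
      double up = prev[j] + gap;               // consume x, gap in y
      if (up > best) best = up;
      double left = row[j - 1] + gap;          // consume y, gap in x
      if (left > best) best = left;
      row[j] = best;
    }
  }

  // End cell: with free terminal gaps the optimum may stop before the corner
  // and pad the rest with unpenalized trailing gaps.  Deterministic choice:
  // the corner, then the last column bottom-up, then the last row right-to-left,
  // moving only on a strict improvement.
  int ei = n, ej = m;
  double best_score = H[(size_t)n * (m + 1) + m];
  if (terminal_gaps_free) {
    for (int i = n - 1; i >= 0; --i) {
      double v = H[(size_t)i * (m + 1) + m];
      if (v > best_score) { best_score = v; ei = i; ej = m; }
    }
    for (int j = m - 1; j >= 0; --j) {
      double v = H[(size_t)n * (m + 1) + j];
      if (v > best_score) { best_score = v; ei = n; ej = j; }
    }
  }

  // Traceback from (n, m): trailing gaps down to the end cell, then the DP
  // path with fixed tie order diagonal > up > left.
  std::string ax, ay;
  ax.reserve(n + m); ay.reserve(n + m);
  int i = n, j = m;
  while (i > ei) { ax.push_back(x[i - 1]); ay.push_back('-'); --i; }
  while (j > ej) { ax.push_back('-'); ay.push_back(y[j - 1]); --j; }
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    double h = H[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0) {
      double s = identical_col(x[i - 1], y[j - 1]) ? match : mismatch;
      if (std::abs(h - (H[(size_t)(i - 1) * (m + 1) + (j - 1)] + s)) < eps) {
        ax.push_back(x[i - 1]); ay.push_back(y[j - 1]); --i; --j;
        continue;
      }
    }
    if (i > 0) {
      double upcost = (j == 0 && terminal_gaps_free) ? 0.0 : gap;
      if (std::abs(h - (H[(size_t)(i - 1) * (m + 1) + j] + upcost)) < eps) {
        ax.push_back(x[i - 1]); ay.push_back('-'); --i;
        continue;
      }
    }
    if (j > 0) {
      ax.push_back('-'); ay.push_back(y[j - 1]); --j;
      continue;
    }
    stop("internal error: traceback failed");  // # nocov
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());

  AlnStats st = column_stats(ax, ay, count_terminal_gaps);
  double dist = apply_overlap_guard(st.distance, st.counted,
                                    n < m ? n : m, min_overlap_frac);
  return List::create(_["aligned_x"] = ax, _["aligned_y"] = ay,
                      _["score"] = best_score,
                      _["identical_cols"] = st.identical,
                      _["counted_cols"] = st.counted,
                      _["distance"] = dist);
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration oracle (test-only): walks every monotone lattice
// path (= every global alignment), scores it column by column under the same
// policy, and records the distances attained by the optimal-score alignments.
// Independent of the DP above by construction: no score matrix, no recurrence.
// ---------------------------------------------------------------------------

struct EnumState {
  const std::string *x, *y;
  double match, mismatch, gap, min_overlap_frac;
  bool terminal_free, count_terminal;
  std::string ax, ay;
  double best;
  std::vector<double> best_distances;
  long n_alignments;
};

static double enum_score(EnumState &st) {
  const std::string &ax = st.ax, &ay = st.ay;
  int L = (int)ax.size();
  int lead_x = 0, lead_y = 0, trail_x = 0, trail_y = 0;
  while (lead_x < L && ax[lead_x] == '-') ++lead_x;
  while (lead_y < L && ay[lead_y] == '-') ++lead_y;
  while (trail_x < L && ax[L - 1 - trail_x] == '-') ++trail_x;
  while (trail_y < L && ay[L - 1 - trail_y] == '-') ++trail_y;
  int lead = lead_x > lead_y ? lead_x : lead_y;
  int trail = trail_x > trail_y ? trail_x : trail_y;
  double s = 0;
  for (int c = 0; c < L; ++c) {
    bool terminal = st.terminal_free && (c < lead || c >= L - trail);
    if (ax[c] == '-' || ay[c] == '-') {
      if (!terminal) s += st.gap;
    } else {
      s += identical_col(ax[c], ay[c]) ? st.match : st.mismatch;
    }
  }
  return s;
}

static void enum_rec(EnumState &st, int i, int j) {
  const std::string &x = *st.x, &y = *st.y;
  if (i == (int)x.size() && j == (int)y.size()) {
    ++st.n_alignments;
    double s = enum_score(st);
    const double eps = 1e-9;
    if (s > st.best + eps) {
      st.best = s;
      st.best_distances.clear();
    }
    if (std::abs(s - st.best) <= eps) {
      AlnStats cs = column_stats(st.ax, st.ay, st.count_terminal);
      int min_len = (int)(st.x->size() < st.y->size() ? st.x->size()
                                                      : st.y->size());
      double d = apply_overlap_guard(cs.distance, cs.counted, min_len,
                                     st.min_overlap_frac);
      bool seen = false;
      for (double v : st.best_distances)
        if (std::abs(v - d) < 1e-12) { seen = true; break; }
      if (!seen) st.best_distances.push_back(d);
    }
    return;
  }
  if (i < (int)x.size() && j < (int)y.size()) {
    st.ax.push_back(x[i]); st.ay.push_back(y[j]);
    enum_rec(st, i + 1, j + 1);
    st.ax.pop_back(); st.ay.pop_back();
  }
  if (i < (int)x.size()) {
    st.ax.push_back(x[i]); st.ay.push_back('-');
    enum_rec(st, i + 1, j);
    st.ax.pop_back(); st.ay.pop_back();
  }
  if (j < (int)y.size()) {
    st.ax.push_back('-'); st.ay.push_back(y[j]);
    enum_rec(st, i, j + 1);
    st.ax.pop_back(); st.ay.pop_back();
  }
}

// [[Rcpp::export(name = ".nw_enumerate_cpp")]]
List nw_enumerate_cpp(std::string x, std::string y, double match,
                      double mismatch, double gap, bool terminal_gaps_free,
                      bool count_terminal_gaps, double min_overlap_frac) {
  if (x.size() < 1 || y.size() < 1) stop("sequences must be non-empty");
  if (x.size() > 12 || y.size() > 12)
    stop("enumeration oracle is limited to sequences of length <= 12");
  EnumState st;
  st.x = &x; st.y = &y;
  st.match = match; st.mismatch = mismatch; st.gap = gap;
  st.min_overlap_frac = min_overlap_frac;
  st.terminal_free = terminal_gaps_free; st.count_terminal = count_terminal_gaps;
  st.best = -1e300;
  st.n_alignments = 0;
  enum_rec(st, 0, 0);
  return List::create(_["best_score"] = st.best,
                      _["distances"] = NumericVector(st.best_distances.begin(),
                                                     st.best_distances.end()),
                      _["n_alignments"] = (double)st.n_alignments);
}
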