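#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh). Gap run of length L costs
// gap_open + (L - 1) * gap_extend. free_start makes a leading gap run in
// either sequence cost 0; free_end does the same for trailing runs.
// Traceback ties resolve diagonal > up (consume a) > left (consume b).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

struct NWResult {
  double score;
  std::string aligned_a;
  std::string aligned_b;
};

// matrices flattened row-major: idx = i * (n + 1) + j
static NWResult nw_core(const std::string& a, const std::string& b,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        bool free_start, bool free_end,
                        bool want_traceback) {
  const int m = a.size(), n = b.size();
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF);  // ends in (mis)match
  std::vector<double> X((m + 1) * W, NEG_INF);  // ends consuming a (gap in b)
  std::vector<double> Y((m + 1) * W, NEG_INF);  // ends consuming b (gap in a)

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i)
    X[i * W] = free_start ? 0.0 : gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= n; ++j)
    Y[j] = free_start ? 0.0 : gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int ij = i * W + j, up = (i - 1) * W + j, di = (i - 1) * W + (j - 1),
                le = i * W + (j - 1);
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double best_prev = std::max(M[di], std::max(X[di], Y[di]));
      M[ij] = best_prev + s;
      // trailing free gaps handled after the fill
      X[ij] = std::max(std::max(M[up], Y[up]) + gap_open, X[up] + gap_extend);
      Y[ij] = std::max(std::max(M[le], X[le]) + gap_open, Y[le] + gap_extend);
    }
  }

  // terminal cell / free-end scan
  auto cell_best = [&](int i, int j) {
    const int ij = i * W + j;
    return std::max(M[ij], std::max(X[ij], Y[ij]));
  };
  int end_i = m, end_j = n;
  double score = cell_best(m, n);
  if (free_end) {
    for (int i = 0; i <= m; ++i)
      if (cell_best(i, n) > score) { score = cell_best(i, n); end_i = i; end_j = n; }
    for (int j = 0; j <= n; ++j)
      if (cell_best(m, j) > score) { score = cell_best(m, j); end_i = m; end_j = j; }
  }

  NWResult res;
  res.score = score;
  if (!want_traceback) return res;

  std::string ra, rb;
  // pad free trailing gaps
  for (int i = m; i > end_i; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = n; j > end_j; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = end_i, j = end_j;
  // current layer: 0 = M, 1 = X, 2 = Y; pick best at the end cell,
  // preferring diagonal (M) then up (X) then left (Y)
  const double eps = 1e-9;
  int layer;
  {
    const int ij = i * W + j;
    double best = std::max(M[ij], std::max(X[ij], Y[ij]));
    if (M[ij] >= best - eps) layer = 0;
    else if (X[ij] >= best - eps) layer = 1;
    else layer = 2;
  }
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (i == 0) {  // forced left moves
      ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue;
    }
    if (j == 0) {  // forced up moves
      ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue;
    }
    if (layer == 0) {
      const int di = (i - 1) * W + (j - 1);
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double target = M[ij] - s;
      if (M[di] >= target - eps) layer = 0;
      else if (X[di] >= target - eps) layer = 1;
      else layer = 2;
      --i; --j;
    } else if (layer == 1) {
      const int up = (i - 1) * W + j;
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (j == 0 && free_start) {  // inside free leading run (unreachable here; j>0)
        layer = 1;
      } else if (std::max(M[up], Y[up]) + gap_open >= X[ij] - eps) {
        layer = (M[up] >= Y[up] - eps) ? 0 : 2;
      } else {
        layer = 1;  // extension
      }
      --i;
    } else {
      const int le = i * W + (j - 1);
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (std::max(M[le], X[le]) + gap_open >= Y[ij] - eps) {
        layer = (M[le] >= X[le] - eps) ? 0 : 1;
      } else {
        layer = 2;
      }
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.aligned_a = ra;
  res.aligned_b = rb;
  return res;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool free_start, bool free_end) {
  NWResult r = nw_core(a, b, match, mismatch, gap_open, gap_extend,
                       free_start, free_end, true);
  return List::create(_["score"] = r.score,
                      _["aligned_a"] = r.aligned_a,
                      _["aligned_b"] = r.aligned_b);
}

// [[Rcpp::export(name = ".nw_score_batch_cpp")]]
NumericVector nw_score_batch_cpp(CharacterVector a, CharacterVector b,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend,
                                 bool free_start, bool free_end) {
  const int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NWResult r = nw_core(as<std::string>(a[i]), as<std::string>(b[i]),
                         match, mismatch, gap_open, gap_extend,
                         free_start, free_end, false);
    out[i] = r.score;
  }
  return out;
}

// Batch genotyping: aligns read i to ref i, then reports substitution calls
// at reference indices win_lo..win_hi (0-based, inclusive) where the
// reference base is C or A and the substitution is one of A>G, C>T, C>G, C>A.
// Reference window positions aligned to a gap in the read are reported as
// uncovered. Indel columns never produce calls; N never produces a call.
// [[Rcpp::export(name = ".genotype_batch_cpp")]]
List genotype_batch_cpp(CharacterVector reads, CharacterVector refs,
                        int win_lo, int win_hi,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        bool free_start, bool free_end) {
  const int n = reads.size();
  std::vector<int> call_read, call_pos;
  std::vector<std::string> call_ref, call_alt;
  std::vector<int> gap_read, gap_pos;
  NumericVector scores(n);

  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::string rf = as<std::string>(refs[r]);
    NWResult al = nw_core(rd, rf, match, mismatch, gap_open, gap_extend,
                          free_start, free_end, true);
    scores[r] = al.score;
    int ref_i = -1;  // 0-based index into rf of the current column's ref base
    for (size_t c = 0; c < al.aligned_b.size(); ++c) {
      char rb = al.aligned_b[c];
      char qb = al.aligned_a[c];
      if (rb != '-') ++ref_i;
      if (rb == '-' || ref_i < win_lo) continue;
      if (ref_i > win_hi) break;
      if (qb == '-') {
        gap_read.push_back(r + 1);
        gap_pos.push_back(ref_i);
        continue;
      }
      if (qb == rb || qb == 'N') continue;
      bool tracked = (rb == 'A' && qb == 'G') ||
                     (rb == 'C' && (qb == 'T' || qb == 'G' || qb == 'A'));
      if (!tracked) continue;
      call_read.push_back(r + 1);
      call_pos.push_back(ref_i);
      call_ref.push_back(std::string(1, rb));
      call_alt.push_back(std::string(1, qb));
    }
  }
  return List::create(
      _["call_read"] = wrap(call_read), _["call_pos"] = wrap(call_pos),
      _["call_ref"] = wrap(call_ref), _["call_alt"] = wrap(call_alt),
      _["gap_read"] = wrap(gap_read), _["gap_pos"] = wrap(gap_pos),
      _["score"] = scores);
}

// Exhaustive alignment-path enumeration (no DP): recursion over all gapped
// global alignments with affine run scoring. Used only as a test oracle for
// short sequences; cost is exponential in length.
static double enum_rec(const std::string& a, const std::string& b,
                       int i, int j, int last,  // last move: 0 none, 2 up, 3 left
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       bool free_start, bool free_end) {
  const int m = a.size(), n = b.size();
  if (i == m && j == n) return 0.0;
  double best = NEG_INF;
  if (i < m && j < n) {
    double s = subst(a[i], b[j], match, mismatch);
    best = std::max(best, s + enum_rec(a, b, i + 1, j + 1, 1, match, mismatch,
                                       gap_open, gap_extend, free_start, free_end));
  }
  if (i < m) {  // up: consume a, gap in b
    double cost;
    if (free_start && j == 0) cost = 0.0;
    else if (free_end && j == n) cost = 0.0;
    else cost = (last == 2) ? gap_extend : gap_open;
    best = std::max(best, cost + enum_rec(a, b, i + 1, j, 2, match, mismatch,
                                          gap_open, gap_extend, free_start, free_end));
  }
  if (j < n) {  // left: consume b, gap in a
    double cost;
    if (free_start && i == 0) cost = 0.0;
    else if (free_end && i == m) cost = 0.0;
    else cost = (last == 3) ? gap_extend : gap_open;
    best = std::max(best, cost + enum_rec(a, b, i, j + 1, 3, match, mismatch,
                                          gap_open, gap_extend, free_start, free_end));
  }
  return best;
}

// [[Rcpp::export(name = ".nw_enum_score_cpp")]]
double nw_enum_score_cpp(std::string a, std::string b,
                         double match, double mismatch,
                         double gap_open, double gap_extend,
                         bool free_start, bool free_end) {
  if (a.size() > 12 || b.size() > 12)
    stop("enumeration oracle limited to sequences of length <= 12");
  return enum_rec(a, b, 0, 0, 0, match, mismatch, gap_open, gap_extend,
                  free_start, free_end);
}
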