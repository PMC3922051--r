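#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Traceback ties are resolved diagonal > up > left, where "up" consumes a
// character of `a` (gap in `b`). This fixed preference makes the alignment
// deterministic, which the clustering layer relies on.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");

  NumericMatrix S(n + 1, m + 1);
  // 0 = diag, 1 = up (consume a), 2 = left (consume b)
  IntegerMatrix tb(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; tb(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; tb(0, j) = 2; }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (ai == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      if (d >= u && d >= l)      { S(i, j) = d; tb(i, j) = 0; }
      else if (u >= l)           { S(i, j) = u; tb(i, j) = 1; }
      else                       { S(i, j) = l; tb(i, j) = 2; }
    }
  }

  std::string oa, ob;
  oa.reserve(n + m); ob.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = tb(i, j);
    if (t == 0)      { oa.push_back(a[i - 1]); ob.push_back(b[j - 1]); --i; --j; }
    else if (t == 1) { oa.push_back(a[i - 1]); ob.push_back('-');      --i; }
    else             { oa.push_back('-');      ob.push_back(b[j - 1]); --j; }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());

  return List::create(_["aligned_a"] = oa, _["aligned_b"] = ob,
                      _["score"] = S(n, m));
}

// Profile-profile global alignment for progressive MSA.
// Profiles are 5 x L frequency matrices (rows A,C,G,T,gap; columns sum to 1).
// Column-column score is the expected pairwise score; aligning a profile
// column against a new gap costs `gap` times its non-gap fraction, so columns
// that are already mostly gaps are cheap to skip.  Returns the traceback as a
// vector of moves (0 = both, 1 = consume P1, 2 = consume P2).
// [[Rcpp::export]]
IntegerVector profile_align_cpp(NumericMatrix p1, NumericMatrix p2,
                                double match, double mismatch, double gap) {
  const int n = p1.ncol(), m = p2.ncol();
  if (p1.nrow() != 5 || p2.nrow() != 5) stop("profiles must have 5 rows");

  // Precompute per-column base frequencies and gap fractions.
  NumericVector g1(n), g2(m);
  for (int i = 0; i < n; ++i) g1[i] = p1(4, i);
  for (int j = 0; j < m; ++j) g2[j] = p2(4, j);

  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    S(i, 0) = S(i - 1, 0) + gap * (1.0 - g1[i - 1]); tb(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S(0, j) = S(0, j - 1) + gap * (1.0 - g2[j - 1]); tb(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    double a0 = p1(0, i - 1), a1 = p1(1, i - 1), a2 = p1(2, i - 1), a3 = p1(3, i - 1);
    double nz1 = 1.0 - g1[i - 1];
    double upcost = gap * nz1;
    for (int j = 1; j <= m; ++j) {
      double b0 = p2(0, j - 1), b1 = p2(1, j - 1), b2 = p2(2, j - 1), b3 = p2(3, j - 1);
      double nz2 = 1.0 - g2[j - 1];
      double same = a0 * b0 + a1 * b1 + a2 * b2 + a3 * b3;
      double cross = nz1 * nz2 - same;
      double gapmix = g1[i - 1] * nz2 + nz1 * g2[j - 1];
      double sc = same * match + cross * mismatch + gapmix * gap;

      double d = S(i - 1, j - 1) + sc;
      double u = S(i - 1, j) + upcost;
      double l = S(i, j - 1) + gap * nz2;
      if (d >= u && d >= l)      { S(i, j) = d; tb(i, j) = 0; }
      else if (u >= l)           { S(i, j) = u; tb(i, j) = 1; }
      else                       { S(i, j) = l; tb(i, j) = 2; }
    }
  }

  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = tb(i, j);
    moves.push_back(t);
    if (t == 0)      { --i; --j; }
    else if (t == 1) { --i; }
    else             { --j; }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}

// Pairwise mismatch / shared-site counts over selected alignment columns.
// M is an n x L integer matrix coding A,C,G,T as 0..3 and gap/ambiguous as
// >= 4; `cols` holds 1-based column indices (possibly repeated, as in a
// bootstrap resample).  A site is shared when both rows hold a plain base.
// [[Rcpp::export]]
List msa_pair_counts_cpp(IntegerMatrix M, IntegerVector cols) {
  const int n = M.nrow();
  const int L = cols.size();
  NumericMatrix mm(n, n), sh(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int s = 0, d = 0;
      for (int k = 0; k < L; ++k) {
        int c = cols[k] - 1;
        int x = M(i, c), y = M(j, c);
        if (x < 4 && y < 4) { ++s; if (x != y) ++d; }
      }
      sh(i, j) = sh(j, i) = s;
      mm(i, j) = mm(j, i) = d;
    }
  }
  return List::create(_["mismatch"] = mm, _["shared"] = sh);
}
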