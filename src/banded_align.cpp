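#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Banded global alignment with affine gaps.
// A gap of length L scores go + L * ge (go, ge <= 0).
// Band: for each row i (0..n, ref prefix length), columns lo[i]..hi[i]
// (0..m, query prefix length) are reachable. Tie-break on traceback:
// diagonal > up (ref gap consumed, i.e. deletion in query) > left.
//
// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string ref, std::string query,
                      IntegerVector lo, IntegerVector hi,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = ref.size(), m = query.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  if ((int)lo.size() != n + 1 || (int)hi.size() != n + 1)
    stop("band vectors must have length n+1");

  // width per row; store offset-indexed bands
  std::vector<int> off(n + 1), w(n + 1);
  size_t total = 0;
  for (int i = 0; i <= n; ++i) {
    if (lo[i] < 0 || hi[i] > m || lo[i] > hi[i]) stop("invalid band at row %d", i);
    off[i] = lo[i];
    w[i] = hi[i] - lo[i] + 1;
    total += w[i];
  }
  std::vector<size_t> base(n + 2, 0);
  for (int i = 0; i <= n; ++i) base[i + 1] = base[i] + w[i];

  std::vector<double> M(total, NEG), X(total, NEG), Y(total, NEG);
  // traceback: 0 none, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> tM(total, 0), tX(total, 0), tY(total, 0);

  auto idx = [&](int i, int j) -> long { return (long)base[i] + (j - off[i]); };
  auto inband = [&](int i, int j) -> bool {
    return i >= 0 && i <= n && j >= off[i] && j <= off[i] + w[i] - 1;
  };

  for (int i = 0; i <= n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      long c = idx(i, j);
      if (i == 0 && j == 0) { M[c] = 0.0; continue; }
      // X: gap in query (consume ref char i)
      if (i > 0 && inband(i - 1, j)) {
        long p = idx(i - 1, j);
        double fromM = (M[p] == NEG) ? NEG : M[p] + gap_open + gap_extend;
        double fromX = (X[p] == NEG) ? NEG : X[p] + gap_extend;
        if (fromM >= fromX) { X[c] = fromM; tX[c] = 1; }
        else { X[c] = fromX; tX[c] = 2; }
        if (X[c] == NEG) tX[c] = 0;
      }
      // Y: gap in ref (consume query char j)
      if (j > 0 && inband(i, j - 1)) {
        long p = idx(i, j - 1);
        double fromM = (M[p] == NEG) ? NEG : M[p] + gap_open + gap_extend;
        double fromY = (Y[p] == NEG) ? NEG : Y[p] + gap_extend;
        if (fromM >= fromY) { Y[c] = fromM; tY[c] = 1; }
        else { Y[c] = fromY; tY[c] = 3; }
        if (Y[c] == NEG) tY[c] = 0;
      }
      // M: consume both
      if (i > 0 && j > 0 && inband(i - 1, j - 1)) {
        long p = idx(i - 1, j - 1);
        double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
        double bM = M[p], bX = X[p], bY = Y[p];
        double best = bM; unsigned char tb = 1;
        if (bX > best) { best = bX; tb = 2; }
        if (bY > best) { best = bY; tb = 3; }
        if (best != NEG) { M[c] = best + s; tM[c] = tb; }
      }
    }
  }

  if (!inband(n, m)) stop("band does not reach the terminal cell");
  long c = idx(n, m);
  double best = M[c]; int state = 1;
  if (X[c] > best) { best = X[c]; state = 2; }
  if (Y[c] > best) { best = Y[c]; state = 3; }
  if (best == NEG) stop("no path through the band");

  std::string ra, qa;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    long cc = idx(i, j);
    if (state == 1) {
      int prev = tM[cc];
      ra.push_back(ref[i - 1]); qa.push_back(query[j - 1]);
      --i; --j; state = prev;
    } else if (state == 2) {
      int prev = tX[cc];
      ra.push_back(ref[i - 1]); qa.push_back('-');
      --i; state = prev;
    } else {
      int prev = tY[cc];
      ra.push_back('-'); qa.push_back(query[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["score"] = best, _["ref_aln"] = ra, _["query_aln"] = qa);
}
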