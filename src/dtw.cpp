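#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Local cost between word i of a and word j of b: per letter 0 if equal,
// otherwise |rank difference| - 1, summed over the 8 positions.
static inline double word_cost(const IntegerMatrix &a, int i,
                               const IntegerMatrix &b, int j) {
  int s = 0;
  const int k = a.ncol();
  for (int c = 0; c < k; ++c) {
    int d = a(i, c) - b(j, c);
    if (d > 0) s += d - 1;
    else if (d < 0) s += -d - 1;
  }
  return (double)s;
}

// Banded DTW dynamic program over two word sequences with the modified
// lexical local cost, Sakoe-Chiba band |i-j| <= band, symmetric (match /
// insert / delete) steps, boundary-aligned endpoints. Returns a list with
// the full alignment distance (NA when the corner is outside the band) and
// the diagonal cells D(q, q), q = 1..min(na, nb), which are the distances of
// all equal-length prefix comparisons.
// [[Rcpp::export(name = ".dtw_band")]]
List dtw_band(IntegerMatrix a, IntegerMatrix b, int band) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) stop("sequences must be nonempty");
  if (a.ncol() != b.ncol()) stop("word lengths differ");
  if (band < 0) stop("band must be >= 0");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> prev(nb + 1, INF), cur(nb + 1, INF);
  std::vector<double> diag(std::min(na, nb), INF);
  prev[0] = 0.0;
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(1, i - band), jhi = std::min(nb, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double best = prev[j - 1];            // match
      if (prev[j] < best) best = prev[j];   // insert
      if (cur[j - 1] < best) best = cur[j - 1]; // delete
      if (best < INF) cur[j] = best + word_cost(a, i - 1, b, j - 1);
    }
    if (i <= nb && cur[i] < INF) diag[i - 1] = cur[i];
    std::swap(prev, cur);
  }
  double full = prev[nb];
  return List::create(
      _["distance"] = (full < INF) ? full : NA_REAL,
      _["diag"] = NumericVector(diag.begin(), diag.end()));
}
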