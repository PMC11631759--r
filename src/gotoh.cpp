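#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch with Gotoh's three-state
// recursion). A gap of length L costs gap_open + (L - 1) * gap_extend, i.e.
// the opening charge covers the first gapped position. End gaps are
// penalized. 'N' against anything scores as a mismatch.
//
// States: M = diagonal (ref i aligned to read j), X = gap in read (ref base
// deleted), Y = gap in ref (read base inserted). Traceback ties are broken
// with fixed priority M > X > Y (diagonal > vertical > horizontal), which
// makes the reported alignment unique.

static const double NEG_INF = -1e18;

inline double subst_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List gotoh_align_cpp(std::string ref, std::string read,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = ref.size();   // rows: reference
  const int m = read.size();  // cols: read
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: previous state for each cell/state (0=M, 1=X, 2=Y)
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char a = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: consume one base of each; predecessor priority M > X > Y
      double best = M[d];
      signed char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      if (best > NEG_INF / 2) {
        M[c] = best + subst_score(a, read[j - 1], match, mismatch);
        tbM[c] = tb;
      }
      // X: gap in read (vertical)
      best = (M[u] > NEG_INF / 2) ? M[u] + gap_open : NEG_INF;
      tb = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; tb = 1; }
      if (Y[u] > NEG_INF / 2 && Y[u] + gap_open > best) {
        best = Y[u] + gap_open; tb = 2;
      }
      if (best > NEG_INF / 2) { X[c] = best; tbX[c] = tb; }
      // Y: gap in ref (horizontal)
      best = (M[l] > NEG_INF / 2) ? M[l] + gap_open : NEG_INF;
      tb = 0;
      if (X[l] > NEG_INF / 2 && X[l] + gap_open > best) {
        best = X[l] + gap_open; tb = 1;
      }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; tb = 2; }
      if (best > NEG_INF / 2) { Y[c] = best; tbY[c] = tb; }
    }
  }

  const int endc = n * W + m;
  double score = M[endc];
  int state = 0;
  if (X[endc] > score) { score = X[endc]; state = 1; }
  if (Y[endc] > score) { score = Y[endc]; state = 2; }

  std::string ra, qa;  // reversed gapped strings
  ra.reserve(n + m);
  qa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      ra.push_back(ref[i - 1]);
      qa.push_back(read[j - 1]);
      state = tbM[c];
      --i; --j;
    } else if (state == 1) {
      ra.push_back(ref[i - 1]);
      qa.push_back('-');
      state = tbX[c];
      --i;
    } else {
      ra.push_back('-');
      qa.push_back(read[j - 1]);
      state = tbY[c];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["ref_aligned"] = ra, _["read_aligned"] = qa,
                      _["score"] = score);
}
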