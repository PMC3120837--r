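#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// A gap of length L costs gap_open + (L - 1) * gap_extend (both >= 0,
// subtracted from the score). 'N' and 'X' never match anything.
// Traceback ties are broken by preferring diagonal, then up (gap in b),
// then left (gap in a). Spans are 0-based half-open.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match,
                  double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), R_NegInf); // gap in a (left)
  std::vector<double> F((n + 1) * (m + 1), R_NegInf); // gap in b (up)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      bool amb = (ca == 'N' || ca == 'X' || cb == 'N' || cb == 'X');
      double s = (!amb && ca == cb) ? match : mismatch;
      double e = std::max(H[at(i, j - 1)] - gap_open,
                          E[at(i, j - 1)] - gap_extend);
      double f = std::max(H[at(i - 1, j)] - gap_open,
                          F[at(i - 1, j)] - gap_extend);
      double h = H[at(i - 1, j - 1)] + s;
      h = std::max(0.0, std::max(h, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["identity"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["n_match"] = 0, _["aln_len"] = 0);
  }

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = F (up), 2 = E (left)
  int n_match = 0, aln_len = 0;
  while (true) {
    if (state == 0) {
      if (H[at(i, j)] <= 0.0) break;
      char ca = a[i - 1], cb = b[j - 1];
      bool amb = (ca == 'N' || ca == 'X' || cb == 'N' || cb == 'X');
      double s = (!amb && ca == cb) ? match : mismatch;
      if (i > 0 && j > 0 && H[at(i, j)] == H[at(i - 1, j - 1)] + s) {
        if (!amb && ca == cb) ++n_match;
        ++aln_len; --i; --j;
      } else if (H[at(i, j)] == F[at(i, j)]) {
        state = 1;
      } else if (H[at(i, j)] == E[at(i, j)]) {
        state = 2;
      } else {
        break; // H == 0 handled above; defensive
      }
    } else if (state == 1) { // in F: consume a
      ++aln_len;
      bool open_here = (F[at(i, j)] == H[at(i - 1, j)] - gap_open);
      --i;
      if (open_here) state = 0;
    } else { // in E: consume b
      ++aln_len;
      bool open_here = (E[at(i, j)] == H[at(i, j - 1)] - gap_open);
      --j;
      if (open_here) state = 0;
    }
  }

  double identity = aln_len > 0 ? (double)n_match / aln_len : 0.0;
  return List::create(_["score"] = best, _["identity"] = identity,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["n_match"] = n_match, _["aln_len"] = aln_len);
}
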