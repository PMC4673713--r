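#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded affine local alignment (Smith-Waterman-Gotoh) of a read against a
// reference, restricted to diagonals (j - i) within
// [center_diag - band, center_diag + band].  Scores: match/mismatch per
// base; gap of length L costs gap_open + (L - 1) * gap_extend.
// Returns best score plus traceback-derived identity, read coverage and
// reference span for the best local path.

// [[Rcpp::export(name = ".banded_align")]]
List banded_align(std::string read, std::string ref, int center_diag,
                  int band, double match = 1.0, double mismatch = -1.0,
                  double gap_open = -2.0, double gap_extend = -1.0) {
  const int n = (int)read.size();   // rows, i over read (1..n)
  const int m = (int)ref.size();    // cols, j over ref  (1..m)
  const int W = 2 * band + 1;
  const double NEG = -1e18;

  // band-compressed matrices: cell (i, j) stored at [i][j - (i + center_diag - band)]
  auto col0 = [&](int i) { return i + center_diag - band; };

  std::vector<std::vector<double>> M(n + 1, std::vector<double>(W, NEG));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(W, NEG)); // gap in ref (up)
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(W, NEG)); // gap in read (left)
  // traceback: 0 none/stop, 1 diag, 2 up (read gap consumed, i-1), 3 left (j-1)
  std::vector<std::vector<unsigned char>> TB(n + 1, std::vector<unsigned char>(W, 0));

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 0; i <= n; ++i) {
    int jlo = std::max(0, col0(i));
    int jhi = std::min(m, i + center_diag + band);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - col0(i);
      if (k < 0 || k >= W) continue;
      if (i == 0 || j == 0) { M[i][k] = 0.0; TB[i][k] = 0; continue; }
      // diagonal predecessor (i-1, j-1) has same k
      double diag = NEG;
      int pk = (j - 1) - col0(i - 1); // = k since col0 shifts by 1 per row
      if (pk >= 0 && pk < W && M[i - 1][pk] > NEG / 2) {
        double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        diag = M[i - 1][pk] + s;
      }
      // up predecessor (i-1, j): k shifts by +1
      double up = NEG;
      int uk = j - col0(i - 1);
      if (uk >= 0 && uk < W) {
        double open_from = (M[i - 1][uk] > NEG / 2) ? M[i - 1][uk] + gap_open : NEG;
        double ext_from = (X[i - 1][uk] > NEG / 2) ? X[i - 1][uk] + gap_extend : NEG;
        up = std::max(open_from, ext_from);
        X[i][k] = up;
      }
      // left predecessor (i, j-1): k shifts by -1
      double left = NEG;
      int lk = k - 1;
      if (lk >= 0) {
        double open_from = (M[i][lk] > NEG / 2) ? M[i][lk] + gap_open : NEG;
        double ext_from = (Y[i][lk] > NEG / 2) ? Y[i][lk] + gap_extend : NEG;
        left = std::max(open_from, ext_from);
        Y[i][k] = left;
      }
      double v = std::max(0.0, std::max(diag, std::max(up, left)));
      M[i][k] = v;
      TB[i][k] = (v == 0.0) ? 0 : (v == diag ? 1 : (v == up ? 2 : 3));
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  // traceback from best cell
  int i = bi, j = bj;
  int aligned = 0, matches = 0, read_aln = 0;
  int ref_end = bj, ref_start = bj;
  while (i > 0 && j > 0) {
    int k = j - col0(i);
    if (k < 0 || k >= W) break;
    unsigned char t = TB[i][k];
    if (t == 0) break;
    if (t == 1) {
      aligned++; read_aln++;
      if (read[i - 1] == ref[j - 1]) matches++;
      i--; j--;
    } else if (t == 2) {
      aligned++; read_aln++; i--;
    } else {
      aligned++; j--;
    }
    ref_start = j;
  }

  double identity = aligned > 0 ? (double)matches / aligned : 0.0;
  double coverage = n > 0 ? (double)read_aln / n : 0.0;
  return List::create(_["score"] = best, _["identity"] = identity,
                      _["read_coverage"] = coverage,
                      _["target_start0"] = ref_start,
                      _["target_end0"] = ref_end);
}
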