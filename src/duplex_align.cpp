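#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Smith-Waterman-style local alignment of a small RNA against the
// reverse of a target window, scoring antiparallel base *pairing*
// (Watson-Crick, G:U wobble, mismatch) with affine gaps and a seed
// multiplier over a 1-based sRNA position range. Bases are encoded
// A=0, C=1, G=2, U=3.
//
// States emitted: 'M' Watson-Crick pair, 'W' wobble pair, 'X'
// mismatch, 'T' sRNA base opposite a target gap, 'S' target base
// opposite an sRNA gap.

static inline int pair_class(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 2 && b == 1) || (a == 1 && b == 2)) return 2;  // WC
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;  // wobble
  return 0;                                                // mismatch
}

// [[Rcpp::export]]
List duplex_align_cpp(IntegerVector s, IntegerVector t,
                      double match, double wobble, double mismatch,
                      double gap_open, double gap_extend,
                      int seed_lo, int seed_hi, double seed_scale) {
  const int m = s.size(), n = t.size();
  const double NEG = -1e18;
  std::vector<int> tr(n);
  for (int j = 0; j < n; ++j) tr[j] = t[n - 1 - j];

  std::vector<std::vector<double> >
      M(m + 1, std::vector<double>(n + 1, NEG)),
      Gx(m + 1, std::vector<double>(n + 1, NEG)),
      Gy(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<signed char> >
      Mtb(m + 1, std::vector<signed char>(n + 1, 0)),
      Gxtb(m + 1, std::vector<signed char>(n + 1, 0)),
      Gytb(m + 1, std::vector<signed char>(n + 1, 0));

  double best = 0.0;
  int bi = 0, bj = 0;
  const double eps = 1e-9;

  for (int i = 1; i <= m; ++i) {
    double scale = (i >= seed_lo && i <= seed_hi) ? seed_scale : 1.0;
    for (int j = 1; j <= n; ++j) {
      int pc = pair_class(s[i - 1], tr[j - 1]);
      double sub = (pc == 2 ? match : (pc == 1 ? wobble : mismatch)) * scale;
      double mx = 0.0;
      signed char tb = 0;
      if (i > 1 && j > 1) {
        if (M[i - 1][j - 1] > mx) { mx = M[i - 1][j - 1]; tb = 1; }
        if (Gx[i - 1][j - 1] > mx) { mx = Gx[i - 1][j - 1]; tb = 2; }
        if (Gy[i - 1][j - 1] > mx) { mx = Gy[i - 1][j - 1]; tb = 3; }
      }
      M[i][j] = mx + sub;
      Mtb[i][j] = tb;
      // Gx: sRNA base i opposite a target gap
      double oM = (M[i - 1][j] <= NEG / 2) ? NEG : M[i - 1][j] + gap_open;
      double oX = (Gx[i - 1][j] <= NEG / 2) ? NEG : Gx[i - 1][j] + gap_extend;
      if (oM >= oX) { Gx[i][j] = oM; Gxtb[i][j] = 1; }
      else { Gx[i][j] = oX; Gxtb[i][j] = 2; }
      // Gy: target base j opposite an sRNA gap
      double pM = (M[i][j - 1] <= NEG / 2) ? NEG : M[i][j - 1] + gap_open;
      double pY = (Gy[i][j - 1] <= NEG / 2) ? NEG : Gy[i][j - 1] + gap_extend;
      if (pM >= pY) { Gy[i][j] = pM; Gytb[i][j] = 1; }
      else { Gy[i][j] = pY; Gytb[i][j] = 3; }

      if (M[i][j] > eps) {
        bool better = M[i][j] > best + eps;
        bool tie = std::fabs(M[i][j] - best) <= eps;
        // leftmost target site first (larger j in reversed coordinates),
        // then the shorter alignment (smaller i endpoint)
        if (better || (tie && (j > bj || (j == bj && i < bi)))) {
          best = M[i][j] > best ? M[i][j] : best;
          bi = i; bj = j;
        }
      }
    }
  }

  if (bi == 0) {
    return List::create(_["score"] = 0.0, _["srna_start"] = NA_INTEGER,
                        _["srna_end"] = NA_INTEGER,
                        _["site_start"] = NA_INTEGER,
                        _["site_end"] = NA_INTEGER,
                        _["states"] = "",
                        _["srna_pos"] = IntegerVector(0),
                        _["target_pos"] = IntegerVector(0));
  }

  // traceback
  std::string states;
  std::vector<int> spos, tpos;
  int i = bi, j = bj;
  char layer = 'M';
  while (true) {
    if (layer == 'M') {
      int pc = pair_class(s[i - 1], tr[j - 1]);
      states.push_back(pc == 2 ? 'M' : (pc == 1 ? 'W' : 'X'));
      spos.push_back(i);
      tpos.push_back(n - j);  // 0-based position on the original target
      signed char tb = Mtb[i][j];
      --i; --j;
      if (tb == 0) break;
      layer = (tb == 1 ? 'M' : (tb == 2 ? 'X' : 'Y'));
    } else if (layer == 'X') {
      states.push_back('T');
      spos.push_back(i);
      tpos.push_back(NA_INTEGER);
      signed char tb = Gxtb[i][j];
      --i;
      layer = (tb == 1 ? 'M' : 'X');
    } else {
      states.push_back('S');
      spos.push_back(NA_INTEGER);
      tpos.push_back(n - j);
      signed char tb = Gytb[i][j];
      --j;
      layer = (tb == 1 ? 'M' : 'Y');
    }
  }
  std::reverse(states.begin(), states.end());
  std::reverse(spos.begin(), spos.end());
  std::reverse(tpos.begin(), tpos.end());

  int site_start = n - bj;
  int site_end = n;  // placeholder; recompute from consumed target range
  // first consumed target cell is at matrix column (j after loop) + 1
  int j_start = j + 1;
  site_end = n - j_start + 1;

  return List::create(_["score"] = best,
                      _["srna_start"] = i,          // 0-based start
                      _["srna_end"] = bi,           // half-open end
                      _["site_start"] = site_start,
                      _["site_end"] = site_end,
                      _["states"] = states,
                      _["srna_pos"] = wrap(spos),
                      _["target_pos"] = wrap(tpos));
}
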