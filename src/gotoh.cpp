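#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap (Gotoh) alignment of every prefix of `query` against `ref`,
// global in the query prefix and free at both reference ends. For each
// prefix length i returns the best score f_i, the 1-based reference end
// column of the best cell, and the number of matches on one optimal path.
// Gap of length g costs gap_open + g * gap_ext (both passed negative).
//
// Running the same routine on the reversed sequences yields the suffix
// scoring vector r of the split-read double dynamic programming.
// [[Rcpp::export(name = ".gotoh_prefix")]]
List gotoh_prefix(std::string query, std::string ref,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int) query.size();
  const int L = (int) ref.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> H(L + 1), Hprev(L + 1), E(L + 1), F(L + 1), Fprev(L + 1);
  std::vector<int> NH(L + 1), NHprev(L + 1), NE(L + 1), NF(L + 1), NFprev(L + 1);

  NumericVector best(n);
  IntegerVector pos(n), nmatch(n);

  // row 0: free reference prefix
  for (int p = 0; p <= L; ++p) {
    Hprev[p] = 0.0; NHprev[p] = 0;
    Fprev[p] = NEG; NFprev[p] = 0;
  }

  for (int i = 1; i <= n; ++i) {
    // column 0: query prefix aligned to nothing (one gap of length i)
    F[0] = (i == 1) ? (Hprev[0] + gap_open + gap_ext) : (Fprev[0] + gap_ext);
    NF[0] = (i == 1) ? NHprev[0] : NFprev[0];
    H[0] = F[0]; NH[0] = NF[0];
    E[0] = NEG; NE[0] = 0;

    double rbest = NEG; int rpos = 0, rnm = 0;
    char qc = query[i - 1];
    for (int p = 1; p <= L; ++p) {
      // vertical: gap in reference (consumes query char)
      double f_open = Hprev[p] + gap_open + gap_ext;
      double f_ext  = Fprev[p] + gap_ext;
      if (f_open >= f_ext) { F[p] = f_open; NF[p] = NHprev[p]; }
      else                 { F[p] = f_ext;  NF[p] = NFprev[p]; }
      // horizontal: gap in query (consumes reference char)
      double e_open = H[p - 1] + gap_open + gap_ext;
      double e_ext  = E[p - 1] + gap_ext;
      if (e_open >= e_ext) { E[p] = e_open; NE[p] = NH[p - 1]; }
      else                 { E[p] = e_ext;  NE[p] = NE[p - 1]; }
      // diagonal
      bool is_m = (qc == ref[p - 1]);
      double d = Hprev[p - 1] + (is_m ? match : mismatch);
      int nd = NHprev[p - 1] + (is_m ? 1 : 0);
      if (d >= E[p] && d >= F[p]) { H[p] = d; NH[p] = nd; }
      else if (E[p] >= F[p])      { H[p] = E[p]; NH[p] = NE[p]; }
      else                        { H[p] = F[p]; NH[p] = NF[p]; }

      if (H[p] > rbest) { rbest = H[p]; rpos = p; rnm = NH[p]; }
    }
    if (H[0] > rbest) { rbest = H[0]; rpos = 0; rnm = NH[0]; }
    best[i - 1] = rbest; pos[i - 1] = rpos; nmatch[i - 1] = rnm;

    std::swap(H, Hprev); std::swap(NH, NHprev);
    std::swap(F, Fprev); std::swap(NF, NFprev);
  }
  return List::create(_["best"] = best, _["pos"] = pos, _["nmatch"] = nmatch);
}
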