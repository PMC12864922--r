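#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Boltzmann weight exp(-E/kT) of a base pair, 0 when the bases cannot pair.
// Accepts DNA or RNA alphabet (T == U). Watson-Crick plus GU wobble.
static inline double pair_weight(char a, char b,
                                 double wGC, double wAU, double wGU) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wGU;
  return 0.0;
}

// Base-pair probability matrix under a base-pair-counting energy model with
// helix cooperativity: a structure's energy is the sum of its pair energies
// plus e_init per maximal helix (run of stacked pairs), all in kT units,
// with a minimum hairpin loop of `min_loop` unpaired bases. The initiation
// penalty is what keeps isolated pairs rare, as in nearest-neighbour
// thermodynamics, while the model stays simple enough for an exact
// enumeration oracle.
//
// Inside (1-based; Q over [i,j], empty/degenerate interval = 1; iota =
// exp(-e_init) paid by the outermost pair of each helix):
//   Qb[i][j] = w(i,j) * ( Q[i+1][j-1] + (1 - iota) * Qb[i+1][j-1] )
//   Q[i][j]  = Q[i][j-1] + sum_k Q[i][k-1] * iota * Qb[k][j]
// (the Qb term re-weights interior structures whose boundary pair
// (i+1,j-1) stacks on (i,j) and therefore pays no initiation).
//
// Outside: a paired (i,j) is exterior, directly enclosed by a non-adjacent
// pair, or stacked on the adjacent pair (i-1,j+1); with
// F(k,l) = P[k][l] * w(k,l) / Qb[k][l]:
//   P[i][j] = Qb[i][j] * ( iota * Q[1][i-1] * Q[j+1][n] / Z
//             + sum_{(k,l) non-adjacent} F(k,l) * iota
//               * Q[k+1][i-1] * Q[j+1][l-1]
//             + F(i-1,j+1) )
// [[Rcpp::export]]
NumericMatrix mccaskill_pairprob_cpp(std::string seq,
                                     double e_gc, double e_au, double e_gu,
                                     double e_init, int min_loop) {
  const int n = (int) seq.size();
  NumericMatrix P(n, n);
  if (n == 0) return P;
  const double wGC = std::exp(-e_gc), wAU = std::exp(-e_au),
               wGU = std::exp(-e_gu), iota = std::exp(-e_init);

  std::vector< std::vector<double> > Q(n + 2, std::vector<double>(n + 2, 1.0));
  std::vector< std::vector<double> > Qb(n + 2, std::vector<double>(n + 2, 0.0));
  std::vector< std::vector<double> > W(n + 2, std::vector<double>(n + 2, 0.0));
  for (int i = 1; i <= n; ++i)
    for (int j = i + min_loop + 1; j <= n; ++j)
      W[i][j] = pair_weight(seq[i - 1], seq[j - 1], wGC, wAU, wGU);

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (W[i][j] > 0.0) {
        Qb[i][j] = W[i][j] * (Q[i + 1][j - 1] +
                              (1.0 - iota) * Qb[i + 1][j - 1]);
      }
      double q = Q[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (Qb[k][j] > 0.0)
          q += (k > i ? Q[i][k - 1] : 1.0) * iota * Qb[k][j];
      }
      Q[i][j] = q;
    }
  }
  const double Z = Q[1][n];

  // Decreasing span so enclosing pairs are available.
  std::vector< std::vector<double> > Pm(n + 2, std::vector<double>(n + 2, 0.0));
  std::vector< std::vector<double> > F(n + 2, std::vector<double>(n + 2, 0.0));
  for (int d = n - 1; d >= min_loop + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (Qb[i][j] <= 0.0) continue;
      double ext = iota * (i > 1 ? Q[1][i - 1] : 1.0) *
                   (j < n ? Q[j + 1][n] : 1.0) / Z;
      for (int k = 1; k < i; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (F[k][l] <= 0.0) continue;
          if (k == i - 1 && l == j + 1) continue; // stacked: handled below
          ext += F[k][l] * iota * Q[k + 1][i - 1] * Q[j + 1][l - 1];
        }
      }
      if (i > 1 && j < n) ext += F[i - 1][j + 1];
      Pm[i][j] = Qb[i][j] * ext;
      F[i][j] = Pm[i][j] * W[i][j] / Qb[i][j];
    }
  }
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      P(i - 1, j - 1) = Pm[i][j];
      P(j - 1, i - 1) = Pm[i][j];
    }
  return P;
}
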