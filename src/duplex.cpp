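#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy dynamic program.
//
// Bases are encoded A=1 C=2 G=3 U=4, 0 = unpairable (N). A duplex structure
// is a monotone set of base pairs (i1,j1)..(ik,jk) with i increasing along
// the miRNA (5'->3') and j decreasing along the target: the two strands are
// antiparallel. Energy = initiation + sum over consecutive pairs of either a
// nearest-neighbor stack term (no unpaired bases) or a bulge/interior-loop
// penalty indexed by total unpaired length. No intramolecular pairing.
//
// E(i,j) = minimum energy over structures whose 3'-most miRNA pair is (i,j),
// including initiation. Predecessor matrices allow traceback in R.

static inline int pidx(int a, int b) {
  // AU=1 UA=2 GC=3 CG=4 GU=5 UG=6, 0 = not a pair
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

// [[Rcpp::export]]
List duplex_dp(IntegerVector mi, IntegerVector tx, NumericMatrix stacks,
               NumericVector bulge, NumericVector interior, double init,
               int max_loop, LogicalVector mask) {
  const int m = mi.size(), n = tx.size();
  const double INF = 1e9;
  NumericMatrix E(m, n);
  IntegerMatrix Pi(m, n), Pj(m, n);
  std::fill(E.begin(), E.end(), INF);
  std::fill(Pi.begin(), Pi.end(), 0);   // 0 = helix start (1-based R indices)
  std::fill(Pj.begin(), Pj.end(), 0);

  const int nb = bulge.size(), ni = interior.size();

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      if (mask[j]) continue;
      const int pr = pidx(mi[i], tx[j]);
      if (!pr) continue;
      double best = init;
      int bi = 0, bj = 0;
      const int pmin = std::max(0, i - 1 - max_loop);
      for (int p = i - 1; p >= pmin; --p) {
        const int qmax = std::min(n - 1, j + 1 + max_loop);
        for (int q = j + 1; q <= qmax; ++q) {
          if (E(p, q) >= INF / 2) continue;
          const int a = i - p - 1, b = q - j - 1;
          double cost;
          if (a == 0 && b == 0) {
            cost = stacks(pidx(mi[p], tx[q]) - 1, pr - 1);
          } else if (a == 0 || b == 0) {
            const int L = a + b;
            if (L > nb || NumericVector::is_na(bulge[L - 1])) continue;
            cost = bulge[L - 1];
          } else {
            const int L = a + b;
            if (L > ni || NumericVector::is_na(interior[L - 1])) continue;
            cost = interior[L - 1];
          }
          const double e = E(p, q) + cost;
          if (e < best - 1e-12) { best = e; bi = p + 1; bj = q + 1; }
        }
      }
      E(i, j) = best;
      Pi(i, j) = bi;
      Pj(i, j) = bj;
    }
  }
  return List::create(_["E"] = E, _["Pi"] = Pi, _["Pj"] = Pj);
}
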