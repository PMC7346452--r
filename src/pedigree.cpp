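#include <Rcpp.h>
using namespace Rcpp;

// Pedigree arrays are 1-based parent indices into the same vectors, 0 =
// unknown, and must be topologically sorted (parents before offspring).

// Meuwissen & Luo (1992) recursive inbreeding coefficients.
// F of the virtual "unknown" animal 0 is -1 so that D = 0.5 - 0.25(Fs + Fd)
// collapses to the right founder variance when a parent is missing.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0);
  std::vector<double> Fpad(n + 1);
  Fpad[0] = -1.0;
  for (int i = 1; i <= n; ++i) {
    const int s = sire[i - 1], d = dam[i - 1];
    if (s == 0 || d == 0) { F[i - 1] = 0.0; Fpad[i] = 0.0; continue; }
    if (i > 1 && s == sire[i - 2] && d == dam[i - 2]) {
      // full sib of the previous animal: identical F
      F[i - 1] = F[i - 2]; Fpad[i] = F[i - 2]; continue;
    }
    double fi = -1.0;
    L[i] = 1.0;
    for (int j = i; j >= 1; --j) {       // ancestors have lower indices
      if (L[j] == 0.0) continue;
      const int sj = sire[j - 1], dj = dam[j - 1];
      const double Dj = 0.5 - 0.25 * (Fpad[sj] + Fpad[dj]);
      if (sj > 0) L[sj] += 0.5 * L[j];
      if (dj > 0) L[dj] += 0.5 * L[j];
      fi += L[j] * L[j] * Dj;
      L[j] = 0.0;
    }
    F[i - 1] = fi;
    Fpad[i] = fi;
  }
  return F;
}

// Dense additive relationship matrix by the tabular method.  Meant for
// pedigrees already pruned to the ancestors of the subset of interest.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_a(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s > 0) aij += 0.5 * A(s - 1, j);
      if (d > 0) aij += 0.5 * A(d - 1, j);
      A(i, j) = aij;
      A(j, i) = aij;
    }
    A(i, i) = 1.0 + ((s > 0 && d > 0) ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}
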