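#include <Rcpp.h>
using namespace Rcpp;

// Gene dropping: founders (and unknown parent slots) receive unique allele
// labels; each non-founder draws one allele copy from each parent.  A
// transmitted copy is flagged "ancestrally autozygous" if the parent's copy
// already carried the flag OR the parent genotype itself was autozygous at
// this locus (both copies the same founder allele), so flags are set on
// transmission and are monotone down the pedigree.
//
// Per replicate and individual we accumulate:
//   auto : 1 if autozygous (the classical F)
//   akw  : if autozygous, the fraction of its two copies that are flagged
//          (the Kalinowski "old" component; F = Fnew + Fak holds exactly)
//   abw  : fraction of flagged copies regardless of autozygosity (Ballou)

namespace {

struct DropState {
  std::vector<int>  a1, a2;
  std::vector<char> f1, f2;
  explicit DropState(int n) : a1(n), a2(n), f1(n), f2(n) {}
};

// One transmission outcome; picks ps/pd in {0,1} choose the parent copy.
inline void drop_locus(const IntegerVector& sire, const IntegerVector& dam,
                       const int* ps, const int* pd, DropState& st) {
  const int n = sire.size();
  int next_allele = 0;
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s == 0) { st.a1[i] = next_allele++; st.f1[i] = 0; }
    else {
      const int si = s - 1;
      const bool auto_s = st.a1[si] == st.a2[si];
      if (ps[i]) { st.a1[i] = st.a2[si]; st.f1[i] = st.f2[si] || auto_s; }
      else       { st.a1[i] = st.a1[si]; st.f1[i] = st.f1[si] || auto_s; }
    }
    if (d == 0) { st.a2[i] = next_allele++; st.f2[i] = 0; }
    else {
      const int di = d - 1;
      const bool auto_d = st.a1[di] == st.a2[di];
      if (pd[i]) { st.a2[i] = st.a2[di]; st.f2[i] = st.f2[di] || auto_d; }
      else       { st.a2[i] = st.a1[di]; st.f2[i] = st.f1[di] || auto_d; }
    }
  }
}

// Accumulates the Kalinowski split directly (column 0 = "new" weight,
// column 1 = "ancestral" weight): the per-replicate identity
// auto = new + ancestral then survives summation exactly, because all
// weights are multiples of 0.5 (or of the enumeration weight 4^-m) and
// sum without rounding.
inline void accumulate(const DropState& st, int n, double w,
                       double* s_new, double* s_akw, double* s_abw) {
  for (int i = 0; i < n; ++i) {
    const bool az = st.a1[i] == st.a2[i];
    const double fl = 0.5 * (st.f1[i] + st.f2[i]);
    if (az) { s_new[i] += w * (1.0 - fl); s_akw[i] += w * fl; }
    s_abw[i] += w * fl;
  }
}

} // namespace

// Monte-Carlo gene dropping; returns an n x 3 matrix of replicate means
// (columns: new, Kalinowski ancestral, Ballou weights).  Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_gene_drop(IntegerVector sire, IntegerVector dam,
                            int iterations) {
  const int n = sire.size();
  DropState st(n);
  std::vector<int> ps(n), pd(n);
  NumericMatrix out(n, 3);
  double* s_new = &out(0, 0);
  double* s_akw = &out(0, 1);
  double* s_abw = &out(0, 2);
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      ps[i] = unif_rand() < 0.5;
      pd[i] = unif_rand() < 0.5;
    }
    drop_locus(sire, dam, ps.data(), pd.data(), st);
    accumulate(st, n, 1.0, s_new, s_akw, s_abw);
  }
  const double inv = 1.0 / iterations;
  for (int i = 0; i < 3 * n; ++i) out[i] *= inv;
  return out;
}

// A single replicate with its full transmission record, for inspection and
// replay in tests.
// [[Rcpp::export]]
List cpp_gene_drop_once(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  DropState st(n);
  IntegerVector ps(n), pd(n);
  for (int i = 0; i < n; ++i) {
    ps[i] = unif_rand() < 0.5;
    pd[i] = unif_rand() < 0.5;
  }
  drop_locus(sire, dam, INTEGER(ps), INTEGER(pd), st);
  return List::create(
    _["allele1"] = IntegerVector(st.a1.begin(), st.a1.end()),
    _["allele2"] = IntegerVector(st.a2.begin(), st.a2.end()),
    _["flag1"]   = LogicalVector(st.f1.begin(), st.f1.end()),
    _["flag2"]   = LogicalVector(st.f2.begin(), st.f2.end()),
    _["pickSire"] = ps, _["pickDam"] = pd);
}

// Exact coefficients by enumerating all 4^m Mendelian transmission outcomes
// (m = number of individuals with at least one known parent), each with
// equal weight.  Same flag semantics as the stochastic path.
// [[Rcpp::export]]
NumericMatrix cpp_enumerate(IntegerVector sire, IntegerVector dam,
                            int max_nonfounders) {
  const int n = sire.size();
  std::vector<int> nf;               // individuals whose picks matter
  for (int i = 0; i < n; ++i)
    if (sire[i] != 0 || dam[i] != 0) nf.push_back(i);
  const int m = static_cast<int>(nf.size());
  if (m > max_nonfounders)
    stop("exact enumeration refused: %d non-founders exceeds cap %d",
         m, max_nonfounders);
  DropState st(n);
  std::vector<int> ps(n, 0), pd(n, 0);
  NumericMatrix out(n, 3);
  const unsigned long long total = 1ULL << (2 * m);
  const double w = 1.0 / static_cast<double>(total);
  for (unsigned long long code = 0; code < total; ++code) {
    for (int t = 0; t < m; ++t) {
      ps[nf[t]] = (code >> (2 * t)) & 1ULL;
      pd[nf[t]] = (code >> (2 * t + 1)) & 1ULL;
    }
    drop_locus(sire, dam, ps.data(), pd.data(), st);
    accumulate(st, n, w, &out(0, 0), &out(0, 1), &out(0, 2));
  }
  return out;
}
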