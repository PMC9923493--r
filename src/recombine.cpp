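#include <Rcpp.h>
using namespace Rcpp;

// Transmitted haplotypes under free recombination: for each offspring i
// (with parent row parent[i], 1-based) and each locus j, pick the allele
// from one of the parent's two homologous copies with probability 1/2.
// Uses R's RNG (reproducible under set.seed()); one uniform draw supplies
// 32 independent copy-choice bits.
// [[Rcpp::export]]
IntegerMatrix recombineCpp(const IntegerMatrix& a1, const IntegerMatrix& a2,
                           const IntegerVector& parent) {
  const int n = parent.size();
  const int L = a1.ncol();
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    const int p = parent[i] - 1;
    uint32_t bits = 0;
    int avail = 0;
    for (int j = 0; j < L; ++j) {
      if (avail == 0) {
        bits = (uint32_t)(unif_rand() * 4294967296.0);
        avail = 32;
      }
      out(i, j) = (bits & 1u) ? a1(p, j) : a2(p, j);
      bits >>= 1;
      --avail;
    }
  }
  return out;
}
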