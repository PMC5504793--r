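// Recombinant gamete formation for the forward Wright-Fisher simulator.
// Crossovers are Poisson per chromosome under a uniform map; the starting
// haplotype is a fair coin. Draws come from R's RNG, so set.seed() in R
// makes the simulation reproducible.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// H: phased haplotypes (2N x p, 0/1), rows 2i-1, 2i belong to diploid i.
// parents: 1-based diploid parent index per requested gamete.
// chromEnd: cumulative 1-based end column of each chromosome.
// pos: physical position per column; morgans: map length per chromosome.
// [[Rcpp::export(name = ".wf_gametes_cpp")]]
IntegerMatrix wf_gametes_cpp(const IntegerMatrix& H,
                             const IntegerVector& parents,
                             const IntegerVector& chromEnd,
                             const NumericVector& pos,
                             const NumericVector& morgans,
                             double lenBp) {
  const int p = H.ncol(), nGam = parents.size(), nChrom = chromEnd.size();
  IntegerMatrix out(nGam, p);
  std::vector<double> xo;
  for (int g = 0; g < nGam; ++g) {
    const int rowA = 2 * (parents[g] - 1), rowB = rowA + 1;
    int s = 0;
    for (int k = 0; k < nChrom; ++k) {
      const int e = chromEnd[k];  // one past the last column (1-based end)
      const int nxo = static_cast<int>(R::rpois(morgans[k]));
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      if (nxo == 0) {
        const int src = phase ? rowB : rowA;
        for (int j = s; j < e; ++j) out(g, j) = H(src, j);
      } else {
        xo.resize(nxo);
        for (int c = 0; c < nxo; ++c) xo[c] = unif_rand() * lenBp;
        std::sort(xo.begin(), xo.end());
        int c = 0;
        for (int j = s; j < e; ++j) {
          while (c < nxo && pos[j] > xo[c]) { phase ^= 1; ++c; }
          out(g, j) = phase ? H(rowB, j) : H(rowA, j);
        }
      }
      s = e;
    }
  }
  return out;
}
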