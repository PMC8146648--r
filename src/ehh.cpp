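#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity decay from a core site.
//
// Walks outward from `core` (1-based column) in `direction` (+1/-1) over
// the 0/1 haplotype matrix, refining the partition of `carriers` (1-based
// row indices) into groups identical from the core out to the current
// site, and records EHH = sum_k C(n_k,2) / C(n,2) at each step.  Stops
// when EHH drops below `stopBelow` (the value at the stopping site is
// still reported) or the matrix edge is reached.
//
// [[Rcpp::export(name = ".ehhDecayCpp")]]
NumericVector ehhDecay(const IntegerMatrix& haps, int core,
                       const IntegerVector& carriers, int direction,
                       double stopBelow, int maxSteps = -1) {
  const int m = haps.ncol();
  const int n = carriers.size();
  if (n < 2) stop("need >= 2 carrier haplotypes");
  const double totPairs = (double)n * (n - 1) / 2.0;
  std::vector<int> group(n, 0);
  std::vector<double> out;
  out.reserve(64);
  // group ids stay < n, so (group, allele) keys fit in a flat 2n table
  std::vector<int> remap(2 * n, -1);
  std::vector<int> counts(n, 0);
  int j = core - 1 + direction;
  int nGroups = 1;
  while (j >= 0 && j < m) {
    // refine: new group id from (old group, allele at j)
    std::fill(remap.begin(), remap.begin() + 2 * nGroups, -1);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
      int key = group[i] * 2 + haps(carriers[i] - 1, j);
      if (remap[key] < 0) remap[key] = ng++;
      group[i] = remap[key];
    }
    std::fill(counts.begin(), counts.begin() + ng, 0);
    for (int i = 0; i < n; ++i) counts[group[i]] += 1;
    double ehh = 0.0;
    for (int g = 0; g < ng; ++g) {
      double c = counts[g];
      ehh += c * (c - 1) / 2.0;
    }
    nGroups = ng;
    ehh /= totPairs;
    out.push_back(ehh);
    if (ehh < stopBelow || ehh == 0.0) break;
    if (maxSteps > 0 && (int)out.size() >= maxSteps) break;
    j += direction;
  }
  return wrap(out);
}
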