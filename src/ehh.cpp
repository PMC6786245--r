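#include <Rcpp.h>
using namespace Rcpp;

// Walk outward from a core column, refining the partition of carrier
// haplotypes by identity of the allele vector from the core to the current
// marker, and recording EHH = sum_g C(k_g,2) / C(n,2) at each marker.
// core, carriers, lo, hi are 1-based; dir is +1 (right) or -1 (left).
// Stops when EHH drops below `cutoff` (that value is still recorded, for
// interpolation) or when the column range [lo, hi] is exhausted.
// [[Rcpp::export]]
List cpp_ehh_side(const IntegerMatrix& haps, int core,
                  const IntegerVector& carriers, int dir, double cutoff,
                  int lo, int hi) {
  const int n = carriers.size();
  const double denom = (double)n * (n - 1) / 2.0;
  // identity runs from the core column inclusive: seed the partition with
  // the core alleles (a no-op when all carriers share the core allele)
  std::vector<int> grp(n), newgrp(n);
  int ngrp = 0;
  {
    int map[2] = {-1, -1};
    for (int k = 0; k < n; ++k) {
      const int a = haps(carriers[k] - 1, core - 1);
      if (map[a] < 0) map[a] = ngrp++;
      grp[k] = map[a];
    }
  }
  std::vector<double> ehh;
  std::vector<int> cols;
  bool reached_cutoff = false;
  std::vector<int> map0, map1, cnt;
  int t = core - 1 + dir;
  while (t >= lo - 1 && t <= hi - 1) {
    map0.assign(ngrp, -1);
    map1.assign(ngrp, -1);
    cnt.clear();
    int next = 0;
    for (int k = 0; k < n; ++k) {
      const int a = haps(carriers[k] - 1, t);
      int& slot = (a == 0) ? map0[grp[k]] : map1[grp[k]];
      if (slot < 0) { slot = next++; cnt.push_back(0); }
      newgrp[k] = slot;
      cnt[slot]++;
    }
    double sum = 0.0;
    for (int g = 0; g < next; ++g)
      sum += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    const double e = sum / denom;
    ehh.push_back(e);
    cols.push_back(t + 1);
    grp.swap(newgrp);
    ngrp = next;
    if (e < cutoff) { reached_cutoff = true; break; }
    t += dir;
  }
  return List::create(_["cols"] = cols, _["ehh"] = ehh,
                      _["reached_cutoff"] = reached_cutoff);
}
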