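#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity along one flank of a core SNP.
//
// hap: haplotype x site 0/1 matrix for one chromosome (NA allowed);
// core: 1-based core site; allele: core allele defining the carriers;
// dir: +1 (right flank) or -1 (left); stop_below: stop extending once
// EHH drops below this value (the below-threshold value is included in
// the output so the caller can see the crossing).
// A carrier haplotype is dropped once it hits a missing allele; the
// denominator tracks the evaluable carriers at each site.
// Returns the EHH value at each successive site outward from the core.
// [[Rcpp::export]]
NumericVector ehh_flank_cpp(IntegerMatrix hap, int core, int allele,
                            int dir, double stop_below) {
  const int H = hap.nrow(), S = hap.ncol();
  std::vector<int> car;
  car.reserve(H);
  for (int h = 0; h < H; ++h)
    if (hap(h, core - 1) == allele) car.push_back(h);
  std::vector<double> out;
  if ((int)car.size() < 2) return NumericVector(0);
  std::vector<int> grp(car.size(), 0);
  for (int x = core - 1 + dir; x >= 0 && x < S; x += dir) {
    // drop carriers with missing alleles at x
    std::vector<int> car2, grp2;
    car2.reserve(car.size());
    grp2.reserve(car.size());
    for (size_t i = 0; i < car.size(); ++i) {
      if (hap(car[i], x) != NA_INTEGER) {
        car2.push_back(car[i]);
        grp2.push_back(grp[i]);
      }
    }
    car.swap(car2);
    grp.swap(grp2);
    if ((int)car.size() < 2) {
      out.push_back(0.0);
      break;
    }
    const double denom = car.size() * (car.size() - 1) / 2.0;
    std::map<std::pair<int, int>, int> remap;
    std::vector<int> counts;
    int newn = 0;
    for (size_t i = 0; i < car.size(); ++i) {
      const int a = hap(car[i], x);
      const std::pair<int, int> key(grp[i], a);
      std::map<std::pair<int, int>, int>::iterator it = remap.find(key);
      int id;
      if (it == remap.end()) {
        id = newn++;
        remap.insert(std::make_pair(key, id));
        counts.push_back(0);
      } else {
        id = it->second;
      }
      grp[i] = id;
      counts[id]++;
    }
    double num = 0.0;
    for (size_t c = 0; c < counts.size(); ++c)
      num += counts[c] * (counts[c] - 1) / 2.0;
    const double e = num / denom;
    out.push_back(e);
    if (e <= 0.0 || e < stop_below) break;
  }
  return wrap(out);
}

// Number of carriers of `allele` at the core site.
// [[Rcpp::export]]
int carrier_count_cpp(IntegerMatrix hap, int core, int allele) {
  int n = 0;
  for (int h = 0; h < hap.nrow(); ++h)
    if (hap(h, core - 1) == allele) ++n;
  return n;
}
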