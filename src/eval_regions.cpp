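#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static int uf_find2(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Fused candidate evaluation for the phasing loop: select the top
// ceil(alpha*N) voxels of rho (ties by grid order), label the selection
// with periodic 6-connectivity and test the region-count constraint.
// Returns accept flag, score, number of large regions and total regions.
// [[Rcpp::export(name = ".eval_regions_cpp")]]
List eval_regions_cpp(NumericVector rho, IntegerVector dims, double alpha,
                      double min_large_fraction, int n_large_expected,
                      double max_total_regions, bool allow_drops) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int k = (int)std::ceil(alpha * n);
  // threshold via nth_element
  std::vector<double> vals(rho.begin(), rho.end());
  std::nth_element(vals.begin(), vals.begin() + (n - k), vals.end());
  const double thr = vals[n - k];
  std::vector<char> mask(n, 0);
  int cnt = 0;
  for (int i = 0; i < n; ++i) if (rho[i] > thr) { mask[i] = 1; ++cnt; }
  for (int i = 0; i < n && cnt < k; ++i)
    if (!mask[i] && rho[i] == thr) { mask[i] = 1; ++cnt; }

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        const int nb[3] = { ((x + 1 == nx) ? 0 : x + 1) + nx * (y + ny * z),
                            x + nx * (((y + 1 == ny) ? 0 : y + 1) + ny * z),
                            x + nx * (y + ny * ((z + 1 == nz) ? 0 : z + 1)) };
        for (int q = 0; q < 3; ++q)
          if (mask[nb[q]]) {
            int ra = uf_find2(parent, i), rb = uf_find2(parent, nb[q]);
            if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
          }
      }
  std::vector<int> size(n, 0);
  for (int i = 0; i < n; ++i)
    if (mask[i]) size[uf_find2(parent, i)]++;
  std::vector<int> sizes;
  for (int i = 0; i < n; ++i) if (size[i] > 0) sizes.push_back(size[i]);
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
  const int nsel = cnt;
  int nlarge = 0;
  for (size_t i = 0; i < sizes.size(); ++i)
    if (sizes[i] >= min_large_fraction * nsel) ++nlarge;
  double top = 0;
  for (int i = 0; i < n_large_expected && i < (int)sizes.size(); ++i)
    top += sizes[i];
  const double score = nsel > 0 ? top / nsel : 0.0;
  bool accept = (nlarge == n_large_expected) &&
    ((double)sizes.size() <= max_total_regions) &&
    (allow_drops || (int)sizes.size() == nlarge);
  return List::create(_["accept"] = accept, _["score"] = score,
                      _["n_large"] = nlarge,
                      _["n_regions"] = (int)sizes.size());
}
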