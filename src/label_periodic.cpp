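#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// 6-connected component labeling of a 3D logical mask with periodic
// (wrap-around) boundaries on all axes. Returns raw labels, 0 background.
// [[Rcpp::export(name = ".label_periodic_cpp")]]
IntegerVector label_periodic_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        const int xp = (x + 1 == nx) ? 0 : x + 1;
        const int yp = (y + 1 == ny) ? 0 : y + 1;
        const int zp = (z + 1 == nz) ? 0 : z + 1;
        const int nb[3] = { xp + nx * (y + ny * z),
                            x + nx * (yp + ny * z),
                            x + nx * (y + ny * zp) };
        for (int k = 0; k < 3; ++k) {
          if (mask[nb[k]]) {
            int ra = uf_find(parent, i), rb = uf_find(parent, nb[k]);
            if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
          }
        }
      }
    }
  }

  IntegerVector out(n, 0);
  std::vector<int> label(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  out.attr("n_regions") = next;
  return out;
}
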