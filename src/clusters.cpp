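// 3D connected-component labeling with 6/18/26 neighbourhoods.
// Labels are assigned in column-major scan order of the first voxel of each
// component, so the labeling is deterministic and independent of any RNG.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;

  // neighbour offsets in (di, dj, dk)
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || labels[v] != 0) continue;
    ++next_label;
    labels[v] = next_label;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int k = cur / (nx * ny);
      int rem = cur - k * nx * ny;
      int j = rem / nx;
      int i = rem - j * nx;
      for (size_t o = 0; o < di.size(); ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int w = ii + nx * (jj + ny * kk);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
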