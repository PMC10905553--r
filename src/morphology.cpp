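#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a binary array.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels (0 = background), numbered in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t id = stack.back();
      stack.pop_back();
      int k = (int)(id / ((R_xlen_t)nx * ny));
      int rem = (int)(id % ((R_xlen_t)nx * ny));
      int j = rem / nx;
      int i = rem % nx;
      for (int q = 0; q < nn; ++q) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nid = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[nid] && labels[nid] == 0) {
          labels[nid] = current;
          stack.push_back(nid);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
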