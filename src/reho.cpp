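#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// midranks (ties averaged) of x[0..n) into out
static void midranks(const double *x, int n, std::vector<int> &idx,
                     double *out) {
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
    for (int k = i; k <= j; ++k) out[idx[k]] = r;
    i = j + 1;
  }
}

// Voxelwise Kendall's coefficient of concordance over the 7/19/27-voxel
// neighbourhood, restricted to in-mask voxels. Returns W per voxel and a
// keep flag (neighbourhood size >= min_k).
// [[Rcpp::export(name = ".reho_w_cpp")]]
List reho_w_cpp(NumericVector data, LogicalVector mask, IntegerVector dims,
                int nbhd, int min_k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  // neighbourhood offsets by Chebyshev/Manhattan distance
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nbhd == 7 && man > 1) continue;
        if (nbhd == 19 && man > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  // ranks for every in-mask voxel (column-major voxel x time)
  std::vector<double> ranks((size_t)nvox * nt, 0.0);
  std::vector<double> series(nt);
  std::vector<int> idx;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!mask[v]) continue;
    for (int t = 0; t < nt; ++t) series[t] = data[v + nvox * (R_xlen_t)t];
    std::vector<double> r(nt);
    midranks(series.data(), nt, idx, r.data());
    for (int t = 0; t < nt; ++t) ranks[(size_t)v * nt + t] = r[t];
  }

  NumericVector w(nvox);
  LogicalVector keep(nvox);
  std::vector<double> ri(nt);
  const double n = nt;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[v]) continue;
        std::fill(ri.begin(), ri.end(), 0.0);
        int K = 0;
        for (const auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (!mask[u]) continue;
          ++K;
          const double *ru = &ranks[(size_t)u * nt];
          for (int t = 0; t < nt; ++t) ri[t] += ru[t];
        }
        if (K < min_k) { w[v] = 0.0; keep[v] = false; continue; }
        double rbar = K * (n + 1.0) / 2.0;
        double s = 0.0;
        for (int t = 0; t < nt; ++t) s += ri[t] * ri[t];
        s -= n * rbar * rbar;
        double denom = (double)K * K * (n * n * n - n) / 12.0;
        w[v] = (denom > 0.0) ? std::max(0.0, s / denom) : 0.0;
        keep[v] = true;
      }
  return List::create(_["w"] = w, _["keep"] = keep);
}
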