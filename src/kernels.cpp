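#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Modeled-activation map: per voxel, max over foci of a 3-D Gaussian with
// standard deviation sigma (mm), scaled to `peak` at distance zero. Voxel
// centers come from the 0-based voxel -> mm affine. Distances beyond
// 6*sigma contribute < 1e-7 of peak and are skipped.
// [[Rcpp::export]]
NumericVector ma_map_cpp(IntegerVector dims, NumericMatrix affine,
                         NumericMatrix foci, double sigma, double peak) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = foci.nrow();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double cutoff2 = 36.0 * sigma * sigma;
  for (int f = 0; f < nf; ++f) {
    const double fx = foci(f, 0), fy = foci(f, 1), fz = foci(f, 2);
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        // voxel (0,j,k) center, then step along x by affine column 1
        double cx = affine(0,1)*j + affine(0,2)*k + affine(0,3);
        double cy = affine(1,1)*j + affine(1,2)*k + affine(1,3);
        double cz = affine(2,1)*j + affine(2,2)*k + affine(2,3);
        for (int i = 0; i < nx; ++i, ++idx) {
          const double dx = cx + affine(0,0)*i - fx;
          const double dy = cy + affine(1,0)*i - fy;
          const double dz = cz + affine(2,0)*i - fz;
          const double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < cutoff2) {
            const double v = peak * std::exp(-d2 * inv2s2);
            if (v > out[idx]) out[idx] = v;
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Connected-component labeling of a 3-D logical array, 6- or 26-neighbor.
// Labels are 1..n in discovery order (column-major scan).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector labels(n);
  std::vector<std::array<int,3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = v % nx, j = (v / nx) % ny, k = v / (static_cast<R_xlen_t>(nx) * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
        if (mask[w] && labels[w] == 0) { labels[w] = cur; q.push(w); }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
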