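#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// 3D flood fill over a scalar grid: grow from seed voxels to connected
// neighbours whose value lies inside [lo, hi]. Seeds are 1-based (i, j, k)
// rows; seeds outside the window are ignored (the caller reports them).
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(NumericVector vol, IntegerVector dims,
                             IntegerMatrix seeds, double lo, double hi,
                             int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  LogicalVector mask(n, false);
  std::queue<R_xlen_t> q;

  for (int s = 0; s < seeds.nrow(); ++s) {
    const int i = seeds(s, 0) - 1, j = seeds(s, 1) - 1, k = seeds(s, 2) - 1;
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      stop("seed outside grid");
    const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    const double v = vol[idx];
    if (v >= lo && v <= hi && !mask[idx]) {
      mask[idx] = true;
      q.push(idx);
    }
  }

  // neighbour offsets in (di, dj, dk)
  std::vector<int> di, dj, dk;
  if (connectivity == 6) {
    const int f[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int t = 0; t < 6; ++t) { di.push_back(f[t][0]); dj.push_back(f[t][1]); dk.push_back(f[t][2]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  }
  const int noff = (int)di.size();

  while (!q.empty()) {
    const R_xlen_t idx = q.front(); q.pop();
    const int k = (int)(idx / ((R_xlen_t)nx * ny));
    const int rem = (int)(idx - (R_xlen_t)k * nx * ny);
    const int j = rem / nx;
    const int i = rem - j * nx;
    for (int t = 0; t < noff; ++t) {
      const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      const R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[nb]) continue;
      const double v = vol[nb];
      if (v >= lo && v <= hi) {
        mask[nb] = true;
        q.push(nb);
      }
    }
  }
  return mask;
}

// 3x3x3 median filter with shrinking window at the grid border (the median
// is taken over the in-bounds neighbours only).
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int ck = std::max(0, k - 1); ck <= std::min(nz - 1, k + 1); ++ck)
          for (int cj = std::max(0, j - 1); cj <= std::min(ny - 1, j + 1); ++cj)
            for (int ci = std::max(0, i - 1); ci <= std::min(nx - 1, i + 1); ++ci)
              buf.push_back(vol[ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)]);
        const size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = med;
      }
  return out;
}
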