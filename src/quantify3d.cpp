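// 3D connected-component labelling (26-connectivity) and an exact
// anisotropic Euclidean distance transform (separable lower-envelope
// algorithm with per-axis sampling in nm).

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  // index layout matches R array (z, y, x): idx = z + nz*(y + ny*x)
  auto at = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  };
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = at(z, y, x);
        if (!mask[i] || labels[i]) continue;
        ++next_label;
        labels[i] = next_label;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back();
          stack.pop_back();
          int cz = (int)(c % nz);
          int cy = (int)((c / nz) % ny);
          int cx = (int)(c / ((R_xlen_t)nz * ny));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                R_xlen_t j = at(zz, yy, xx);
                if (mask[j] && !labels[j]) {
                  labels[j] = next_label;
                  stack.push_back(j);
                }
              }
        }
      }
  labels.attr("dim") = dims;
  return labels;
}

// 1D squared-distance transform along a line with sample spacing `s`
// (Felzenszwalb & Huttenlocher lower envelope of parabolas).
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> zb, d;
  v.assign(n, 0);
  zb.assign(n + 1, 0.0);
  d.assign(n, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q * s;
    while (true) {
      int p = v[k];
      double sp = (double)p * s;
      if (f[p] == INF) { // only possible for k == 0 before any finite site
        v[k] = q;
        zb[k] = -INF;
        zb[k + 1] = INF;
        break;
      }
      double inter = ((f[q] + sq * sq) - (f[p] + sp * sp)) / (2 * sq - 2 * sp);
      if (inter <= zb[k]) {
        --k;
        continue;
      }
      ++k;
      v[k] = q;
      zb[k] = inter;
      zb[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zb[k + 1] < sq) ++k;
    double sp = (double)v[k] * s;
    d[q] = (f[v[k]] == INF) ? INF : (sq - sp) * (sq - sp) + f[v[k]];
  }
  f.assign(d.begin(), d.end());
}

// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;
  auto at = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  };
  std::vector<double> line;
  // pass along z
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      bool any = false;
      for (int z = 0; z < nz; ++z) {
        line[z] = out[at(z, y, x)];
        if (line[z] < INF) any = true;
      }
      if (!any) continue;
      dt1d(line, sz);
      for (int z = 0; z < nz; ++z) out[at(z, y, x)] = line[z];
    }
  // pass along y
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int y = 0; y < ny; ++y) {
        line[y] = out[at(z, y, x)];
        if (line[y] < INF) any = true;
      }
      if (!any) continue;
      dt1d(line, sy);
      for (int y = 0; y < ny; ++y) out[at(z, y, x)] = line[y];
    }
  // pass along x
  line.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int x = 0; x < nx; ++x) {
        line[x] = out[at(z, y, x)];
        if (line[x] < INF) any = true;
      }
      if (!any) continue;
      dt1d(line, sx);
      for (int x = 0; x < nx; ++x) out[at(z, y, x)] = line[x];
    }
  out.attr("dim") = dims;
  return out;
}
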