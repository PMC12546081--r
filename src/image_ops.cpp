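// Exact anisotropic Euclidean distance transform (Felzenszwalb-Huttenlocher
// lower envelope of parabolas, one pass per axis) and connected-component
// labeling for binary 3D masks.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// Background sentinel: large but finite so the parabola arithmetic stays
// well defined; any result at or above it means "no source on this image".
const double BIG = 1e30;

// 1D squared distance transform (lower envelope of parabolas) with sample
// positions x_i = i * h.
void dt1d(std::vector<double>& f, double h, std::vector<double>& d,
          std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s = ((f[q] + xq * xq) - (f[v[k]] + (double)v[k] * h * v[k] * h)) /
               (2.0 * xq - 2.0 * v[k] * h);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + xq * xq) - (f[v[k]] + (double)v[k] * h * v[k] * h)) /
          (2.0 * xq - 2.0 * v[k] * h);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    if (d[q] > BIG) d[q] = BIG;
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

} // namespace

// Squared Euclidean distance (mm^2) from each voxel to the nearest
// foreground voxel centre. Foreground: mask != 0.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      f.assign(nx, INF);
      for (int i = 0; i < nx; ++i) f[i] = out[i + nx * (j + ny * k)];
      dt1d(f, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) out[i + nx * (j + ny * k)] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      f.assign(ny, INF);
      for (int j = 0; j < ny; ++j) f[j] = out[i + nx * (j + ny * k)];
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[i + nx * (j + ny * k)] = f[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      f.assign(nz, INF);
      for (int k = 0; k < nz; ++k) f[k] = out[i + nx * (j + ny * k)];
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) out[i + nx * (j + ny * k)] = f[k];
    }

  for (int i = 0; i < n; ++i)
    if (out[i] >= BIG * 0.5) out[i] = INF; // empty-foreground image

  out.attr("dim") = dim;
  return out;
}

// Label connected components of a binary mask. connectivity: 6 (faces),
// 18 (faces + edges) or 26 (faces + edges + corners). Component ids are
// assigned in order of the first foreground voxel met in column-major scan
// order, so labeling is deterministic.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity = 18) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int nn = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }

  std::vector<int> stack;
  int next = 0;
  for (int id = 0; id < n; ++id) {
    if (mask[id] == 0 || labels[id] != 0) continue;
    ++next;
    labels[id] = next;
    stack.clear();
    stack.push_back(id);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int k = cur / (nx * ny), j = (cur / nx) % ny, i = cur % nx;
      for (size_t m = 0; m < offs_i.size(); ++m) {
        int i1 = i + offs_i[m], j1 = j + offs_j[m], k1 = k + offs_k[m];
        if (i1 < 0 || j1 < 0 || k1 < 0 || i1 >= nx || j1 >= ny || k1 >= nz)
          continue;
        int id1 = i1 + nx * (j1 + ny * k1);
        if (mask[id1] != 0 && labels[id1] == 0) {
          labels[id1] = next;
          stack.push_back(id1);
        }
      }
    }
  }

  labels.attr("dim") = dim;
  return labels;
}
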