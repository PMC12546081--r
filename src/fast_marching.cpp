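// Second-order upwind fast marching solver for the Eikonal equation
// |grad T| = 1/F on a masked 3D lattice with anisotropic voxel spacing.
// Voxels with speed <= 0 (or NA) are outside the domain and keep T = Inf.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct HeapNode {
  double t;
  int idx;
  bool operator<(const HeapNode& other) const { return t > other.t; }
};

inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Solve sum_a alpha_a (T - beta_a)^2 = rhs for the largest root with
// T >= max(beta_a) over the retained terms; drop the term with the largest
// beta when no causal root exists (standard upwind exclusion).
double solve_quadratic(std::vector<double>& alpha, std::vector<double>& beta,
                       double rhs) {
  while (!alpha.empty()) {
    double A = 0.0, B = 0.0, C = 0.0, bmax = -INF;
    size_t imax = 0;
    for (size_t m = 0; m < alpha.size(); ++m) {
      A += alpha[m];
      B += alpha[m] * beta[m];
      C += alpha[m] * beta[m] * beta[m];
      if (beta[m] > bmax) { bmax = beta[m]; imax = m; }
    }
    double disc = B * B - A * (C - rhs);
    if (disc >= 0.0) {
      double t = (B + std::sqrt(disc)) / A;
      if (t >= bmax) return t;
    }
    alpha.erase(alpha.begin() + imax);
    beta.erase(beta.begin() + imax);
  }
  return INF;
}

} // namespace

// [[Rcpp::export(name = ".cpp_fmm_arrival")]]
NumericVector cpp_fmm_arrival(NumericVector speed, IntegerVector dim,
                              NumericVector spacing, IntegerVector source,
                              int order = 2, double init_radius_vox = 4.0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double h[3] = {hx, hy, hz};

  NumericVector T(n, INF);
  std::vector<unsigned char> state(n, 0); // 0 far, 1 trial, 2 accepted
  std::vector<unsigned char> fixed(n, 0); // exact-init voxels, never updated

  auto inside = [&](int i, int j, int k) {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    double f = speed[lin(i, j, k, nx, ny)];
    return R_finite(f) && f > 0.0;
  };

  const int si = source[0], sj = source[1], sk = source[2];
  if (!inside(si, sj, sk)) stop("source voxel lies outside the speed domain");

  std::priority_queue<HeapNode> heap;

  // Exact initialization in a small ball around the source using the source
  // speed; removes the large first-order error of the immediate neighbours.
  const double f0 = speed[lin(si, sj, sk, nx, ny)];
  const double hmax = std::max(hx, std::max(hy, hz));
  const double rinit = init_radius_vox * hmax;
  const int ri = (int)std::ceil(rinit / hx), rj = (int)std::ceil(rinit / hy),
            rk = (int)std::ceil(rinit / hz);
  for (int dk = -rk; dk <= rk; ++dk)
    for (int dj = -rj; dj <= rj; ++dj)
      for (int di = -ri; di <= ri; ++di) {
        int i = si + di, j = sj + dj, k = sk + dk;
        if (!inside(i, j, k)) continue;
        double d = std::sqrt(di * hx * di * hx + dj * hy * dj * hy +
                             dk * hz * dk * hz);
        if (d > rinit) continue;
        // the straight ray from the source must stay inside the domain,
        // otherwise the exact value would tunnel through masked walls
        bool clear = true;
        int nstep = 4 * (std::abs(di) + std::abs(dj) + std::abs(dk)) + 1;
        for (int q = 1; q < nstep && clear; ++q) {
          double t = (double)q / nstep;
          int ii = si + (int)std::lround(t * di);
          int jj = sj + (int)std::lround(t * dj);
          int kk = sk + (int)std::lround(t * dk);
          if (!inside(ii, jj, kk)) clear = false;
        }
        if (!clear) continue;
        int id = lin(i, j, k, nx, ny);
        T[id] = d / f0;
        state[id] = 1;
        fixed[id] = 1;
        heap.push({T[id], id});
      }

  // Stencil frames: the axis-aligned frame plus, on (near-)isotropic
  // in-plane spacing, three face-diagonal frames (the multi-stencils
  // scheme). Each frame is three mutually orthogonal lattice directions;
  // summing squared directional derivatives along a frame approximates
  // |grad T|^2, and the minimum over frames is taken.
  struct Stencil { int dir[3][3]; double len[3]; };
  std::vector<Stencil> stencils;
  {
    Stencil ax = {{{1, 0, 0}, {0, 1, 0}, {0, 0, 1}}, {hx, hy, hz}};
    stencils.push_back(ax);
    auto close = [](double a, double b) {
      return std::fabs(a - b) <= 0.05 * std::max(a, b);
    };
    if (close(hx, hy)) {
      Stencil s = {{{1, 1, 0}, {1, -1, 0}, {0, 0, 1}},
                   {std::sqrt(hx * hx + hy * hy),
                    std::sqrt(hx * hx + hy * hy), hz}};
      stencils.push_back(s);
    }
    if (close(hx, hz)) {
      Stencil s = {{{1, 0, 1}, {1, 0, -1}, {0, 1, 0}},
                   {std::sqrt(hx * hx + hz * hz),
                    std::sqrt(hx * hx + hz * hz), hy}};
      stencils.push_back(s);
    }
    if (close(hy, hz)) {
      Stencil s = {{{0, 1, 1}, {0, 1, -1}, {1, 0, 0}},
                   {std::sqrt(hy * hy + hz * hz),
                    std::sqrt(hy * hy + hz * hz), hx}};
      stencils.push_back(s);
    }
  }

  auto update_voxel = [&](int i, int j, int k) {
    int id = lin(i, j, k, nx, ny);
    if (fixed[id]) return; // exact source-ball values are authoritative
    double f = speed[id];
    double rhs = 1.0 / (f * f);
    double tbest = INF;
    std::vector<double> alpha, beta;
    for (size_t sn = 0; sn < stencils.size(); ++sn) {
      const Stencil& st = stencils[sn];
      // second-order differences are used on the axis frame only: on the
      // rotated frames the one-sided extrapolation loses causality near
      // curved fronts and biases the minimum-over-frames low, while
      // first-order rotated estimates converge from above
      int st_order = (sn == 0) ? order : 1;
      alpha.clear(); beta.clear();
      for (int a = 0; a < 3; ++a) {
        const int* dv = st.dir[a];
        double hl = st.len[a];
        double best1 = INF, best2 = INF;
        for (int s = -1; s <= 1; s += 2) {
          int i1 = i + s * dv[0], j1 = j + s * dv[1], k1 = k + s * dv[2];
          if (!inside(i1, j1, k1)) continue;
          int id1 = lin(i1, j1, k1, nx, ny);
          if (state[id1] != 2) continue;
          double t1 = T[id1];
          if (t1 < best1) {
            best1 = t1;
            best2 = INF;
            int i2 = i + 2 * s * dv[0], j2 = j + 2 * s * dv[1],
                k2 = k + 2 * s * dv[2];
            if (st_order >= 2 && inside(i2, j2, k2)) {
              int id2 = lin(i2, j2, k2, nx, ny);
              if (state[id2] == 2 && T[id2] <= t1) best2 = T[id2];
            }
          }
        }
        if (!R_finite(best1)) continue;
        if (R_finite(best2)) {
          // (3T - 4T1 + T2) / (2h): second-order one-sided difference
          double c = 1.5 / hl;
          alpha.push_back(c * c);
          beta.push_back((4.0 * best1 - best2) / 3.0);
        } else {
          double c = 1.0 / hl;
          alpha.push_back(c * c);
          beta.push_back(best1);
        }
      }
      if (alpha.empty()) continue;
      double t = solve_quadratic(alpha, beta, rhs);
      if (t < tbest) tbest = t;
    }
    if (tbest < T[id]) {
      T[id] = tbest;
      state[id] = 1;
      heap.push({tbest, id});
    }
  };


  while (!heap.empty()) {
    HeapNode node = heap.top();
    heap.pop();
    int id = node.idx;
    if (state[id] == 2 || node.t > T[id]) continue; // stale entry
    state[id] = 2;
    int k = id / (nx * ny), j = (id / nx) % ny, i = id % nx;
    // 18-neighborhood: face and edge neighbours feed the stencil frames
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int nn = std::abs(di) + std::abs(dj) + std::abs(dk);
          if (nn == 0 || nn > 2) continue;
          int i1 = i + di, j1 = j + dj, k1 = k + dk;
          if (!inside(i1, j1, k1)) continue;
          if (state[lin(i1, j1, k1, nx, ny)] != 2) update_voxel(i1, j1, k1);
        }
  }

  T.attr("dim") = dim;
  return T;
}
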