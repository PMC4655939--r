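#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement of a 3D statistic map.
//
// For each voxel v with stat > 0, sums e(h)^E * h^H * dh over n_steps
// thresholds h = dh, 2*dh, ..., hmax (dh = hmax / n_steps), where e(h) is
// the size of the connected supra-threshold (stat >= h) cluster containing
// v under the given connectivity (6, 18 or 26). Non-positive voxels map to
// zero; negative contrasts are handled by the caller on the negated map.
//
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim,
                       double E, double H, int n_steps, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int V = nx * ny * nz;
  if (stat.size() != V) stop("stat length does not match dim");
  NumericVector out(V);

  double hmax = 0.0;
  for (int i = 0; i < V; ++i) if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0 || n_steps < 1) return out;
  const double dh = hmax / n_steps;

  // neighbour offsets for the requested connectivity
  std::vector<int> ndx, ndy, ndz;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (a == 0) continue;
        if (connectivity == 6 && a > 1) continue;
        if (connectivity == 18 && a > 2) continue;
        ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
      }
  const int nn = (int)ndx.size();

  // voxels that can ever be supra-threshold
  std::vector<int> active;
  active.reserve(V);
  for (int i = 0; i < V; ++i) if (stat[i] > 0.0) active.push_back(i);

  std::vector<int> stamp(V, -1);
  std::vector<int> stack, members;
  stack.reserve(active.size());
  members.reserve(active.size());

  for (int s = 1; s <= n_steps; ++s) {
    // the top threshold is exactly hmax; s*dh can round past it and lose
    // the maximum voxel's final contribution
    const double h = (s == n_steps) ? hmax : s * dh;
    const double hH = std::pow(h, H) * dh;
    for (size_t ai = 0; ai < active.size(); ++ai) {
      const int seed = active[ai];
      if (stat[seed] < h || stamp[seed] == s) continue;
      // flood fill the component containing `seed`
      members.clear(); stack.clear();
      stack.push_back(seed); stamp[seed] = s;
      while (!stack.empty()) {
        const int v = stack.back(); stack.pop_back();
        members.push_back(v);
        const int vx = v % nx, vy = (v / nx) % ny, vz = v / (nx * ny);
        for (int k = 0; k < nn; ++k) {
          const int x = vx + ndx[k], y = vy + ndy[k], z = vz + ndz[k];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          const int w = x + nx * (y + ny * z);
          if (stamp[w] != s && stat[w] >= h) {
            stamp[w] = s;
            stack.push_back(w);
          }
        }
      }
      const double add = std::pow((double)members.size(), E) * hH;
      for (size_t m = 0; m < members.size(); ++m) out[members[m]] += add;
    }
  }
  return out;
}
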