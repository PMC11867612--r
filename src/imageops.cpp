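#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <unordered_map>
using namespace Rcpp;

// Greedy minimum-separation suppression of candidate peaks.
// Candidates must be pre-sorted by priority (descending intensity, ties by
// ascending index). Coordinates are physical (um). Returns a logical vector:
// TRUE = kept. Uses a uniform grid hash with cell size = min_sep so each
// candidate only checks neighbouring cells.
// [[Rcpp::export(name = ".cpp_suppress_min_sep")]]
LogicalVector cpp_suppress_min_sep(NumericMatrix coords, double min_sep) {
  const int n = coords.nrow();
  LogicalVector keep(n);
  if (n == 0) return keep;
  const double cell = min_sep > 0 ? min_sep : 1.0;
  const double sep2 = min_sep * min_sep;
  // hash key from 3D cell indices
  auto key = [&](long long ix, long long iy, long long iz) {
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  };
  std::unordered_map<long long, std::vector<int> > grid;
  for (int i = 0; i < n; ++i) {
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    const long long ix = (long long)std::floor(x / cell);
    const long long iy = (long long)std::floor(y / cell);
    const long long iz = (long long)std::floor(z / cell);
    bool ok = true;
    for (long long dx = -1; dx <= 1 && ok; ++dx)
      for (long long dy = -1; dy <= 1 && ok; ++dy)
        for (long long dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = x - coords(j, 0);
            const double ddy = y - coords(j, 1);
            const double ddz = z - coords(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < sep2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      grid[key(ix, iy, iz)].push_back(i);
    }
  }
  return keep;
}

struct QItem {
  double priority;   // inverted intensity: lower = flooded first
  long long order;   // FIFO tie-break for determinism
  int idx;           // linear voxel index
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;
  }
};

// Marker-based watershed by Meyer flooding on the inverted intensity
// landscape, restricted to `mask`. 6-connectivity (4 in a single plane).
// img: intensity vector (column-major [y, x, z]); dims = (ny, nx, nz);
// seeds: 1-based linear indices, one marker label per seed (1..nseeds).
// Returns integer label vector, 0 outside the mask.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector img, IntegerVector dims,
                            IntegerVector seeds, LogicalVector mask) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(nvox, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long order = 0;

  for (int s = 0; s < seeds.size(); ++s) {
    const int idx = seeds[s] - 1;
    if (idx < 0 || idx >= nvox || !mask[idx]) continue;
    labels[idx] = s + 1;
    pq.push({img[idx], order++, idx});
  }

  const int planesz = ny * nx;
  while (!pq.empty()) {
    const QItem it = pq.top(); pq.pop();
    const int idx = it.idx;
    const int z = idx / planesz;
    const int rem = idx - z * planesz;
    const int x = rem / ny;
    const int y = rem - x * ny;
    const int lab = labels[idx];
    const int dyv[6] = {-1, 1, 0, 0, 0, 0};
    const int dxv[6] = {0, 0, -1, 1, 0, 0};
    const int dzv[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      const int yy = y + dyv[k], xx = x + dxv[k], zz = z + dzv[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      const int nidx = yy + xx * ny + zz * planesz;
      if (!mask[nidx] || labels[nidx] != 0) continue;
      labels[nidx] = lab;
      pq.push({img[nidx], order++, nidx});
    }
  }
  return labels;
}

// 26-connected local maxima: voxel must be >= every in-bounds neighbour and
// > at least one of them (constant plateaus yield none). Returns 1-based
// linear indices into the column-major [y, x, z] array.
// [[Rcpp::export(name = ".cpp_local_maxima")]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int planesz = ny * nx;
  std::vector<int> out;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        const int idx = y + x * ny + z * planesz;
        const double v = img[idx];
        bool ge_all = true, gt_one = false;
        for (int dz = -1; dz <= 1 && ge_all; ++dz)
          for (int dx = -1; dx <= 1 && ge_all; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              if (dy == 0 && dx == 0 && dz == 0) continue;
              const int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                  zz < 0 || zz >= nz) continue;
              const double w = img[yy + xx * ny + zz * planesz];
              if (v < w) { ge_all = false; break; }
              if (v > w) gt_one = true;
            }
        if (ge_all && gt_one) out.push_back(idx + 1);
      }
  return wrap(out);
}

// Accumulate anisotropic Gaussian spots (peak amplitude, sigma per axis in
// um) onto a column-major [y, x, z] volume, evaluated at voxel centers
// within +/- 3.5 sigma. Modifies and returns a copy.
// [[Rcpp::export(name = ".cpp_add_spots")]]
NumericVector cpp_add_spots(NumericVector img, IntegerVector dims,
                            NumericMatrix centers, NumericVector peaks,
                            NumericVector sigma_um,
                            NumericVector voxel_size_um) {
  NumericVector out = clone(img);
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int planesz = ny * nx;
  const double vx = voxel_size_um[0], vy = voxel_size_um[1],
               vz = voxel_size_um[2];
  const double sx = sigma_um[0], sy = sigma_um[1], sz = sigma_um[2];
  const int rx = (int)std::ceil(3.5 * sx / vx);
  const int ry = (int)std::ceil(3.5 * sy / vy);
  const int rz = (int)std::ceil(3.5 * sz / vz);
  for (int b = 0; b < centers.nrow(); ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double pk = peaks[b];
    const int jc = (int)std::floor(cx / vx);
    const int ic = (int)std::floor(cy / vy);
    const int kc = (int)std::floor(cz / vz);
    for (int k = std::max(0, kc - rz); k <= std::min(nz - 1, kc + rz); ++k) {
      const double dz = (k + 0.5) * vz - cz;
      const double gz = std::exp(-dz * dz / (2 * sz * sz));
      for (int j = std::max(0, jc - rx); j <= std::min(nx - 1, jc + rx); ++j) {
        const double dx = (j + 0.5) * vx - cx;
        const double gx = std::exp(-dx * dx / (2 * sx * sx));
        for (int i = std::max(0, ic - ry); i <= std::min(ny - 1, ic + ry); ++i) {
          const double dy = (i + 0.5) * vy - cy;
          out[i + j * ny + k * planesz] +=
            pk * gx * gz * std::exp(-dy * dy / (2 * sy * sy));
        }
      }
    }
  }
  return out;
}
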