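#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level arrays are passed as integer vectors in R array order
// (column-major, x fastest) with 0 marking voxels outside the ROI.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_zone_sizes")]]
IntegerMatrix cpp_zone_sizes(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> zlevel, zsize;
  std::vector<int> stack;
  stack.reserve(256);

  for (int p = 0; p < n; ++p) {
    if (levels[p] == 0 || visited[p]) continue;
    const int g = levels[p];
    int size = 0;
    visited[p] = 1;
    stack.push_back(p);
    while (!stack.empty()) {
      const int q = stack.back();
      stack.pop_back();
      ++size;
      const int zq = q / (nx * ny);
      const int yq = (q / nx) % ny;
      const int xq = q % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = zq + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = yq + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x2 = xq + dx;
            if (x2 < 0 || x2 >= nx) continue;
            const int r = idx3(x2, y2, z2, nx, ny);
            if (!visited[r] && levels[r] == g) {
              visited[r] = 1;
              stack.push_back(r);
            }
          }
        }
      }
    }
    zlevel.push_back(g);
    zsize.push_back(size);
  }

  IntegerMatrix out(zlevel.size(), 2);
  for (size_t i = 0; i < zlevel.size(); ++i) {
    out(i, 0) = zlevel[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_run_counts")]]
IntegerMatrix cpp_run_counts(IntegerVector levels, IntegerVector dim,
                             IntegerMatrix directions) {
  // Enumerates maximal same-level runs along each direction; runs break at
  // ROI boundaries (level 0) and grid edges. Returns (direction, level,
  // run length) rows, one per run.
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> rdir, rlev, rlen;

  for (int d = 0; d < directions.nrow(); ++d) {
    const int dx = directions(d, 0), dy = directions(d, 1), dz = directions(d, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          // only start walking at line origins (previous voxel off-grid)
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            continue;
          int cx = x, cy = y, cz = z;
          int cur = 0, len = 0;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            const int g = levels[idx3(cx, cy, cz, nx, ny)];
            if (g == cur) {
              if (g != 0) ++len;
            } else {
              if (cur != 0) {
                rdir.push_back(d + 1); rlev.push_back(cur); rlen.push_back(len);
              }
              cur = g;
              len = (g != 0) ? 1 : 0;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur != 0) {
            rdir.push_back(d + 1); rlev.push_back(cur); rlen.push_back(len);
          }
        }
      }
    }
  }

  IntegerMatrix out(rdir.size(), 3);
  for (size_t i = 0; i < rdir.size(); ++i) {
    out(i, 0) = rdir[i];
    out(i, 1) = rlev[i];
    out(i, 2) = rlen[i];
  }
  return out;
}
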