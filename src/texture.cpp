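#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26-connected zones of equal gray level. `levels` is a flattened 3D integer
// array with NA outside the ROI. Returns a 2-column matrix (level, zone size),
// one row per zone.
// [[Rcpp::export(name = ".zone_sizes_26")]]
IntegerMatrix zone_sizes_26(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = levels.size();
  std::vector<char> seen(n, 0);
  std::vector<int> out_level, out_size, stack;
  stack.reserve(1024);

  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || levels[s] == NA_INTEGER) continue;
    const int lev = levels[s];
    int size = 0;
    seen[s] = 1;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            const int w = xx + nx * (yy + ny * zz);
            if (!seen[w] && levels[w] == lev) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
        }
      }
    }
    out_level.push_back(lev);
    out_size.push_back(size);
  }

  IntegerMatrix res(out_level.size(), 2);
  for (size_t i = 0; i < out_level.size(); ++i) {
    res(i, 0) = out_level[i];
    res(i, 1) = out_size[i];
  }
  colnames(res) = CharacterVector::create("level", "size");
  return res;
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  const double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  const double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  const double cx = u[1] * v[2] - u[2] * v[1];
  const double cy = u[2] * v[0] - u[0] * v[2];
  const double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Isosurface area of a scalar field by marching tetrahedra: each grid cell is
// split into 6 tetrahedra; within a tetrahedron the `level` crossing is
// triangulated with linear interpolation along edges. `field` is a flattened
// 3D array; `spacing` gives physical voxel size (mm).
// [[Rcpp::export(name = ".isosurface_area_mt")]]
double isosurface_area_mt(NumericVector field, IntegerVector dims,
                          NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, index c = x + 2y + 4z
  static const int corner[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                                   {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6-tetrahedron decomposition around the main diagonal 0-7
  static const int tets[6][4] = {{0,1,3,7},{0,1,5,7},{0,2,3,7},
                                 {0,2,6,7},{0,4,5,7},{0,4,6,7}};
  double area = 0.0;
  double val[8];
  double pos[8][3];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int xx = x + corner[c][0], yy = y + corner[c][1],
                    zz = z + corner[c][2];
          val[c] = field[xx + nx * (yy + (R_xlen_t)ny * zz)];
          pos[c][0] = xx * sx; pos[c][1] = yy * sy; pos[c][2] = zz * sz;
          (val[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int inside[4], nin = 0;
          for (int k = 0; k < 4; ++k)
            if (val[T[k]] > level) inside[nin++] = k;
          if (nin == 0 || nin == 4) continue;
          // edge crossing points between vertex sets
          double pts[4][3];
          int np = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b) {
              const double va = val[T[a]], vb = val[T[b]];
              if ((va > level) == (vb > level)) continue;
              const double w = (level - va) / (vb - va);
              for (int d = 0; d < 3; ++d)
                pts[np][d] = pos[T[a]][d] + w * (pos[T[b]][d] - pos[T[a]][d]);
              ++np;
            }
          if (np == 3) {
            area += tri_area(pts[0], pts[1], pts[2]);
          } else if (np == 4) {
            // quad: order is a-b, a-c (or similar); split on shorter diagonal
            // after sorting into a fan around pts[0]
            area += tri_area(pts[0], pts[1], pts[2]) +
                    tri_area(pts[1], pts[3], pts[2]);
          }
        }
      }
  return area;
}
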