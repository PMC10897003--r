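#ifndef ALN_INTERP_H
#define ALN_INTERP_H

#include <algorithm>

// Bilinear interpolation on an ascending rectangular grid with clamping to
// the boundary value for out-of-range queries.
inline void bilinear_clamped(const double* grid_x, int nx,
                             const double* grid_y, int ny, double x, double y,
                             int* ix_out, int* iy_out, double* fx_out,
                             double* fy_out) {
  int ix, iy;
  double fx, fy;
  if (x <= grid_x[0]) {
    ix = 0; fx = 0.0;
  } else if (x >= grid_x[nx - 1]) {
    ix = nx - 2; fx = 1.0;
  } else {
    ix = (int)(std::upper_bound(grid_x, grid_x + nx, x) - grid_x) - 1;
    if (ix > nx - 2) ix = nx - 2;
    fx = (x - grid_x[ix]) / (grid_x[ix + 1] - grid_x[ix]);
  }
  if (y <= grid_y[0]) {
    iy = 0; fy = 0.0;
  } else if (y >= grid_y[ny - 1]) {
    iy = ny - 2; fy = 1.0;
  } else {
    iy = (int)(std::upper_bound(grid_y, grid_y + ny, y) - grid_y) - 1;
    if (iy > ny - 2) iy = ny - 2;
    fy = (y - grid_y[iy]) / (grid_y[iy + 1] - grid_y[iy]);
  }
  *ix_out = ix; *iy_out = iy; *fx_out = fx; *fy_out = fy;
}

inline double bilinear_value(const double* tab, int nx, int ix, int iy,
                             double fx, double fy) {
  const double v00 = tab[ix + nx * iy];
  const double v10 = tab[ix + 1 + nx * iy];
  const double v01 = tab[ix + nx * (iy + 1)];
  const double v11 = tab[ix + 1 + nx * (iy + 1)];
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

#endif
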