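#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at 0-based positions.
// pad == 0: zero outside the grid; pad == 1: clamp coordinates to the grid.
// Optionally returns the spatial gradient of the interpolant.
// [[Rcpp::export]]
List cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                          NumericVector px, NumericVector py,
                          NumericVector pz, bool grad, int pad) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = px.size();
  NumericVector v(n);
  NumericVector gx, gy, gz;
  if (grad) { gx = NumericVector(n); gy = NumericVector(n); gz = NumericVector(n); }
  const double *V = vol.begin();

  for (R_xlen_t i = 0; i < n; ++i) {
    double x = px[i], y = py[i], z = pz[i];
    if (pad == 1) {
      x = std::min(std::max(x, 0.0), (double)(d1 - 1));
      y = std::min(std::max(y, 0.0), (double)(d2 - 1));
      z = std::min(std::max(z, 0.0), (double)(d3 - 1));
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (pad == 1) {
      x0 = std::min(x0, d1 - 2); y0 = std::min(y0, d2 - 2); z0 = std::min(z0, d3 - 2);
    }
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double c[8];
    for (int k = 0; k < 8; ++k) {
      const int ix = x0 + (k & 1), iy = y0 + ((k >> 1) & 1), iz = z0 + (k >> 2);
      if (ix < 0 || ix >= d1 || iy < 0 || iy >= d2 || iz < 0 || iz >= d3)
        c[k] = 0.0;
      else
        c[k] = V[ix + (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz)];
    }
    const double w00 = c[0] * (1 - fx) + c[1] * fx;
    const double w10 = c[2] * (1 - fx) + c[3] * fx;
    const double w01 = c[4] * (1 - fx) + c[5] * fx;
    const double w11 = c[6] * (1 - fx) + c[7] * fx;
    const double v0 = w00 * (1 - fy) + w10 * fy;
    const double v1 = w01 * (1 - fy) + w11 * fy;
    v[i] = v0 * (1 - fz) + v1 * fz;
    if (grad) {
      gx[i] = ((c[1] - c[0]) * (1 - fy) + (c[3] - c[2]) * fy) * (1 - fz) +
              ((c[5] - c[4]) * (1 - fy) + (c[7] - c[6]) * fy) * fz;
      gy[i] = (w10 - w00) * (1 - fz) + (w11 - w01) * fz;
      gz[i] = v1 - v0;
    }
  }
  if (grad)
    return List::create(_["v"] = v, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
  return List::create(_["v"] = v);
}

// Diffusion penalty of a displacement field u (nx*ny*nz*3 array): mean of
// the 3 per-component sums of per-axis mean squared forward differences,
// with optional gradient.
// [[Rcpp::export]]
List cpp_reg_grad(NumericVector u, IntegerVector dim, bool grad) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  const double *U = u.begin();
  NumericVector G;
  double *Gp = nullptr;
  if (grad) { G = NumericVector(u.size()); Gp = G.begin(); }
  const double m1 = (double)(d1 - 1) * d2 * d3;
  const double m2 = (double)d1 * (d2 - 1) * d3;
  const double m3 = (double)d1 * d2 * (d3 - 1);
  double value = 0.0;
  for (int cc = 0; cc < 3; ++cc) {
    const double *uc = U + cc * nvox;
    double *gc = grad ? Gp + cc * nvox : nullptr;
    for (int iz = 0; iz < d3; ++iz) {
      for (int iy = 0; iy < d2; ++iy) {
        const R_xlen_t base = (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz);
        for (int ix = 0; ix < d1; ++ix) {
          const R_xlen_t idx = base + ix;
          const double uv = uc[idx];
          if (ix + 1 < d1) {
            const double df = uc[idx + 1] - uv;
            value += df * df / m1;
            if (grad) {
              const double g = 2.0 * df / (3.0 * m1);
              gc[idx] -= g; gc[idx + 1] += g;
            }
          }
          if (iy + 1 < d2) {
            const double df = uc[idx + d1] - uv;
            value += df * df / m2;
            if (grad) {
              const double g = 2.0 * df / (3.0 * m2);
              gc[idx] -= g; gc[idx + d1] += g;
            }
          }
          if (iz + 1 < d3) {
            const double df = uc[idx + (R_xlen_t)d1 * d2] - uv;
            value += df * df / m3;
            if (grad) {
              const double g = 2.0 * df / (3.0 * m3);
              gc[idx] -= g; gc[idx + (R_xlen_t)d1 * d2] += g;
            }
          }
        }
      }
    }
  }
  if (grad) return List::create(_["value"] = value / 3.0, _["grad"] = G);
  return List::create(_["value"] = value / 3.0);
}
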