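// Numerical kernels for volumetric conv-net layers and the phantom dose engine.
//
// Array conventions (R column-major throughout):
//   feature volumes  dim = (nx, ny, nz, C)      x fastest
//   conv weights     dim = (k, k, k, Cin, Cout)
//   plain volumes    dim = (nx, ny, nz)
// Convolutions are "same" padded for k = 3 (pad 1) and unpadded for k = 1;
// stride 2 with even extents halves each axis exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& nx, int& ny, int& nz, int& nc) {
  IntegerVector d = x.attr("dim");
  if (d.size() < 3) stop("expected an array with >= 3 dimensions");
  nx = d[0]; ny = d[1]; nz = d[2];
  nc = d.size() > 3 ? d[3] : 1;
}

static inline int outExtent(int n, int k, int s) {
  int pad = (k == 3) ? 1 : 0;
  return (n + 2 * pad - k) / s + 1;
}

// Fill im2col buffer for output voxels [v0, v1) (flattened x-fastest over
// the output grid). col is (Cin*k^3) x (v1-v0), column-major.
static void im2col_chunk(const double* x, int nx, int ny, int nz, int nc,
                         int k, int s, int ox, int oy, int oz,
                         std::size_t v0, std::size_t v1, double* col) {
  const int pad = (k == 3) ? 1 : 0;
  const int krows = nc * k * k * k;
  const std::size_t planexy = (std::size_t)nx * ny;
  for (std::size_t v = v0; v < v1; ++v) {
    int rem = (int)(v % ((std::size_t)ox * oy));
    int izo = (int)(v / ((std::size_t)ox * oy));
    int iyo = rem / ox;
    int ixo = rem % ox;
    int x0 = ixo * s - pad, y0 = iyo * s - pad, z0 = izo * s - pad;
    double* c = col + (v - v0) * krows;
    for (int ci = 0; ci < nc; ++ci) {
      const double* xc = x + (std::size_t)ci * planexy * nz;
      for (int kz = 0; kz < k; ++kz) {
        int iz = z0 + kz;
        bool zok = iz >= 0 && iz < nz;
        for (int ky = 0; ky < k; ++ky) {
          int iy = y0 + ky;
          bool yok = zok && iy >= 0 && iy < ny;
          const double* row = yok ? xc + planexy * iz + (std::size_t)nx * iy : nullptr;
          for (int kx = 0; kx < k; ++kx) {
            int ix = x0 + kx;
            double val = (yok && ix >= 0 && ix < nx) ? row[ix] : 0.0;
            // row index: kx + k*(ky + k*(kz + k*ci)) matches weight layout
            c[kx + k * (ky + k * (kz + k * ci))] = val;
          }
        }
      }
    }
  }
}

static std::size_t chunkCols(int krows) {
  std::size_t target = 4000000; // ~32 MB double workspace cap
  std::size_t ncols = target / (std::size_t)krows;
  if (ncols < 1024) ncols = 1024;
  return ncols;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cin = wd[3], cout = wd[4];
  if (cin != nc) stop("conv3d: input channel mismatch");
  int ox = outExtent(nx, k, stride), oy = outExtent(ny, k, stride),
      oz = outExtent(nz, k, stride);
  std::size_t nov = (std::size_t)ox * oy * oz;
  NumericVector y(nov * cout);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  const int krows = nc * k * k * k;
  arma::mat W(w.begin(), krows, cout, false, true);
  std::size_t step = chunkCols(krows);
  arma::mat col(krows, std::min(step, nov));
  double* yp = y.begin();
  for (std::size_t v0 = 0; v0 < nov; v0 += step) {
    std::size_t v1 = std::min(v0 + step, nov);
    std::size_t nv = v1 - v0;
    im2col_chunk(x.begin(), nx, ny, nz, nc, k, stride, ox, oy, oz, v0, v1,
                 col.memptr());
    arma::mat yc = W.t() * col.cols(0, nv - 1); // cout x nv
    for (int c = 0; c < cout; ++c) {
      double bc = b[c];
      double* dst = yp + (std::size_t)c * nov + v0;
      for (std::size_t j = 0; j < nv; ++j) dst[j] = yc(c, j) + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, bool need_dx) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cout = wd[4];
  int ox = outExtent(nx, k, stride), oy = outExtent(ny, k, stride),
      oz = outExtent(nz, k, stride);
  std::size_t nov = (std::size_t)ox * oy * oz;
  const int krows = nc * k * k * k;
  const int pad = (k == 3) ? 1 : 0;
  arma::mat W(w.begin(), krows, cout, false, true);
  arma::mat dW(krows, cout, arma::fill::zeros);
  NumericVector db(cout);
  NumericVector dx;
  double* dxp = nullptr;
  if (need_dx) {
    dx = NumericVector((std::size_t)nx * ny * nz * nc);
    dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
    dxp = dx.begin();
  }
  const std::size_t planexy = (std::size_t)nx * ny;
  std::size_t step = chunkCols(krows);
  arma::mat col(krows, std::min(step, nov));
  arma::mat gyc(std::min(step, nov), cout);
  const double* gp = gy.begin();
  for (std::size_t v0 = 0; v0 < nov; v0 += step) {
    std::size_t v1 = std::min(v0 + step, nov);
    std::size_t nv = v1 - v0;
    im2col_chunk(x.begin(), nx, ny, nz, nc, k, stride, ox, oy, oz, v0, v1,
                 col.memptr());
    for (int c = 0; c < cout; ++c) {
      const double* src = gp + (std::size_t)c * nov + v0;
      double s = 0;
      for (std::size_t j = 0; j < nv; ++j) { gyc(j, c) = src[j]; s += src[j]; }
      db[c] += s;
    }
    dW += col.cols(0, nv - 1) * gyc.rows(0, nv - 1);
    if (need_dx) {
      arma::mat dcol = W * gyc.rows(0, nv - 1).t(); // krows x nv
      // col2im scatter-add
      for (std::size_t v = v0; v < v1; ++v) {
        int rem = (int)(v % ((std::size_t)ox * oy));
        int izo = (int)(v / ((std::size_t)ox * oy));
        int iyo = rem / ox, ixo = rem % ox;
        int x0 = ixo * stride - pad, y0 = iyo * stride - pad,
            z0 = izo * stride - pad;
        const double* c = dcol.colptr(v - v0);
        for (int ci = 0; ci < nc; ++ci) {
          double* xc = dxp + (std::size_t)ci * planexy * nz;
          for (int kz = 0; kz < k; ++kz) {
            int iz = z0 + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              int iy = y0 + ky;
              if (iy < 0 || iy >= ny) continue;
              double* row = xc + planexy * iz + (std::size_t)nx * iy;
              for (int kx = 0; kx < k; ++kx) {
                int ix = x0 + kx;
                if (ix < 0 || ix >= nx) continue;
                row[ix] += c[kx + k * (ky + k * (kz + k * ci))];
              }
            }
          }
        }
      }
    }
  }
  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// Trilinear x2 upsampling with half-pixel centers: src = (dst + 0.5)/2 - 0.5.
static void up2_weights(int o, int n, int& i0, int& i1, double& w1) {
  double s = (o + 0.5) / 2.0 - 0.5;
  double f = std::floor(s);
  i0 = (int)f; i1 = i0 + 1;
  w1 = s - f;
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  NumericVector y((std::size_t)mx * my * mz * nc);
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<int> xi0(mx), xi1(mx), yi0(my), yi1(my), zi0(mz), zi1(mz);
  std::vector<double> xw(mx), yw(my), zw(mz);
  for (int o = 0; o < mx; ++o) up2_weights(o, nx, xi0[o], xi1[o], xw[o]);
  for (int o = 0; o < my; ++o) up2_weights(o, ny, yi0[o], yi1[o], yw[o]);
  for (int o = 0; o < mz; ++o) up2_weights(o, nz, zi0[o], zi1[o], zw[o]);
  const std::size_t sxy = (std::size_t)nx * ny, dxy = (std::size_t)mx * my;
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + (std::size_t)c * sxy * nz;
    double* yc = yp + (std::size_t)c * dxy * mz;
    for (int oz = 0; oz < mz; ++oz) {
      const double* z0 = xc + sxy * zi0[oz];
      const double* z1 = xc + sxy * zi1[oz];
      double wz = zw[oz];
      for (int oy = 0; oy < my; ++oy) {
        const double* r00 = z0 + (std::size_t)nx * yi0[oy];
        const double* r01 = z0 + (std::size_t)nx * yi1[oy];
        const double* r10 = z1 + (std::size_t)nx * yi0[oy];
        const double* r11 = z1 + (std::size_t)nx * yi1[oy];
        double wy = yw[oy];
        double* out = yc + dxy * oz + (std::size_t)mx * oy;
        for (int ox = 0; ox < mx; ++ox) {
          double wx = xw[ox];
          int a = xi0[ox], b = xi1[ox];
          double v00 = r00[a] * (1 - wx) + r00[b] * wx;
          double v01 = r01[a] * (1 - wx) + r01[b] * wx;
          double v10 = r10[a] * (1 - wx) + r10[b] * wx;
          double v11 = r11[a] * (1 - wx) + r11[b] * wx;
          double v0 = v00 * (1 - wy) + v01 * wy;
          double v1 = v10 * (1 - wy) + v11 * wy;
          out[ox] = v0 * (1 - wz) + v1 * wz;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy, int nx, int ny, int nz) {
  int mx, my, mz, nc;
  dims4(gy, mx, my, mz, nc);
  if (mx != 2 * nx || my != 2 * ny || mz != 2 * nz)
    stop("upsample2 backward: size mismatch");
  NumericVector dx((std::size_t)nx * ny * nz * nc);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  std::vector<int> xi0(mx), xi1(mx), yi0(my), yi1(my), zi0(mz), zi1(mz);
  std::vector<double> xw(mx), yw(my), zw(mz);
  for (int o = 0; o < mx; ++o) up2_weights(o, nx, xi0[o], xi1[o], xw[o]);
  for (int o = 0; o < my; ++o) up2_weights(o, ny, yi0[o], yi1[o], yw[o]);
  for (int o = 0; o < mz; ++o) up2_weights(o, nz, zi0[o], zi1[o], zw[o]);
  const std::size_t sxy = (std::size_t)nx * ny, dxy = (std::size_t)mx * my;
  const double* gp = gy.begin();
  double* dp = dx.begin();
  for (int c = 0; c < nc; ++c) {
    const double* gc = gp + (std::size_t)c * dxy * mz;
    double* dc = dp + (std::size_t)c * sxy * nz;
    for (int oz = 0; oz < mz; ++oz) {
      double wz = zw[oz];
      for (int oy = 0; oy < my; ++oy) {
        double wy = yw[oy];
        const double* g = gc + dxy * oz + (std::size_t)mx * oy;
        for (int ox = 0; ox < mx; ++ox) {
          double wx = xw[ox], gv = g[ox];
          for (int dz = 0; dz < 2; ++dz) {
            int iz = dz ? zi1[oz] : zi0[oz];
            double wzz = dz ? wz : 1 - wz;
            for (int dy = 0; dy < 2; ++dy) {
              int iy = dy ? yi1[oy] : yi0[oy];
              double wyy = dy ? wy : 1 - wy;
              double* row = dc + sxy * iz + (std::size_t)nx * iy;
              row[xi0[ox]] += gv * wzz * wyy * (1 - wx);
              row[xi1[ox]] += gv * wzz * wyy * wx;
            }
          }
        }
      }
    }
  }
  return dx;
}

// Rotate a (nx, ny, nz[, C]) volume about the z (superior-inferior) axis by
// angle_deg, about the x-y center, resampling from the source volume
// (bilinear or nearest), out-of-grid -> fill.
// Positive angles rotate +x toward +y (right-handed about +z).
// [[Rcpp::export]]
NumericVector cpp_rotate_z(NumericVector x, double angle_deg, bool nearest,
                           double fill) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  NumericVector y(clone(x));
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const std::size_t pxy = (std::size_t)nx * ny;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < nc; ++c) {
    for (int iz = 0; iz < nz; ++iz) {
      const double* src = xp + ((std::size_t)c * nz + iz) * pxy;
      double* dst = yp + ((std::size_t)c * nz + iz) * pxy;
      for (int iy = 0; iy < ny; ++iy) {
        double dy = iy - cy;
        for (int ix = 0; ix < nx; ++ix) {
          double dx0 = ix - cx;
          // inverse map: source coords of this output pixel
          double sx = ca * dx0 + sa * dy + cx;
          double sy = -sa * dx0 + ca * dy + cy;
          double val;
          if (nearest) {
            int jx = (int)std::lround(sx), jy = (int)std::lround(sy);
            val = (jx >= 0 && jx < nx && jy >= 0 && jy < ny)
                      ? src[(std::size_t)nx * jy + jx] : fill;
          } else {
            int jx = (int)std::floor(sx), jy = (int)std::floor(sy);
            double fx = sx - jx, fy = sy - jy;
            val = 0; double wsum = 0; bool any = false;
            for (int b2 = 0; b2 < 2; ++b2)
              for (int b1 = 0; b1 < 2; ++b1) {
                int px = jx + b1, py = jy + b2;
                double w = (b1 ? fx : 1 - fx) * (b2 ? fy : 1 - fy);
                if (px >= 0 && px < nx && py >= 0 && py < ny) {
                  val += w * src[(std::size_t)nx * py + px];
                  wsum += w; any = true;
                } else {
                  val += w * fill; wsum += w;
                }
              }
            if (!any) val = fill;
          }
          dst[(std::size_t)nx * iy + ix] = val;
        }
      }
    }
  }
  return y;
}

// Radiological depth: for every voxel, integrate relative density along the
// straight line from the source to the voxel center (trilinear samples every
// step_mm, outside-grid density 0). origin = mm position of voxel (1,1,1)
// center; spacing in mm.
// [[Rcpp::export]]
NumericVector cpp_ray_depth(NumericVector dens, NumericVector spacing,
                            NumericVector origin, NumericVector source,
                            double step_mm) {
  int nx, ny, nz, nc;
  dims4(dens, nx, ny, nz, nc);
  NumericVector out((std::size_t)nx * ny * nz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* d = dens.begin();
  double* o = out.begin();
  const std::size_t pxy = (std::size_t)nx * ny;
  double sx = source[0], sy = source[1], sz = source[2];
  std::size_t v = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double pz = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double py = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix, ++v) {
        double px = origin[0] + ix * spacing[0];
        double vx = px - sx, vy = py - sy, vz = pz - sz;
        double L = std::sqrt(vx * vx + vy * vy + vz * vz);
        int nstep = (int)std::ceil(L / step_mm);
        if (nstep < 1) nstep = 1;
        double dt = L / nstep;
        double acc = 0;
        // midpoint sampling along the ray
        for (int sI = 0; sI < nstep; ++sI) {
          double t = (sI + 0.5) / nstep;
          double qx = (sx + t * vx - origin[0]) / spacing[0];
          double qy = (sy + t * vy - origin[1]) / spacing[1];
          double qz = (sz + t * vz - origin[2]) / spacing[2];
          int jx = (int)std::floor(qx), jy = (int)std::floor(qy),
              jz = (int)std::floor(qz);
          if (jx < -1 || jx > nx - 1 || jy < -1 || jy > ny - 1 || jz < -1 ||
              jz > nz - 1)
            continue;
          double fx = qx - jx, fy = qy - jy, fz = qz - jz;
          double val = 0;
          for (int b3 = 0; b3 < 2; ++b3)
            for (int b2 = 0; b2 < 2; ++b2)
              for (int b1 = 0; b1 < 2; ++b1) {
                int ax = jx + b1, ay = jy + b2, az = jz + b3;
                if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 ||
                    az >= nz)
                  continue;
                double w = (b1 ? fx : 1 - fx) * (b2 ? fy : 1 - fy) *
                           (b3 ? fz : 1 - fz);
                val += w * d[pxy * az + (std::size_t)nx * ay + ax];
              }
          acc += val * dt;
        }
        o[v] = acc;
      }
    }
  }
  return out;
}

// Separable Gaussian blur of a 3D volume, reflecting boundaries; sigma in
// voxels per axis, kernel radius 3*sigma.
static void blur1d(std::vector<double>& buf, const double* in, int n,
                   std::ptrdiff_t stride, const std::vector<double>& kern,
                   double* out) {
  int r = ((int)kern.size() - 1) / 2;
  for (int i = 0; i < n; ++i) buf[i] = in[(std::ptrdiff_t)i * stride];
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int j = -r; j <= r; ++j) {
      int s = i + j;
      if (s < 0) s = -s - 1;
      if (s >= n) s = 2 * n - 1 - s;
      acc += kern[j + r] * buf[s];
    }
    out[(std::ptrdiff_t)i * stride] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, NumericVector sigma_vox) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  NumericVector y(clone(x));
  double* p = y.begin();
  const std::size_t pxy = (std::size_t)nx * ny;
  int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3 * s));
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int j = -r; j <= r; ++j) {
      kern[j + r] = std::exp(-0.5 * j * j / (s * s));
      tot += kern[j + r];
    }
    for (auto& k : kern) k /= tot;
    std::vector<double> buf(dims[ax]);
    if (ax == 0) {
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy) {
          double* line = p + pxy * iz + (std::size_t)nx * iy;
          blur1d(buf, line, nx, 1, kern, line);
        }
    } else if (ax == 1) {
      for (int iz = 0; iz < nz; ++iz)
        for (int ix = 0; ix < nx; ++ix) {
          double* line = p + pxy * iz + ix;
          blur1d(buf, line, ny, nx, kern, line);
        }
    } else {
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          double* line = p + (std::size_t)nx * iy + ix;
          blur1d(buf, line, nz, (std::ptrdiff_t)pxy, kern, line);
        }
    }
  }
  return y;
}

// In-place instance normalization + affine + ReLU over a (nx,ny,nz,C)
// array; used on the inference path to avoid temporary copies.
// [[Rcpp::export]]
void cpp_in_relu(NumericVector x, NumericVector g, NumericVector be,
                 double eps) {
  int nx, ny, nz, nc;
  dims4(x, nx, ny, nz, nc);
  std::size_t nvox = (std::size_t)nx * ny * nz;
  double* p = x.begin();
  for (int c = 0; c < nc; ++c) {
    double* xc = p + (std::size_t)c * nvox;
    double s = 0;
    for (std::size_t i = 0; i < nvox; ++i) s += xc[i];
    double mu = s / nvox;
    double s2 = 0;
    for (std::size_t i = 0; i < nvox; ++i) {
      double d = xc[i] - mu;
      s2 += d * d;
    }
    double var = s2 / nvox;
    double inv = g[c] / std::sqrt(var + eps);
    double b0 = be[c];
    for (std::size_t i = 0; i < nvox; ++i) {
      double v = (xc[i] - mu) * inv + b0;
      xc[i] = v > 0 ? v : 0;
    }
  }
}
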