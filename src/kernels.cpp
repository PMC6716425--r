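#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Array layout convention: volumes are R arrays in column-major order with
// dims (nx, ny, nz, c); index = x + nx*(y + ny*(z + nz*c)). Convolution
// kernels have dims (k, k, k, cin, cout) with odd k and "same" padding.

static inline int idx4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return x + nx * (y + ny * (z + nz * c));
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, IntegerVector xdim,
                                 IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  const int hk = k / 2;
  NumericVector y(static_cast<R_xlen_t>(nx) * ny * nz * cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    const double bias = pb[co];
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
          double acc = bias;
          for (int ci = 0; ci < cin; ++ci) {
            for (int dz = -hk; dz <= hk; ++dz) {
              const int z2 = zz + dz;
              if (z2 < 0 || z2 >= nz) continue;
              for (int dy = -hk; dy <= hk; ++dy) {
                const int y2 = yy + dy;
                if (y2 < 0 || y2 >= ny) continue;
                for (int dx = -hk; dx <= hk; ++dx) {
                  const int x2 = xx + dx;
                  if (x2 < 0 || x2 >= nx) continue;
                  const int wi = (dx + hk) + k * ((dy + hk) + k * ((dz + hk)
                                 + k * (ci + cin * co)));
                  acc += px[idx4(x2, y2, z2, ci, nx, ny, nz)] * pw[wi];
                }
              }
            }
          }
          py[idx4(xx, yy, zz, co, nx, ny, nz)] = acc;
        }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector w, NumericVector gy,
                         IntegerVector xdim, IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  const int hk = k / 2;
  NumericVector gx(x.size()), gw(w.size()), gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < cout; ++co) {
    double bacc = 0.0;
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
          const double g = pgy[idx4(xx, yy, zz, co, nx, ny, nz)];
          bacc += g;
          if (g == 0.0) continue;
          for (int ci = 0; ci < cin; ++ci) {
            for (int dz = -hk; dz <= hk; ++dz) {
              const int z2 = zz + dz;
              if (z2 < 0 || z2 >= nz) continue;
              for (int dy = -hk; dy <= hk; ++dy) {
                const int y2 = yy + dy;
                if (y2 < 0 || y2 >= ny) continue;
                for (int dx = -hk; dx <= hk; ++dx) {
                  const int x2 = xx + dx;
                  if (x2 < 0 || x2 >= nx) continue;
                  const int wi = (dx + hk) + k * ((dy + hk) + k * ((dz + hk)
                                 + k * (ci + cin * co)));
                  const int xi = idx4(x2, y2, z2, ci, nx, ny, nz);
                  pgx[xi] += g * pw[wi];
                  pgw[wi] += g * px[xi];
                }
              }
            }
          }
        }
    pgb[co] = bacc;
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x max pooling; output dims floor(n/2) (inputs are kept divisible by the
// network config contract). Returns pooled values and flat argmax indices.
// [[Rcpp::export]]
List maxpool2_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y(static_cast<R_xlen_t>(ox) * oy * oz * c);
  IntegerVector arg(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int cc = 0; cc < c; ++cc)
    for (int zz = 0; zz < oz; ++zz)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx) {
          double best = -INFINITY; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int xi = idx4(2 * xx + dx, 2 * yy + dy, 2 * zz + dz,
                                    cc, nx, ny, nz);
                if (px[xi] > best) { best = px[xi]; bi = xi; }
              }
          const int oi = idx4(xx, yy, zz, cc, ox, oy, oz);
          py[oi] = best;
          pa[oi] = bi;
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward_cpp(IntegerVector argmax, NumericVector gy,
                                    IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2]
                   * xdim[3]);
  const double *pgy = gy.begin();
  const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pa[i]] += pgy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector y(static_cast<R_xlen_t>(ox) * oy * oz * c);
  const double *px = x.begin();
  double *py = y.begin();
  for (int cc = 0; cc < c; ++cc)
    for (int zz = 0; zz < oz; ++zz)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          py[idx4(xx, yy, zz, cc, ox, oy, oz)] =
            px[idx4(xx / 2, yy / 2, zz / 2, cc, nx, ny, nz)];
  y.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward_cpp(NumericVector gy, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector gx(static_cast<R_xlen_t>(nx) * ny * nz * c);
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  for (int cc = 0; cc < c; ++cc)
    for (int zz = 0; zz < oz; ++zz)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          pgx[idx4(xx / 2, yy / 2, zz / 2, cc, nx, ny, nz)] +=
            pgy[idx4(xx, yy, zz, cc, ox, oy, oz)];
  gx.attr("dim") = xdim;
  return gx;
}

// Trilinear resampling of a 3D volume. M is a 4x4 matrix mapping 0-based
// target voxel indices to continuous 0-based source indices. Samples with
// any corner outside the source grid are flagged outside and set to `fill`.
// [[Rcpp::export]]
List resample_trilinear_cpp(NumericVector src, IntegerVector sdim,
                            NumericMatrix M, IntegerVector odim,
                            double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz, fill);
  LogicalVector inside(out.size());
  const double *ps = src.begin();
  double *po = out.begin();
  int *pi = inside.begin();
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        const double u = M(0,0)*xx + M(0,1)*yy + M(0,2)*zz + M(0,3);
        const double v = M(1,0)*xx + M(1,1)*yy + M(1,2)*zz + M(1,3);
        const double w = M(2,0)*xx + M(2,1)*yy + M(2,2)*zz + M(2,3);
        const int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
                  k0 = (int)std::floor(w);
        const R_xlen_t oi = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= sx || j0 + 1 >= sy ||
            k0 + 1 >= sz) {
          pi[oi] = FALSE;
          continue;
        }
        const double fu = u - i0, fv = v - j0, fw = w - k0;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double wt = (dx ? fu : 1 - fu) * (dy ? fv : 1 - fv)
                                * (dz ? fw : 1 - fw);
              acc += wt * ps[(i0 + dx) + (R_xlen_t)sx *
                             ((j0 + dy) + (R_xlen_t)sy * (k0 + dz))];
            }
        po[oi] = acc;
        pi[oi] = TRUE;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Nearest-neighbour resampling of an integer label volume through the same
// index-space matrix convention as resample_trilinear_cpp.
// [[Rcpp::export]]
IntegerVector resample_nearest_cpp(IntegerVector src, IntegerVector sdim,
                                   NumericMatrix M, IntegerVector odim,
                                   int fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int nx = odim[0], ny = odim[1], nz = odim[2];
  IntegerVector out(static_cast<R_xlen_t>(nx) * ny * nz, fill);
  const int *ps = src.begin();
  int *po = out.begin();
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        const double u = M(0,0)*xx + M(0,1)*yy + M(0,2)*zz + M(0,3);
        const double v = M(1,0)*xx + M(1,1)*yy + M(1,2)*zz + M(1,3);
        const double w = M(2,0)*xx + M(2,1)*yy + M(2,2)*zz + M(2,3);
        const int i = (int)std::lround(u), j = (int)std::lround(v),
                  k = (int)std::lround(w);
        if (i < 0 || j < 0 || k < 0 || i >= sx || j >= sy || k >= sz)
          continue;
        po[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] =
          ps[i + (R_xlen_t)sx * (j + (R_xlen_t)sy * k)];
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Joint histogram with linear (Parzen, first-order) binning on both axes so
// the mutual-information surface is smooth in the transform parameters.
// Values are mapped to [0, bins-1] using the supplied ranges; samples
// outside the range are clamped.
// [[Rcpp::export]]
NumericMatrix joint_hist_linear_cpp(NumericVector a, NumericVector b,
                                    int bins, double amin, double amax,
                                    double bmin, double bmax) {
  NumericMatrix H(bins, bins);
  const double ascale = (bins - 1) / std::max(amax - amin, 1e-12);
  const double bscale = (bins - 1) / std::max(bmax - bmin, 1e-12);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    double u = (a[i] - amin) * ascale;
    double v = (b[i] - bmin) * bscale;
    if (u < 0) u = 0; if (u > bins - 1) u = bins - 1;
    if (v < 0) v = 0; if (v > bins - 1) v = bins - 1;
    const int u0 = std::min((int)std::floor(u), bins - 2);
    const int v0 = std::min((int)std::floor(v), bins - 2);
    const double fu = u - u0, fv = v - v0;
    H(u0, v0)         += (1 - fu) * (1 - fv);
    H(u0 + 1, v0)     += fu * (1 - fv);
    H(u0, v0 + 1)     += (1 - fu) * fv;
    H(u0 + 1, v0 + 1) += fu * fv;
  }
  return H;
}

// 2x block-mean downsampling (trailing odd slices averaged over the voxels
// that exist), used by the multi-resolution registration pyramid.
// [[Rcpp::export]]
NumericVector downsample2_mean_cpp(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(ox) * oy * oz);
  const double *px = x.begin();
  double *py = y.begin();
  for (int zz = 0; zz < oz; ++zz)
    for (int yy = 0; yy < oy; ++yy)
      for (int xx = 0; xx < ox; ++xx) {
        double acc = 0.0; int cnt = 0;
        for (int dz = 0; dz < 2; ++dz) {
          const int z2 = 2 * zz + dz;
          if (z2 >= nz) continue;
          for (int dy = 0; dy < 2; ++dy) {
            const int y2 = 2 * yy + dy;
            if (y2 >= ny) continue;
            for (int dx = 0; dx < 2; ++dx) {
              const int x2 = 2 * xx + dx;
              if (x2 >= nx) continue;
              acc += px[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              ++cnt;
            }
          }
        }
        py[xx + (R_xlen_t)ox * (yy + (R_xlen_t)oy * zz)] = acc / cnt;
      }
  y.attr("dim") = IntegerVector::create(ox, oy, oz);
  return y;
}
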