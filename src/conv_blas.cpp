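// BLAS-backed 3D convolution: im2col + GEMM. The naive 7-loop kernel is the
// training bottleneck; routing the inner product through Armadillo (BLAS)
// keeps full-volume training of the small networks within the test budget.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Columns layout: row = output voxel (x fastest), col = (kx,ky,kz,ci).
static void im2col3(const double *x, int nx, int ny, int nz, int cin, int k,
                    arma::mat &cols) {
  const int hk = k / 2;
  const long nvox = (long)nx * ny * nz;
  for (int ci = 0; ci < cin; ++ci) {
    const double *xc = x + (long)ci * nvox;
    for (int dz = -hk; dz <= hk; ++dz)
      for (int dy = -hk; dy <= hk; ++dy)
        for (int dx = -hk; dx <= hk; ++dx) {
          const int col = (dx + hk) + k * ((dy + hk) + k * ((dz + hk)
                          + k * ci));
          double *dst = cols.colptr(col);
          for (int zz = 0; zz < nz; ++zz) {
            const int z2 = zz + dz;
            const bool zok = z2 >= 0 && z2 < nz;
            for (int yy = 0; yy < ny; ++yy) {
              const int y2 = yy + dy;
              const bool yok = zok && y2 >= 0 && y2 < ny;
              long row = (long)nx * (yy + (long)ny * zz);
              if (!yok) {
                for (int xx = 0; xx < nx; ++xx) dst[row + xx] = 0.0;
                continue;
              }
              const double *src = xc + (long)nx * (y2 + (long)ny * z2);
              for (int xx = 0; xx < nx; ++xx) {
                const int x2 = xx + dx;
                dst[row + xx] = (x2 >= 0 && x2 < nx) ? src[x2] : 0.0;
              }
            }
          }
        }
  }
}

// Scatter-add the column representation back to image space (adjoint of
// im2col), used for the gradient w.r.t. the convolution input.
static void col2im3(const arma::mat &cols, int nx, int ny, int nz, int cin,
                    int k, double *gx) {
  const int hk = k / 2;
  const long nvox = (long)nx * ny * nz;
  std::fill(gx, gx + nvox * cin, 0.0);
  for (int ci = 0; ci < cin; ++ci) {
    double *gxc = gx + (long)ci * nvox;
    for (int dz = -hk; dz <= hk; ++dz)
      for (int dy = -hk; dy <= hk; ++dy)
        for (int dx = -hk; dx <= hk; ++dx) {
          const int col = (dx + hk) + k * ((dy + hk) + k * ((dz + hk)
                          + k * ci));
          const double *src = cols.colptr(col);
          for (int zz = 0; zz < nz; ++zz) {
            const int z2 = zz + dz;
            if (z2 < 0 || z2 >= nz) continue;
            for (int yy = 0; yy < ny; ++yy) {
              const int y2 = yy + dy;
              if (y2 < 0 || y2 >= ny) continue;
              const long row = (long)nx * (yy + (long)ny * zz);
              double *dst = gxc + (long)nx * (y2 + (long)ny * z2);
              for (int xx = 0; xx < nx; ++xx) {
                const int x2 = xx + dx;
                if (x2 >= 0 && x2 < nx) dst[x2] += src[row + xx];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_blas(NumericVector x, NumericVector w,
                                  NumericVector b, IntegerVector xdim,
                                  IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  const long nvox = (long)nx * ny * nz;
  arma::mat cols(nvox, (long)k * k * k * cin);
  im2col3(x.begin(), nx, ny, nz, cin, k, cols);
  const arma::mat W(const_cast<double *>(w.begin()), k * k * k * cin, cout,
                    false, true);
  arma::mat Y = cols * W;
  Y.each_row() += arma::rowvec(const_cast<double *>(b.begin()), cout, false,
                               true);
  NumericVector out(nvox * cout);
  std::copy(Y.memptr(), Y.memptr() + nvox * cout, out.begin());
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_blas(NumericVector x, NumericVector w, NumericVector gy,
                          IntegerVector xdim, IntegerVector wdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  const long nvox = (long)nx * ny * nz;
  arma::mat cols(nvox, (long)k * k * k * cin);
  im2col3(x.begin(), nx, ny, nz, cin, k, cols);
  const arma::mat W(const_cast<double *>(w.begin()), k * k * k * cin, cout,
                    false, true);
  const arma::mat GY(const_cast<double *>(gy.begin()), nvox, cout, false,
                     true);
  arma::mat GW = cols.t() * GY;
  arma::mat Gcols = GY * W.t();
  NumericVector gx(nvox * cin), gw(w.size()), gb(cout);
  col2im3(Gcols, nx, ny, nz, cin, k, gx.begin());
  std::copy(GW.memptr(), GW.memptr() + GW.n_elem, gw.begin());
  arma::rowvec gbv = arma::sum(GY, 0);
  std::copy(gbv.memptr(), gbv.memptr() + cout, gb.begin());
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
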