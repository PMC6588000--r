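// Stack-of-stars non-uniform Fourier encoding core.
//
// The forward map for one parameter encoding is
//   d(s, kz, c) = sum_x b_c(x) m(x) exp(-2i*pi*(k_s . (x-cx,y-cy), kz~(z-cz)/nz))
// factorised as a unitary Cartesian DFT along z followed by a per-slice
// 2D type-2 NUFFT, implemented by Kaiser-Bessel gridding on an oversampled
// grid (FFTW for the on-grid transforms).  The adjoint is the exact
// conjugate transpose of the discretised forward map, which the dot tests
// rely on.
//
// Interpolation indices/weights are precomputed in R (nufft_plan) and passed
// down; this file only does the heavy batched work.

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>
#include <map>
#include <utility>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// cached in-place 2D c2c plans keyed by (n, sign); planned on an aligned
// scratch buffer and executed on caller buffers of identical alignment.
static std::map<std::pair<int, int>, fftw_plan> plan_cache;

static fftw_plan get_plan2d(int n, int sign) {
  std::pair<int, int> key(n, sign);
  std::map<std::pair<int, int>, fftw_plan>::iterator it = plan_cache.find(key);
  if (it != plan_cache.end()) return it->second;
  fftw_complex* scratch = fftw_alloc_complex((size_t)n * n);
  fftw_plan p = fftw_plan_dft_2d(n, n, scratch, scratch, sign, FFTW_MEASURE);
  fftw_free(scratch);
  plan_cache[key] = p;
  return p;
}

static inline void fft2_exec(fftw_plan p, cplx* g) {
  fftw_execute_dft(p, reinterpret_cast<fftw_complex*>(g),
                   reinterpret_cast<fftw_complex*>(g));
}

// centred unitary DFT matrix along z: W(kz, z) = exp(-2i*pi*kz~*z~/nz)/sqrt(nz)
// with kz~ = kz - floor(nz/2), z~ = z - floor(nz/2); column-major (kz fastest).
static std::vector<cplx> zdft_matrix(int nz) {
  std::vector<cplx> W((size_t)nz * nz);
  int c = nz / 2;
  double s = 1.0 / std::sqrt((double)nz);
  for (int z = 0; z < nz; ++z)
    for (int k = 0; k < nz; ++k) {
      double a = -2.0 * M_PI * (double)((k - c) * (z - c)) / (double)nz;
      W[k + (size_t)nz * z] = cplx(s * std::cos(a), s * std::sin(a));
    }
  return W;
}

// gxw: J x Ns wrapped x-indices; gyo: J x Ns wrapped y-indices pre-multiplied
// by osn; wx, wy: J x Ns separable Kaiser-Bessel weights.
// [[Rcpp::export]]
ComplexMatrix cpp_sos_forward(ComplexVector img, ComplexVector coils,
                              NumericVector apod, IntegerMatrix gxw,
                              IntegerMatrix gyo, NumericMatrix wx,
                              NumericMatrix wy, int nx, int ny, int nz,
                              int nc, int osn) {
  const int Ns = gxw.ncol(), J = gxw.nrow();
  const size_t nxy = (size_t)nx * ny, nvox = nxy * nz, ng = (size_t)osn * osn;
  const int cx = nx / 2, cy = ny / 2;
  const cplx* im = reinterpret_cast<const cplx*>(&img[0]);
  const cplx* co = reinterpret_cast<const cplx*>(&coils[0]);
  const double* ap = &apod[0];
  const int* gxp = &gxw(0, 0);
  const int* gyp = &gyo(0, 0);
  const double* wxp = &wx(0, 0);
  const double* wyp = &wy(0, 0);

  ComplexMatrix out(Ns, nz * nc);
  cplx* op = reinterpret_cast<cplx*>(&out(0, 0));

  fftw_plan pfwd = get_plan2d(osn, FFTW_FORWARD);
  std::vector<cplx> W = zdft_matrix(nz);
  std::vector<cplx> vol(nvox), zline(nz), grid(ng);

  for (int c = 0; c < nc; ++c) {
    const cplx* bc = co + (size_t)c * nvox;
    for (size_t v = 0; v < nvox; ++v) vol[v] = im[v] * bc[v];
    // unitary DFT along z, in place
    for (size_t ixy = 0; ixy < nxy; ++ixy) {
      for (int z = 0; z < nz; ++z) zline[z] = vol[ixy + nxy * z];
      for (int k = 0; k < nz; ++k) {
        cplx acc(0.0, 0.0);
        const cplx* Wk = &W[k];
        for (int z = 0; z < nz; ++z) acc += Wk[(size_t)nz * z] * zline[z];
        vol[ixy + nxy * k] = acc;
      }
    }
    for (int kz = 0; kz < nz; ++kz) {
      std::fill(grid.begin(), grid.end(), cplx(0.0, 0.0));
      const cplx* plane = &vol[nxy * kz];
      for (int iy = 0; iy < ny; ++iy) {
        int gy = iy - cy; if (gy < 0) gy += osn;
        for (int ix = 0; ix < nx; ++ix) {
          int gx = ix - cx; if (gx < 0) gx += osn;
          grid[gx + (size_t)osn * gy] =
              plane[ix + (size_t)nx * iy] * ap[ix + (size_t)nx * iy];
        }
      }
      fft2_exec(pfwd, &grid[0]);
      cplx* ocol = op + (size_t)Ns * (kz + (size_t)nz * c);
      for (int s = 0; s < Ns; ++s) {
        const double* wxs = wxp + (size_t)J * s;
        const double* wys = wyp + (size_t)J * s;
        const int* gxs = gxp + (size_t)J * s;
        const int* gys = gyp + (size_t)J * s;
        double ar = 0.0, ai = 0.0;
        for (int jy = 0; jy < J; ++jy) {
          const cplx* row = &grid[(size_t)gys[jy]];
          double rr = 0.0, ri = 0.0;
          for (int jx = 0; jx < J; ++jx) {
            const cplx& g = row[gxs[jx]];
            rr += wxs[jx] * g.real();
            ri += wxs[jx] * g.imag();
          }
          ar += wys[jy] * rr;
          ai += wys[jy] * ri;
        }
        ocol[s] = cplx(ar, ai);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_sos_adjoint(ComplexMatrix samp, ComplexVector coils,
                              NumericVector apod, IntegerMatrix gxw,
                              IntegerMatrix gyo, NumericMatrix wx,
                              NumericMatrix wy, int nx, int ny, int nz,
                              int nc, int osn) {
  const int Ns = gxw.ncol(), J = gxw.nrow();
  const size_t nxy = (size_t)nx * ny, nvox = nxy * nz, ng = (size_t)osn * osn;
  const int cx = nx / 2, cy = ny / 2;
  const cplx* sp = reinterpret_cast<const cplx*>(&samp(0, 0));
  const cplx* co = reinterpret_cast<const cplx*>(&coils[0]);
  const double* ap = &apod[0];
  const int* gxp = &gxw(0, 0);
  const int* gyp = &gyo(0, 0);
  const double* wxp = &wx(0, 0);
  const double* wyp = &wy(0, 0);

  ComplexVector out(nvox);
  cplx* op = reinterpret_cast<cplx*>(&out[0]);
  for (size_t v = 0; v < nvox; ++v) op[v] = cplx(0.0, 0.0);

  fftw_plan pbwd = get_plan2d(osn, FFTW_BACKWARD);  // adjoint of forward FFT
  std::vector<cplx> W = zdft_matrix(nz);
  std::vector<cplx> vol(nvox), zline(nz), grid(ng);

  for (int c = 0; c < nc; ++c) {
    const cplx* bc = co + (size_t)c * nvox;
    for (int kz = 0; kz < nz; ++kz) {
      std::fill(grid.begin(), grid.end(), cplx(0.0, 0.0));
      const cplx* scol = sp + (size_t)Ns * (kz + (size_t)nz * c);
      for (int s = 0; s < Ns; ++s) {
        const double* wxs = wxp + (size_t)J * s;
        const double* wys = wyp + (size_t)J * s;
        const int* gxs = gxp + (size_t)J * s;
        const int* gys = gyp + (size_t)J * s;
        const cplx v = scol[s];
        for (int jy = 0; jy < J; ++jy) {
          cplx* row = &grid[(size_t)gys[jy]];
          const cplx tv = wys[jy] * v;
          for (int jx = 0; jx < J; ++jx) row[gxs[jx]] += wxs[jx] * tv;
        }
      }
      fft2_exec(pbwd, &grid[0]);
      cplx* plane = &vol[nxy * kz];
      for (int iy = 0; iy < ny; ++iy) {
        int gy = iy - cy; if (gy < 0) gy += osn;
        for (int ix = 0; ix < nx; ++ix) {
          int gx = ix - cx; if (gx < 0) gx += osn;
          plane[ix + (size_t)nx * iy] =
              grid[gx + (size_t)osn * gy] * ap[ix + (size_t)nx * iy];
        }
      }
    }
    // adjoint of the unitary z-DFT: conjugate transpose of W
    for (size_t ixy = 0; ixy < nxy; ++ixy) {
      for (int k = 0; k < nz; ++k) zline[k] = vol[ixy + nxy * k];
      for (int z = 0; z < nz; ++z) {
        cplx acc(0.0, 0.0);
        for (int k = 0; k < nz; ++k)
          acc += std::conj(W[k + (size_t)nz * z]) * zline[k];
        vol[ixy + nxy * z] = acc;
      }
    }
    for (size_t v = 0; v < nvox; ++v) op[v] += std::conj(bc[v]) * vol[v];
  }
  return out;
}

// fused data-dual update: rnew = (r + sigma*((1+theta)*Kx_new - theta*Kx_old)
//                                  - sigma*dk) / (1+sigma)
// returns rnew and accumulates ||rnew - r||^2 into *dn2 (passed back to R).
// [[Rcpp::export]]
List cpp_dual_r_update(ComplexVector r, ComplexVector kx_new,
                       ComplexVector kx_old, ComplexVector dk, double sigma,
                       double theta) {
  const size_t n = r.size();
  const cplx* rp = reinterpret_cast<const cplx*>(&r[0]);
  const cplx* an = reinterpret_cast<const cplx*>(&kx_new[0]);
  const cplx* ao = reinterpret_cast<const cplx*>(&kx_old[0]);
  const cplx* dp = reinterpret_cast<const cplx*>(&dk[0]);
  ComplexVector outv(n);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  const double c1 = 1.0 + theta, c2 = theta, den = 1.0 / (1.0 + sigma);
  double dn2 = 0.0;
  for (size_t i = 0; i < n; ++i) {
    cplx kb = c1 * an[i] - c2 * ao[i];
    cplx rn = (rp[i] + sigma * (kb - dp[i])) * den;
    cplx d = rn - rp[i];
    dn2 += d.real() * d.real() + d.imag() * d.imag();
    op[i] = rn;
  }
  return List::create(Named("r") = outv, Named("dn2") = dn2);
}

// ||a - b||^2 for complex vectors without R-level temporaries
// [[Rcpp::export]]
double cpp_cdiff_norm2(ComplexVector a, ComplexVector b) {
  const size_t n = a.size();
  const cplx* ap = reinterpret_cast<const cplx*>(&a[0]);
  const cplx* bp = reinterpret_cast<const cplx*>(&b[0]);
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) {
    cplx d = ap[i] - bp[i];
    s += d.real() * d.real() + d.imag() * d.imag();
  }
  return s;
}
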