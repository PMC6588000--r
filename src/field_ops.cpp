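// Finite-difference field operators and pointwise dual projections.
//
// Conventions (see R/regularization.R): forward differences with replicate
// (Neumann) boundary for the gradient; backward differences with replicated
// left boundary (annihilating constants) for the symmetrized derivative;
// each operator is paired with its exact transpose.  Tensor fields store
// (xx, yy, zz, xy, xz, yz) with off-diagonal weight 2 in inner products.
// reg2d = true zeroes every z-derivative (2D-regularization mode).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// forward difference along dimension d (0,1,2) of one channel
static void fdiff_ch(const cplx* a, cplx* out, int n1, int n2, int n3,
                     int d) {
  const size_t s[3] = {1, (size_t)n1, (size_t)n1 * n2};
  const int n[3] = {n1, n2, n3};
  const size_t sd = s[d];
  const int nd = n[d];
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        int id = (d == 0) ? i1 : (d == 1) ? i2 : i3;
        out[idx] = (id < nd - 1) ? a[idx + sd] - a[idx] : cplx(0.0, 0.0);
      }
}

// adjoint of fdiff_ch: (grad^T v)(j) = v(j-1) 1[j>1] - v(j) 1[j<n]
static void fdiff_adj_ch(const cplx* v, cplx* out, int n1, int n2, int n3,
                         int d, bool accumulate) {
  const size_t s[3] = {1, (size_t)n1, (size_t)n1 * n2};
  const int n[3] = {n1, n2, n3};
  const size_t sd = s[d];
  const int nd = n[d];
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        int id = (d == 0) ? i1 : (d == 1) ? i2 : i3;
        cplx r(0.0, 0.0);
        if (id > 0) r += v[idx - sd];
        if (id < nd - 1) r -= v[idx];
        if (accumulate) out[idx] += r; else out[idx] = r;
      }
}

// backward difference with replicated left boundary: (D v)(j) =
// v(j) - v(j-1) for j > 1, 0 at j = 1; annihilates constants exactly
static void bdiff_ch(const cplx* a, cplx* out, int n1, int n2, int n3,
                     int d, double w, bool accumulate) {
  const size_t s[3] = {1, (size_t)n1, (size_t)n1 * n2};
  const size_t sd = s[d];
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        int id = (d == 0) ? i1 : (d == 1) ? i2 : i3;
        cplx r(0.0, 0.0);
        if (id > 0) r = a[idx] - a[idx - sd];
        if (accumulate) out[idx] += w * r; else out[idx] = w * r;
      }
}

// exact transpose of bdiff_ch: (D^T w)(j) = w(j) 1[j>1] - w(j+1) 1[j<n]
static void bdiff_adj_ch(const cplx* v, cplx* out, int n1, int n2, int n3,
                         int d, double w, bool accumulate) {
  const size_t s[3] = {1, (size_t)n1, (size_t)n1 * n2};
  const int n[3] = {n1, n2, n3};
  const size_t sd = s[d];
  const int nd = n[d];
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        int id = (d == 0) ? i1 : (d == 1) ? i2 : i3;
        cplx r(0.0, 0.0);
        if (id > 0) r += v[idx];
        if (id < nd - 1) r -= v[idx + sd];
        if (accumulate) out[idx] += w * r; else out[idx] = w * r;
      }
}

// [[Rcpp::export]]
ComplexVector cpp_grad3(ComplexVector u, int n1, int n2, int n3, int nu,
                        bool reg2d) {
  const size_t vox = (size_t)n1 * n2 * n3;
  ComplexVector outv(vox * 3 * nu);
  const cplx* up = reinterpret_cast<const cplx*>(&u[0]);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  for (int i = 0; i < nu; ++i) {
    const cplx* ui = up + vox * i;
    for (int d = 0; d < 3; ++d) {
      cplx* od = op + vox * (d + 3 * (size_t)i);
      if (reg2d && d == 2)
        std::fill(od, od + vox, cplx(0.0, 0.0));
      else
        fdiff_ch(ui, od, n1, n2, n3, d);
    }
  }
  return outv;
}

// [[Rcpp::export]]
ComplexVector cpp_grad3_adj(ComplexVector v, int n1, int n2, int n3, int nu,
                            bool reg2d) {
  const size_t vox = (size_t)n1 * n2 * n3;
  ComplexVector outv(vox * nu);
  const cplx* vp = reinterpret_cast<const cplx*>(&v[0]);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  std::fill(op, op + vox * nu, cplx(0.0, 0.0));
  int nd = reg2d ? 2 : 3;
  for (int i = 0; i < nu; ++i)
    for (int d = 0; d < nd; ++d)
      fdiff_adj_ch(vp + vox * (d + 3 * (size_t)i), op + vox * i,
                   n1, n2, n3, d, true);
  return outv;
}

// [[Rcpp::export]]
ComplexVector cpp_symgrad(ComplexVector v, int n1, int n2, int n3, int nu,
                          bool reg2d) {
  const size_t vox = (size_t)n1 * n2 * n3;
  ComplexVector outv(vox * 6 * nu);
  const cplx* vp = reinterpret_cast<const cplx*>(&v[0]);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  std::fill(op, op + vox * 6 * nu, cplx(0.0, 0.0));
  for (int i = 0; i < nu; ++i) {
    const cplx* v1 = vp + vox * (0 + 3 * (size_t)i);
    const cplx* v2 = vp + vox * (1 + 3 * (size_t)i);
    const cplx* v3 = vp + vox * (2 + 3 * (size_t)i);
    cplx* o = op + vox * 6 * (size_t)i;
    bdiff_ch(v1, o + 0 * vox, n1, n2, n3, 0, 1.0, false);   // xx
    bdiff_ch(v2, o + 1 * vox, n1, n2, n3, 1, 1.0, false);   // yy
    if (!reg2d) bdiff_ch(v3, o + 2 * vox, n1, n2, n3, 2, 1.0, false); // zz
    bdiff_ch(v1, o + 3 * vox, n1, n2, n3, 1, 0.5, false);   // xy
    bdiff_ch(v2, o + 3 * vox, n1, n2, n3, 0, 0.5, true);
    if (!reg2d) bdiff_ch(v1, o + 4 * vox, n1, n2, n3, 2, 0.5, false); // xz
    bdiff_ch(v3, o + 4 * vox, n1, n2, n3, 0, 0.5, !reg2d);
    if (!reg2d) bdiff_ch(v2, o + 5 * vox, n1, n2, n3, 2, 0.5, false); // yz
    bdiff_ch(v3, o + 5 * vox, n1, n2, n3, 1, 0.5, !reg2d);
  }
  return outv;
}

// [[Rcpp::export]]
ComplexVector cpp_symgrad_adj(ComplexVector xi, int n1, int n2, int n3,
                              int nu, bool reg2d) {
  const size_t vox = (size_t)n1 * n2 * n3;
  ComplexVector outv(vox * 3 * nu);
  const cplx* xp = reinterpret_cast<const cplx*>(&xi[0]);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  for (int i = 0; i < nu; ++i) {
    const cplx* x = xp + vox * 6 * (size_t)i;
    cplx* w1 = op + vox * (0 + 3 * (size_t)i);
    cplx* w2 = op + vox * (1 + 3 * (size_t)i);
    cplx* w3 = op + vox * (2 + 3 * (size_t)i);
    bdiff_adj_ch(x + 0 * vox, w1, n1, n2, n3, 0, 1.0, false);
    bdiff_adj_ch(x + 3 * vox, w1, n1, n2, n3, 1, 1.0, true);
    if (!reg2d) bdiff_adj_ch(x + 4 * vox, w1, n1, n2, n3, 2, 1.0, true);
    bdiff_adj_ch(x + 3 * vox, w2, n1, n2, n3, 0, 1.0, false);
    bdiff_adj_ch(x + 1 * vox, w2, n1, n2, n3, 1, 1.0, true);
    if (!reg2d) bdiff_adj_ch(x + 5 * vox, w2, n1, n2, n3, 2, 1.0, true);
    bdiff_adj_ch(x + 4 * vox, w3, n1, n2, n3, 0, 1.0, false);
    bdiff_adj_ch(x + 5 * vox, w3, n1, n2, n3, 1, 1.0, true);
    if (!reg2d) bdiff_adj_ch(x + 2 * vox, w3, n1, n2, n3, 2, 1.0, true);
  }
  return outv;
}

// pointwise pooled squared magnitudes: out(vox [, iu]) = sum_c w_c |z|^2
// (summed over unknowns too when joint)
// [[Rcpp::export]]
NumericMatrix cpp_pooled_sq(ComplexVector z, int vox, int ncomp, int nu,
                            NumericVector w, bool joint) {
  const cplx* zp = reinterpret_cast<const cplx*>(&z[0]);
  NumericMatrix out(vox, joint ? 1 : nu);
  double* op = &out(0, 0);
  for (int i = 0; i < nu; ++i) {
    double* oc = joint ? op : op + (size_t)vox * i;
    for (int c = 0; c < ncomp; ++c) {
      const double wc = w[c];
      const cplx* zc = zp + (size_t)vox * (c + (size_t)ncomp * i);
      for (int k = 0; k < vox; ++k)
        oc[k] += wc * (zc[k].real() * zc[k].real() +
                       zc[k].imag() * zc[k].imag());
    }
  }
  return out;
}

// z <- z / max(1, sqrt(pooled)/radius), pooling per the coupling
// [[Rcpp::export]]
ComplexVector cpp_project_ball(ComplexVector z, int vox, int ncomp, int nu,
                               NumericVector w, double radius, bool joint) {
  const cplx* zp = reinterpret_cast<const cplx*>(&z[0]);
  ComplexVector outv(z.size());
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  std::vector<double> pool((size_t)vox * (joint ? 1 : nu), 0.0);
  for (int i = 0; i < nu; ++i) {
    double* oc = joint ? &pool[0] : &pool[(size_t)vox * i];
    for (int c = 0; c < ncomp; ++c) {
      const double wc = w[c];
      const cplx* zc = zp + (size_t)vox * (c + (size_t)ncomp * i);
      for (int k = 0; k < vox; ++k)
        oc[k] += wc * (zc[k].real() * zc[k].real() +
                       zc[k].imag() * zc[k].imag());
    }
  }
  for (int i = 0; i < nu; ++i) {
    const double* oc = joint ? &pool[0] : &pool[(size_t)vox * i];
    for (int c = 0; c < ncomp; ++c) {
      const cplx* zc = zp + (size_t)vox * (c + (size_t)ncomp * i);
      cplx* out_c = op + (size_t)vox * (c + (size_t)ncomp * i);
      for (int k = 0; k < vox; ++k) {
        double nrm = std::sqrt(oc[k]);
        double f = (nrm > radius) ? radius / nrm : 1.0;
        out_c[k] = f * zc[k];
      }
    }
  }
  return outv;
}

// a + s * ((1+t) * b - t * c) for complex vectors (dual z updates)
// [[Rcpp::export]]
ComplexVector cpp_dual_z_update(ComplexVector a, ComplexVector b,
                                ComplexVector c, double s, double t) {
  const size_t n = a.size();
  const cplx* ap = reinterpret_cast<const cplx*>(&a[0]);
  const cplx* bp = reinterpret_cast<const cplx*>(&b[0]);
  const cplx* cp = reinterpret_cast<const cplx*>(&c[0]);
  ComplexVector outv(n);
  cplx* op = reinterpret_cast<cplx*>(&outv[0]);
  const double c1 = s * (1.0 + t), c2 = s * t;
  for (size_t i = 0; i < n; ++i) op[i] = ap[i] + c1 * bp[i] - c2 * cp[i];
  return outv;
}
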