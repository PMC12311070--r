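#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3-D array at 0-based voxel coordinates (x,y,z).
// Returns 0 and sets in_field = false when the point falls outside the grid.
static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, bool &in_field) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
    in_field = false;
    return 0.0;
  }
  in_field = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nn_sample(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int xi = (int)std::floor(x + 0.5), yi = (int)std::floor(y + 0.5),
      zi = (int)std::floor(z + 0.5);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
    return 0.0;
  return v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
}

// Mean of trilinear samples of `vol` at A %*% (i,j,k,1) for each row (i,j,k)
// of `idx` (0-based voxel indices of the ROI grid mapped into the volume's
// 0-based voxel space by the 3x4 matrix A). Out-of-field samples contribute 0
// but still count in the denominator.
// [[Rcpp::export(name = ".masked_mean_cpp")]]
double masked_mean_cpp(NumericVector vol, IntegerVector dim,
                       NumericMatrix idx, NumericMatrix A) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  const R_xlen_t n = idx.nrow();
  if (n == 0) stop("empty ROI");
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  double acc = 0.0;
  bool in;
  for (R_xlen_t r = 0; r < n; ++r) {
    double i = idx(r, 0), j = idx(r, 1), k = idx(r, 2);
    double x = a00 * i + a01 * j + a02 * k + a03;
    double y = a10 * i + a11 * j + a12 * k + a13;
    double z = a20 * i + a21 * j + a22 * k + a23;
    acc += tri_sample(v, nx, ny, nz, x, y, z, in);
  }
  return acc / (double)n;
}

// Resample `vol` onto its own grid: out(v) = vol(A %*% (v,1)), A in 0-based
// voxel coordinates. mode 0 = trilinear, 1 = nearest. Out-of-field -> 0.
// [[Rcpp::export(name = ".resample_cpp")]]
NumericVector resample_cpp(NumericVector vol, IntegerVector dim,
                           NumericMatrix A, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  bool in;
  R_xlen_t off = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++off) {
        double x = a00 * i + a01 * j + a02 * k + a03;
        double y = a10 * i + a11 * j + a12 * k + a13;
        double z = a20 * i + a21 * j + a22 * k + a23;
        o[off] = (mode == 0) ? tri_sample(v, nx, ny, nz, x, y, z, in)
                             : nn_sample(v, nx, ny, nz, x, y, z);
      }
  return out;
}

// Slice-wise discrete Radon transform. For each axial slice (third index)
// and angle, integrates along rays with unit (one pixel) step using bilinear
// interpolation. Output array: n_angles x n_bins x n_slices. Detector bins
// and integration steps are centered on the slice center; lengths in pixels.
// [[Rcpp::export(name = ".radon_cpp")]]
NumericVector radon_cpp(NumericVector vol, IntegerVector dim,
                        NumericVector angles_rad, int nbins) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int na = angles_rad.size();
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)na * nbins * nz);
  double *o = REAL(out);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double half = (nbins - 1) / 2.0;
  for (int z = 0; z < nz; ++z) {
    const double *slice = v + (R_xlen_t)nx * ny * z;
    for (int a = 0; a < na; ++a) {
      const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
      for (int b = 0; b < nbins; ++b) {
        const double det = b - half;
        double acc = 0.0;
        for (int t = 0; t < nbins; ++t) {
          const double tt = t - half;
          const double x = cx + det * c - tt * s;
          const double y = cy + det * s + tt * c;
          if (x >= 0.0 && y >= 0.0 && x <= nx - 1.0 && y <= ny - 1.0) {
            int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
            if (x0 > nx - 2) x0 = nx - 2;
            if (y0 > ny - 2) y0 = ny - 2;
            const double fx = x - x0, fy = y - y0;
            const double *p = slice + x0 + (R_xlen_t)nx * y0;
            acc += (p[0] * (1 - fx) + p[1] * fx) * (1 - fy) +
                   (p[nx] * (1 - fx) + p[nx + 1] * fx) * fy;
          }
        }
        o[a + (R_xlen_t)na * (b + (R_xlen_t)nbins * z)] = acc;
      }
    }
  }
  return out;
}

// Slice-wise backprojection of filtered sinograms (n_angles x n_bins x
// n_slices) onto nx x ny x n_slices; linear interpolation across detector
// bins, scaled by pi / n_angles.
// [[Rcpp::export(name = ".backproject_cpp")]]
NumericVector backproject_cpp(NumericVector sino, IntegerVector sdim,
                              int nx, int ny) {
  const int na = sdim[0], nbins = sdim[1], nz = sdim[2];
  const double *sn = REAL(sino);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double half = (nbins - 1) / 2.0;
  std::vector<double> cs(na), sv(na);
  for (int a = 0; a < na; ++a) {
    cs[a] = std::cos(M_PI * a / na);
    sv[a] = std::sin(M_PI * a / na);
  }
  // angles are assumed uniform over [0, pi); recompute from count to avoid
  // passing them twice -- caller guarantees this layout.
  const double scale = M_PI / na;
  for (int z = 0; z < nz; ++z) {
    const double *szl = sn + (R_xlen_t)na * nbins * z;
    double *ozl = o + (R_xlen_t)nx * ny * z;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const double dx = i - cx, dy = j - cy;
        for (int a = 0; a < na; ++a) {
          const double sc = dx * cs[a] + dy * sv[a] + half;
          if (sc >= 0.0 && sc <= nbins - 1.0) {
            int b0 = (int)std::floor(sc);
            if (b0 > nbins - 2) b0 = nbins - 2;
            const double f = sc - b0;
            const double *col = szl + a;
            acc += col[(R_xlen_t)na * b0] * (1 - f) +
                   col[(R_xlen_t)na * (b0 + 1)] * f;
          }
        }
        ozl[i + (R_xlen_t)nx * j] = acc * scale;
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fast objective evaluators used inside the registration loops. Volumes are
// held as single-precision copies (half the memory traffic of the double
// arrays; the transform algebra stays in double precision). Construction
// happens once per registration; evaluation takes the six rigid parameters.
// ---------------------------------------------------------------------------

struct FloatVol {
  std::vector<float> v;
  int nx, ny, nz;
};

static inline void fill_floatvol(FloatVol &fv, const NumericVector &vol,
                                 const IntegerVector &dim) {
  fv.nx = dim[0]; fv.ny = dim[1]; fv.nz = dim[2];
  const double *p = REAL(vol);
  fv.v.resize(vol.size());
  for (R_xlen_t i = 0; i < vol.size(); ++i) fv.v[i] = (float)p[i];
}

static inline float tri_sample_f(const FloatVol &fv, double x, double y,
                                 double z) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= fv.nx - 1.0 && y <= fv.ny - 1.0 && z <= fv.nz - 1.0))
    return 0.0f;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  if (x0 > fv.nx - 2) x0 = fv.nx - 2;
  if (y0 > fv.ny - 2) y0 = fv.ny - 2;
  if (z0 > fv.nz - 2) z0 = fv.nz - 2;
  float fx = (float)(x - x0), fy = (float)(y - y0), fz = (float)(z - z0);
  const R_xlen_t sy = fv.nx, sz = (R_xlen_t)fv.nx * fv.ny;
  const float *p = fv.v.data() + x0 + y0 * sy + z0 * sz;
  float c00 = p[0] + (p[1] - p[0]) * fx;
  float c10 = p[sy] + (p[sy + 1] - p[sy]) * fx;
  float c01 = p[sz] + (p[sz + 1] - p[sz]) * fx;
  float c11 = p[sz + sy] + (p[sz + sy + 1] - p[sz + sy]) * fx;
  float c0 = c00 + (c10 - c00) * fy;
  float c1 = c01 + (c11 - c01) * fy;
  return c0 + (c1 - c0) * fz;
}

// 4x4 double matrices stored row-major in double[16]
static void mat44_mul(const double *a, const double *b, double *c) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0;
      for (int k = 0; k < 4; ++k) s += a[i * 4 + k] * b[k * 4 + j];
      c[i * 4 + j] = s;
    }
}

// rigid transform T(t) T(c) Rz Ry Rx T(-c), params = tx,ty,tz,rx,ry,rz (deg)
static void rigid_mat(const double *p, const double *c, double *m) {
  const double d2r = M_PI / 180.0;
  double ax = p[3] * d2r, ay = p[4] * d2r, az = p[5] * d2r;
  double cx = std::cos(ax), sx = std::sin(ax);
  double cy = std::cos(ay), sy = std::sin(ay);
  double cz = std::cos(az), sz = std::sin(az);
  double R[9] = {
    cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
    sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
    -sy,     cy * sx,                cy * cx};
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) m[i * 4 + j] = R[i * 3 + j];
    m[i * 4 + 3] = p[i] + c[i] -
      (R[i * 3] * c[0] + R[i * 3 + 1] * c[1] + R[i * 3 + 2] * c[2]);
  }
  m[12] = m[13] = m[14] = 0.0; m[15] = 1.0;
}

// inverse of a rigid 4x4 (row-major)
static void rigid_inv(const double *m, double *inv) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) inv[i * 4 + j] = m[j * 4 + i];
  for (int i = 0; i < 3; ++i)
    inv[i * 4 + 3] = -(inv[i * 4] * m[3] + inv[i * 4 + 1] * m[7] +
                       inv[i * 4 + 2] * m[11]);
  inv[12] = inv[13] = inv[14] = 0.0; inv[15] = 1.0;
}

static void copy44(const NumericMatrix &src, double *dst) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) dst[i * 4 + j] = src(i, j);
}

struct TcbcObjective {
  FloatVol pet;
  std::vector<float> ix, iy, iz;   // ROI voxel indices (0-based)
  double PA[16], RA[16], center[3], sgn;
};

// [[Rcpp::export(name = ".tcbc_obj_new")]]
SEXP tcbc_obj_new(NumericVector vol, IntegerVector dim, NumericMatrix idx,
                  NumericMatrix pet_inv_affine, NumericMatrix roi_affine,
                  NumericVector center, double sgn) {
  XPtr<TcbcObjective> p(new TcbcObjective(), true);
  fill_floatvol(p->pet, vol, dim);
  R_xlen_t n = idx.nrow();
  p->ix.resize(n); p->iy.resize(n); p->iz.resize(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    p->ix[r] = (float)idx(r, 0);
    p->iy[r] = (float)idx(r, 1);
    p->iz[r] = (float)idx(r, 2);
  }
  copy44(pet_inv_affine, p->PA);
  copy44(roi_affine, p->RA);
  for (int i = 0; i < 3; ++i) p->center[i] = center[i];
  p->sgn = sgn;
  return p;
}

// [[Rcpp::export(name = ".tcbc_obj_eval")]]
double tcbc_obj_eval(SEXP ptr, NumericVector par) {
  XPtr<TcbcObjective> p(ptr);
  double M[16], T1[16], A[16];
  rigid_mat(REAL(par), p->center, M);
  mat44_mul(p->PA, M, T1);
  mat44_mul(T1, p->RA, A);
  const double a00 = A[0], a01 = A[1], a02 = A[2], a03 = A[3];
  const double a10 = A[4], a11 = A[5], a12 = A[6], a13 = A[7];
  const double a20 = A[8], a21 = A[9], a22 = A[10], a23 = A[11];
  const R_xlen_t n = p->ix.size();
  double acc = 0.0;
  for (R_xlen_t r = 0; r < n; ++r) {
    double i = p->ix[r], j = p->iy[r], k = p->iz[r];
    acc += tri_sample_f(p->pet,
                        a00 * i + a01 * j + a02 * k + a03,
                        a10 * i + a11 * j + a12 * k + a13,
                        a20 * i + a21 * j + a22 * k + a23);
  }
  return p->sgn * acc / (double)n;
}

struct NmiObjective {
  FloatVol mov;
  std::vector<float> px, py, pz;
  std::vector<unsigned char> fbin;
  double MA[16], FA[16], center[3], lo, hi;
  int nbins;
  std::vector<double> joint;
};

// [[Rcpp::export(name = ".nmi_obj_new")]]
SEXP nmi_obj_new(NumericVector mov, IntegerVector mdim, NumericMatrix pts,
                 IntegerVector fixed_bin, NumericMatrix mov_inv_affine,
                 NumericMatrix fixed_affine, NumericVector center,
                 double lo, double hi, int nbins) {
  XPtr<NmiObjective> p(new NmiObjective(), true);
  fill_floatvol(p->mov, mov, mdim);
  R_xlen_t n = pts.nrow();
  p->px.resize(n); p->py.resize(n); p->pz.resize(n); p->fbin.resize(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    p->px[r] = (float)pts(r, 0);
    p->py[r] = (float)pts(r, 1);
    p->pz[r] = (float)pts(r, 2);
    p->fbin[r] = (unsigned char)fixed_bin[r];
  }
  copy44(mov_inv_affine, p->MA);
  copy44(fixed_affine, p->FA);
  for (int i = 0; i < 3; ++i) p->center[i] = center[i];
  p->lo = lo; p->hi = hi; p->nbins = nbins;
  p->joint.resize((size_t)nbins * nbins);
  return p;
}

// [[Rcpp::export(name = ".nmi_obj_eval")]]
double nmi_obj_eval(SEXP ptr, NumericVector par) {
  XPtr<NmiObjective> p(ptr);
  double M[16], Minv[16], T1[16], A[16];
  rigid_mat(REAL(par), p->center, M);
  rigid_inv(M, Minv);
  mat44_mul(p->MA, Minv, T1);
  mat44_mul(T1, p->FA, A);
  const double a00 = A[0], a01 = A[1], a02 = A[2], a03 = A[3];
  const double a10 = A[4], a11 = A[5], a12 = A[6], a13 = A[7];
  const double a20 = A[8], a21 = A[9], a22 = A[10], a23 = A[11];
  const int nb = p->nbins;
  std::fill(p->joint.begin(), p->joint.end(), 0.0);
  const double w = (p->hi > p->lo) ? nb / (p->hi - p->lo) : 0.0;
  const R_xlen_t n = p->px.size();
  double total = 0.0;
  for (R_xlen_t r = 0; r < n; ++r) {
    double i = p->px[r], j = p->py[r], k = p->pz[r];
    double x = a00 * i + a01 * j + a02 * k + a03;
    double y = a10 * i + a11 * j + a12 * k + a13;
    double z = a20 * i + a21 * j + a22 * k + a23;
    if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 && x <= p->mov.nx - 1.0 &&
          y <= p->mov.ny - 1.0 && z <= p->mov.nz - 1.0))
      continue;
    float val = tri_sample_f(p->mov, x, y, z);
    int b = (int)std::floor((val - p->lo) * w);
    if (b < 0) b = 0;
    if (b >= nb) b = nb - 1;
    p->joint[(size_t)p->fbin[r] * nb + b] += 1.0;
    total += 1.0;
  }
  if (total < 2.0) return NA_REAL;
  double ha = 0.0, hb = 0.0, hab = 0.0;
  std::vector<double> pa(nb, 0.0), pb(nb, 0.0);
  for (int a = 0; a < nb; ++a)
    for (int b = 0; b < nb; ++b) {
      double q = p->joint[(size_t)a * nb + b];
      pa[a] += q; pb[b] += q;
    }
  for (int a = 0; a < nb; ++a) {
    if (pa[a] > 0) { double q = pa[a] / total; ha -= q * std::log(q); }
    if (pb[a] > 0) { double q = pb[a] / total; hb -= q * std::log(q); }
    for (int b = 0; b < nb; ++b) {
      double q = p->joint[(size_t)a * nb + b];
      if (q > 0) { q /= total; hab -= q * std::log(q); }
    }
  }
  if (hab <= 0.0) return NA_REAL;
  return (ha + hb) / hab;
}
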