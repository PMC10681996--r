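#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3-D arrays arrive as flat vectors in R's column-major layout:
// index = i + nx*(j + ny*k), zero-based here.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---- separable Gaussian convolution, reflect padding -----------------------

static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (double &k : kern) k /= s;

  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len), out(len);

  // iterate over all lines along `axis`
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int u = 0; u < n[a1]; ++u) {
    for (int w = 0; w < n[a2]; ++w) {
      int c[3];
      c[a1] = u; c[a2] = w;
      for (int t = 0; t < len; ++t) {
        c[axis] = t;
        line[t] = v[idx3(c[0], c[1], c[2], nx, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int d = -radius; d <= radius; ++d) {
          int p = t + d;
          // reflect at boundaries
          while (p < 0 || p >= len) {
            if (p < 0) p = -p - 1;
            if (p >= len) p = 2 * len - p - 1;
          }
          acc += kern[d + radius] * line[p];
        }
        out[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        c[axis] = t;
        v[idx3(c[0], c[1], c[2], nx, ny)] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim,
                             NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int ax = 0; ax < 3; ++ax) blur_axis(v, nx, ny, nz, ax, sigma_vox[ax]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double step) {
  // lower envelope of parabolas; sample positions t*step
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (!R_finite(f[q]) && f[q] > 0) continue; // +inf handled by formula anyway
    double qs = q * step;
    double s;
    while (true) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2 * qs - 2 * vs);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  // squared Euclidean distance (mm^2) of every voxel to the nearest
  // feature voxel, honoring anisotropic spacing
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t)n);
  for (long long t = 0; t < n; ++t) d[t] = feature[t] ? 0.0 : INF;

  int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    int len = dims[ax];
    int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
    std::vector<double> f(len), out(len);
    for (int u = 0; u < dims[a1]; ++u) {
      for (int w = 0; w < dims[a2]; ++w) {
        int c[3];
        c[a1] = u; c[a2] = w;
        bool any_finite = false;
        for (int t = 0; t < len; ++t) {
          c[ax] = t;
          f[t] = d[idx3(c[0], c[1], c[2], nx, ny)];
          if (R_finite(f[t])) any_finite = true;
        }
        if (!any_finite) continue;
        // replace inf with a large finite sentinel to keep envelope stable
        double big = 1e30;
        for (int t = 0; t < len; ++t) if (!R_finite(f[t])) f[t] = big;
        dt1d(f, out, len, spacing[ax]);
        for (int t = 0; t < len; ++t) {
          c[ax] = t;
          d[idx3(c[0], c[1], c[2], nx, ny)] = out[t];
        }
      }
    }
  }
  NumericVector res(d.begin(), d.end());
  res.attr("dim") = dim;
  return res;
}

// ---- 6-connected components ------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_flood6(LogicalVector fg, IntegerVector dim, int seed0) {
  // component of `fg` containing zero-based linear index seed0
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  LogicalVector out(n, false);
  if (seed0 < 0 || seed0 >= n || !fg[seed0]) { out.attr("dim") = dim; return out; }
  std::vector<char> seen((size_t)n, 0);
  std::queue<int> q;
  q.push(seed0);
  seen[seed0] = 1;
  while (!q.empty()) {
    int t = q.front(); q.pop();
    out[t] = true;
    int i = t % nx, r = t / nx, j = r % ny, k = r / ny;
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int tt = idx3(ii, jj, kk, nx, ny);
      if (fg[tt] && !seen[tt]) { seen[tt] = 1; q.push(tt); }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector fg, IntegerVector dim) {
  // all 6-connected components, labels 1..K in scan order; 0 = background
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  for (long long s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] != 0) continue;
    ++next;
    std::queue<int> q;
    q.push((int)s);
    lab[s] = next;
    while (!q.empty()) {
      int t = q.front(); q.pop();
      int i = t % nx, r = t / nx, j = r % ny, k = r / ny;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int tt = idx3(ii, jj, kk, nx, ny);
        if (fg[tt] && lab[tt] == 0) { lab[tt] = next; q.push(tt); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- marching tetrahedra isosurface area -----------------------------------

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1],
                 u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

static inline void interp(const double p1[3], const double p2[3], double f1,
                          double f2, double level, double out[3]) {
  double t = (level - f1) / (f2 - f1);
  for (int d = 0; d < 3; ++d) out[d] = p1[d] + t * (p2[d] - p1[d]);
}

// [[Rcpp::export]]
double cpp_marchtet_area(NumericVector field, IntegerVector dim,
                         NumericVector spacing, double level) {
  // iso-surface area at `level` by marching tetrahedra: each grid cell is
  // split into 6 tetrahedra sharing the main diagonal, so adjacent cells
  // tile consistently and the surface is watertight
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // cube corner offsets (unit cell)
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                        {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tetrahedra decomposition along diagonal corner0 - corner6
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                          {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  double P[8][3], F[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          F[c] = field[idx3(ii, jj, kk, nx, ny)];
          P[c][0] = ii * spacing[0];
          P[c][1] = jj * spacing[1];
          P[c][2] = kk * spacing[2];
          if (F[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int *v = tets[t];
          int hi[4], lo[4], nhi = 0, nlo = 0;
          for (int m = 0; m < 4; ++m) {
            if (F[v[m]] > level) hi[nhi++] = v[m]; else lo[nlo++] = v[m];
          }
          if (nhi == 0 || nhi == 4) continue;
          double q[4][3];
          if (nhi == 1 || nhi == 3) {
            int apex = (nhi == 1) ? hi[0] : lo[0];
            int *base = (nhi == 1) ? lo : hi;
            for (int m = 0; m < 3; ++m)
              interp(P[apex], P[base[m]], F[apex], F[base[m]], level, q[m]);
            area += tri_area(q[0], q[1], q[2]);
          } else { // 2-2: quad across edges hi0-lo0, hi0-lo1, hi1-lo1, hi1-lo0
            interp(P[hi[0]], P[lo[0]], F[hi[0]], F[lo[0]], level, q[0]);
            interp(P[hi[0]], P[lo[1]], F[hi[0]], F[lo[1]], level, q[1]);
            interp(P[hi[1]], P[lo[1]], F[hi[1]], F[lo[1]], level, q[2]);
            interp(P[hi[1]], P[lo[0]], F[hi[1]], F[lo[0]], level, q[3]);
            area += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
    }
  }
  return area;
}
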