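// Low-level 3D image kernels for vesselmorph.
//
// Conventions shared with the R side:
//  - volumes are R arrays with dim = c(nz, ny, nx), i.e. axis order (z, y, x)
//    and z varying fastest in memory;
//  - linear index of (z, y, x) is z + nz*(y + ny*x), 0-based here;
//  - foreground connectivity is 26, background/cavity connectivity is 6;
//  - out-of-volume voxels are treated as *foreground continuation* by the
//    topology/metric kernels (thinning, EDT, local thickness): structures
//    clipped by the field of view are assumed to continue past it.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <queue>

using namespace Rcpp;

namespace {

struct Dim3 {
  int nz, ny, nx;
  R_xlen_t n;
};

Dim3 get_dim(SEXP x) {
  IntegerVector d = Rf_getAttrib(x, R_DimSymbol);
  if (d.size() != 3) stop("expected a 3D array");
  Dim3 dd;
  dd.nz = d[0]; dd.ny = d[1]; dd.nx = d[2];
  dd.n = (R_xlen_t)dd.nz * dd.ny * dd.nx;
  return dd;
}

inline R_xlen_t lin(const Dim3& d, int z, int y, int x) {
  return (R_xlen_t)z + (R_xlen_t)d.nz * ((R_xlen_t)y + (R_xlen_t)d.ny * x);
}

// symmetric (half-sample) reflection: ... c b a | a b c ... | c b a
inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

const int OFF26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},{-1,1,0},{-1,1,1},
  {0,-1,-1},{0,-1,0},{0,-1,1},{0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}
};
const int OFF6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
};

} // namespace

// ---------------------------------------------------------------------------
// 3D median filter
// ---------------------------------------------------------------------------

// Exact running-histogram median for integer-valued volumes (values in
// [0, nlev), nlev <= 65536).  Window slides along z; per step the histogram
// is updated with two k x k planes and the median tracked incrementally
// (Huang's method).
// [[Rcpp::export]]
NumericVector cpp_median3d_int(NumericVector vol, int k, int nlev) {
  Dim3 d = get_dim(vol);
  const int p = k / 2;
  // padded integer copy (symmetric reflection)
  const int pz = d.nz + 2 * p, py = d.ny + 2 * p, px = d.nx + 2 * p;
  std::vector<int> pad((size_t)pz * py * px);
  for (int x = 0; x < px; ++x) {
    int xs = reflect(x - p, d.nx);
    for (int y = 0; y < py; ++y) {
      int ys = reflect(y - p, d.ny);
      const double* col = &vol[lin(d, 0, ys, xs)];
      int* pcol = &pad[(size_t)0 + (size_t)pz * ((size_t)y + (size_t)py * x)];
      for (int z = 0; z < pz; ++z) pcol[z] = (int)col[reflect(z - p, d.nz)];
    }
  }
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  std::vector<int> hist(nlev, 0);
  const int mid = (k * k * k - 1) / 2;  // 0-based sorted position of median
  // slide along x so the entering/leaving k x k planes are contiguous in z
  for (int y = 0; y < d.ny; ++y) {
    for (int z = 0; z < d.nz; ++z) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int xx = 0; xx < k; ++xx)
        for (int yy = y; yy < y + k; ++yy) {
          const int* pcol = &pad[(size_t)z + (size_t)pz * ((size_t)yy + (size_t)py * xx)];
          for (int zz = 0; zz < k; ++zz) hist[pcol[zz]]++;
        }
      int med = 0, less = 0;  // less = #elements < med
      while (less + hist[med] <= mid) { less += hist[med]; ++med; }
      for (int x = 0; x < d.nx; ++x) {
        if (x > 0) {
          const int xrm = x - 1, xad = x - 1 + k;
          for (int yy = y; yy < y + k; ++yy) {
            const int* prm = &pad[(size_t)z + (size_t)pz * ((size_t)yy + (size_t)py * xrm)];
            const int* pad2 = &pad[(size_t)z + (size_t)pz * ((size_t)yy + (size_t)py * xad)];
            for (int zz = 0; zz < k; ++zz) {
              int v = prm[zz];
              hist[v]--; if (v < med) --less;
              v = pad2[zz];
              hist[v]++; if (v < med) ++less;
            }
          }
          while (less > mid) { --med; less -= hist[med]; }
          while (less + hist[med] <= mid) { less += hist[med]; ++med; }
        }
        out[lin(d, z, y, x)] = med;
      }
    }
  }
  return out;
}

// Brute-force median for arbitrary numeric volumes (used for float data and
// as the general fallback; quadratic-ish, intended for moderate sizes).
// [[Rcpp::export]]
NumericVector cpp_median3d_brute(NumericVector vol, int k) {
  Dim3 d = get_dim(vol);
  const int p = k / 2;
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  std::vector<double> buf((size_t)k * k * k);
  const size_t mid = buf.size() / 2;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        size_t m = 0;
        for (int dx = -p; dx <= p; ++dx) {
          int xs = reflect(x + dx, d.nx);
          for (int dy = -p; dy <= p; ++dy) {
            int ys = reflect(y + dy, d.ny);
            for (int dz = -p; dz <= p; ++dz)
              buf[m++] = vol[lin(d, reflect(z + dz, d.nz), ys, xs)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[lin(d, z, y, x)] = buf[mid];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Deriche recursive filtering
// ---------------------------------------------------------------------------

namespace {

// One line, length n, symmetric-reflection padding of width P, steady-state
// initialised second-order recursions.  order 0: Deriche smoother with unit
// DC gain; order 1: antisymmetric Deriche derivative normalised so a unit
// ramp has derivative 1.
void deriche_line(const double* in, double* out, int n, double alpha, int order,
                  std::vector<double>& xbuf, std::vector<double>& yp,
                  std::vector<double>& ym) {
  const double e = std::exp(-alpha);
  int P = (int)std::ceil(12.0 / alpha);
  const int m = n + 2 * P;
  if ((int)xbuf.size() < m) { xbuf.resize(m); yp.resize(m); ym.resize(m); }
  for (int i = 0; i < m; ++i) xbuf[i] = in[reflect(i - P, n)];
  const double b1 = 2.0 * e, b2 = -e * e;
  if (order == 0) {
    const double kk = (1.0 - e) * (1.0 - e) / (1.0 + 2.0 * alpha * e - e * e);
    const double a1 = kk, a2 = kk * e * (alpha - 1.0),
                 a3 = kk * e * (alpha + 1.0), a4 = -kk * e * e;
    // causal: kernel k(1+alpha n)e^{-alpha n}, n >= 0
    double ss = (a1 + a2) / (1.0 - b1 - b2);  // steady state per unit input
    double y1 = ss * xbuf[0], y2 = ss * xbuf[0];
    for (int i = 0; i < m; ++i) {
      double xm1 = (i >= 1) ? xbuf[i - 1] : xbuf[0];
      double y = a1 * xbuf[i] + a2 * xm1 + b1 * y1 + b2 * y2;
      y2 = y1; y1 = y; yp[i] = y;
    }
    // anticausal: kernel k(1+alpha|n|)e^{-alpha|n|}, n <= -1
    ss = (a3 + a4) / (1.0 - b1 - b2);
    y1 = ss * xbuf[m - 1]; y2 = ss * xbuf[m - 1];
    for (int i = m - 1; i >= 0; --i) {
      double xp1 = (i + 1 < m) ? xbuf[i + 1] : xbuf[m - 1];
      double xp2 = (i + 2 < m) ? xbuf[i + 2] : xbuf[m - 1];
      double y = a3 * xp1 + a4 * xp2 + b1 * y1 + b2 * y2;
      y2 = y1; y1 = y; ym[i] = y;
    }
    for (int i = 0; i < n; ++i) out[i] = yp[i + P] + ym[i + P];
  } else {
    // h+(n) = n e^{-alpha n} (n>=1);  h-(n) = |n| e^{-alpha|n|} (n<=-1)
    const double c = (1.0 - e) * (1.0 - e) * (1.0 - e) / (2.0 * e * (1.0 + e));
    double ss = e / ((1.0 - e) * (1.0 - e));
    double y1 = ss * xbuf[0], y2 = ss * xbuf[0];
    for (int i = 0; i < m; ++i) {
      double xm1 = (i >= 1) ? xbuf[i - 1] : xbuf[0];
      double y = e * xm1 + b1 * y1 + b2 * y2;
      y2 = y1; y1 = y; yp[i] = y;
    }
    y1 = ss * xbuf[m - 1]; y2 = ss * xbuf[m - 1];
    for (int i = m - 1; i >= 0; --i) {
      double xp1 = (i + 1 < m) ? xbuf[i + 1] : xbuf[m - 1];
      double y = e * xp1 + b1 * y1 + b2 * y2;
      y2 = y1; y1 = y; ym[i] = y;
    }
    for (int i = 0; i < n; ++i) out[i] = c * (ym[i + P] - yp[i + P]);
  }
}

} // namespace

// Apply the Deriche filter of given order along one axis (0=z, 1=y, 2=x).
// [[Rcpp::export]]
NumericVector cpp_deriche_axis(NumericVector vol, double alpha, int axis, int order) {
  Dim3 d = get_dim(vol);
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  std::vector<double> xb, yp, ym;
  if (axis == 0) {
    std::vector<double> line(d.nz), lout(d.nz);
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y) {
        const double* src = &vol[lin(d, 0, y, x)];
        deriche_line(src, &out[lin(d, 0, y, x)], d.nz, alpha, order, xb, yp, ym);
      }
  } else if (axis == 1) {
    std::vector<double> line(d.ny), lout(d.ny);
    for (int x = 0; x < d.nx; ++x)
      for (int z = 0; z < d.nz; ++z) {
        for (int y = 0; y < d.ny; ++y) line[y] = vol[lin(d, z, y, x)];
        deriche_line(line.data(), lout.data(), d.ny, alpha, order, xb, yp, ym);
        for (int y = 0; y < d.ny; ++y) out[lin(d, z, y, x)] = lout[y];
      }
  } else {
    std::vector<double> line(d.nx), lout(d.nx);
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        for (int x = 0; x < d.nx; ++x) line[x] = vol[lin(d, z, y, x)];
        deriche_line(line.data(), lout.data(), d.nx, alpha, order, xb, yp, ym);
        for (int x = 0; x < d.nx; ++x) out[lin(d, z, y, x)] = lout[x];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Canny: non-maximum suppression + hysteresis
// ---------------------------------------------------------------------------

// Suppress non-maxima of the gradient magnitude along the 26-quantized
// gradient direction.  Returns the magnitude with suppressed voxels zeroed.
// [[Rcpp::export]]
NumericVector cpp_nms26(NumericVector gz, NumericVector gy, NumericVector gx) {
  Dim3 d = get_dim(gz);
  NumericVector mag(gz.size());
  mag.attr("dim") = gz.attr("dim");
  for (R_xlen_t i = 0; i < d.n; ++i)
    mag[i] = std::sqrt(gz[i] * gz[i] + gy[i] * gy[i] + gx[i] * gx[i]);
  NumericVector out(gz.size());
  out.attr("dim") = gz.attr("dim");
  // precompute normalized offset directions
  double dirn[26][3];
  for (int k = 0; k < 26; ++k) {
    double nn = std::sqrt((double)(OFF26[k][0] * OFF26[k][0] +
                                   OFF26[k][1] * OFF26[k][1] +
                                   OFF26[k][2] * OFF26[k][2]));
    dirn[k][0] = OFF26[k][0] / nn;
    dirn[k][1] = OFF26[k][1] / nn;
    dirn[k][2] = OFF26[k][2] / nn;
  }
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        double m = mag[i];
        if (m <= 0) continue;
        double bz = gz[i] / m, by = gy[i] / m, bx = gx[i] / m;
        int best = 0; double bestdot = -2.0;
        for (int k = 0; k < 26; ++k) {
          double dot = bz * dirn[k][0] + by * dirn[k][1] + bx * dirn[k][2];
          if (dot >= bestdot) { bestdot = dot; best = k; }
        }
        const int dz = OFF26[best][0], dy = OFF26[best][1], dx = OFF26[best][2];
        double fwd = 0.0, bwd = 0.0;
        int z2 = z + dz, y2 = y + dy, x2 = x + dx;
        if (z2 >= 0 && z2 < d.nz && y2 >= 0 && y2 < d.ny && x2 >= 0 && x2 < d.nx)
          fwd = mag[lin(d, z2, y2, x2)];
        z2 = z - dz; y2 = y - dy; x2 = x - dx;
        if (z2 >= 0 && z2 < d.nz && y2 >= 0 && y2 < d.ny && x2 >= 0 && x2 < d.nx)
          bwd = mag[lin(d, z2, y2, x2)];
        if ((m > fwd && m >= bwd) || (m >= fwd && m > bwd)) out[i] = m;
      }
  return out;
}

// Hysteresis thresholding with 26-connectivity.
// [[Rcpp::export]]
LogicalVector cpp_hysteresis(NumericVector nms, double tlow, double thigh) {
  Dim3 d = get_dim(nms);
  LogicalVector out(nms.size());
  out.attr("dim") = nms.attr("dim");
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        if (nms[i] >= thigh && !out[i]) {
          out[i] = TRUE; stack.push_back(i);
          while (!stack.empty()) {
            R_xlen_t j = stack.back(); stack.pop_back();
            int xz = (int)(j % d.nz);
            int xy = (int)((j / d.nz) % d.ny);
            int xx = (int)(j / ((R_xlen_t)d.nz * d.ny));
            for (int k = 0; k < 26; ++k) {
              int z2 = xz + OFF26[k][0], y2 = xy + OFF26[k][1], x2 = xx + OFF26[k][2];
              if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
                continue;
              R_xlen_t jj = lin(d, z2, y2, x2);
              if (!out[jj] && nms[jj] >= tlow) { out[jj] = TRUE; stack.push_back(jj); }
            }
          }
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (26-connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < d.n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next; stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int z = (int)(j % d.nz);
      int y = (int)((j / d.nz) % d.ny);
      int x = (int)(j / ((R_xlen_t)d.nz * d.ny));
      for (int k = 0; k < 26; ++k) {
        int z2 = z + OFF26[k][0], y2 = y + OFF26[k][1], x2 = x + OFF26[k][2];
        if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
          continue;
        R_xlen_t jj = lin(d, z2, y2, x2);
        if (mask[jj] && !lab[jj]) { lab[jj] = next; stack.push_back(jj); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Hole filling
// ---------------------------------------------------------------------------

// Fill 3D cavities: background components (6-connectivity) not reachable
// from the volume border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_3d(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  std::vector<char> outside(d.n, 0);
  std::vector<R_xlen_t> stack;
  auto push_if_bg = [&](int z, int y, int x) {
    R_xlen_t i = lin(d, z, y, x);
    if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
  };
  for (int y = 0; y < d.ny; ++y)
    for (int x = 0; x < d.nx; ++x) { push_if_bg(0, y, x); push_if_bg(d.nz - 1, y, x); }
  for (int z = 0; z < d.nz; ++z)
    for (int x = 0; x < d.nx; ++x) { push_if_bg(z, 0, x); push_if_bg(z, d.ny - 1, x); }
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y) { push_if_bg(z, y, 0); push_if_bg(z, y, d.nx - 1); }
  while (!stack.empty()) {
    R_xlen_t j = stack.back(); stack.pop_back();
    int z = (int)(j % d.nz);
    int y = (int)((j / d.nz) % d.ny);
    int x = (int)(j / ((R_xlen_t)d.nz * d.ny));
    for (int k = 0; k < 6; ++k) {
      int z2 = z + OFF6[k][0], y2 = y + OFF6[k][1], x2 = x + OFF6[k][2];
      if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
        continue;
      R_xlen_t jj = lin(d, z2, y2, x2);
      if (!mask[jj] && !outside[jj]) { outside[jj] = 1; stack.push_back(jj); }
    }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < d.n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Per-slice 2D hole filling along one axis (slices perpendicular to `axis`;
// 4-connectivity within the slice).
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, int axis) {
  Dim3 d = get_dim(mask);
  LogicalVector out = clone(mask);
  // slice dims (a = slice index axis; u, v in-plane)
  int na, nu, nv;
  if (axis == 0)      { na = d.nz; nu = d.ny; nv = d.nx; }
  else if (axis == 1) { na = d.ny; nu = d.nz; nv = d.nx; }
  else                { na = d.nx; nu = d.nz; nv = d.ny; }
  auto at = [&](int a, int u, int v) -> R_xlen_t {
    if (axis == 0) return lin(d, a, u, v);
    if (axis == 1) return lin(d, u, a, v);
    return lin(d, u, v, a);
  };
  std::vector<char> outside((size_t)nu * nv);
  std::vector<int> stack;
  for (int a = 0; a < na; ++a) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    auto push_if_bg = [&](int u, int v) {
      if (!mask[at(a, u, v)] && !outside[(size_t)u + (size_t)nu * v]) {
        outside[(size_t)u + (size_t)nu * v] = 1;
        stack.push_back(u + nu * v);
      }
    };
    for (int u = 0; u < nu; ++u) { push_if_bg(u, 0); push_if_bg(u, nv - 1); }
    for (int v = 0; v < nv; ++v) { push_if_bg(0, v); push_if_bg(nu - 1, v); }
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      int u = j % nu, v = j / nu;
      const int du[4] = {-1, 1, 0, 0}, dv[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int u2 = u + du[k], v2 = v + dv[k];
        if (u2 < 0 || u2 >= nu || v2 < 0 || v2 >= nv) continue;
        if (!mask[at(a, u2, v2)] && !outside[(size_t)u2 + (size_t)nu * v2]) {
          outside[(size_t)u2 + (size_t)nu * v2] = 1;
          stack.push_back(u2 + nu * v2);
        }
      }
    }
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u)
        if (!outside[(size_t)u + (size_t)nu * v]) out[at(a, u, v)] = TRUE;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology with an explicit offset list (structuring element)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerMatrix offsets) {
  Dim3 d = get_dim(mask);
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  const int no = offsets.nrow();
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        if (!mask[lin(d, z, y, x)]) continue;
        for (int k = 0; k < no; ++k) {
          int z2 = z + offsets(k, 0), y2 = y + offsets(k, 1), x2 = x + offsets(k, 2);
          if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
            continue;
          out[lin(d, z2, y2, x2)] = TRUE;
        }
      }
  return out;
}

// Erosion; out-of-volume voxels count as foreground (border structures are
// not eroded from outside the field of view).
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerMatrix offsets) {
  Dim3 d = get_dim(mask);
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  const int no = offsets.nrow();
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        if (!mask[lin(d, z, y, x)]) continue;
        bool keep = true;
        for (int k = 0; k < no && keep; ++k) {
          int z2 = z + offsets(k, 0), y2 = y + offsets(k, 1), x2 = x + offsets(k, 2);
          if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
            continue;  // outside treated as foreground
          if (!mask[lin(d, z2, y2, x2)]) keep = false;
        }
        out[lin(d, z, y, x)] = keep;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher)
// ---------------------------------------------------------------------------

namespace {

const double DT_INF = 1e20;

// 1D squared distance transform of sampled function f; result into g.
void dt1d(const double* f, double* g, int n, std::vector<int>& v,
          std::vector<double>& z) {
  if ((int)v.size() < n) { v.resize(n); z.resize(n + 1); }
  int k = 0;
  v[0] = 0; z[0] = -DT_INF; z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    g[q] = dq * dq + f[v[k]];
  }
}

} // namespace

// Squared Euclidean distance (in voxel units) from each foreground voxel to
// the nearest background voxel centre.  Background voxels get 0.  Voxels
// outside the volume are not considered background (FOV continuation).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  NumericVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < d.n; ++i) out[i] = mask[i] ? DT_INF : 0.0;
  std::vector<int> v; std::vector<double> zz;
  std::vector<double> f(std::max(std::max(d.nz, d.ny), d.nx));
  std::vector<double> g(f.size());
  // along z (contiguous)
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      double* col = &out[lin(d, 0, y, x)];
      dt1d(col, g.data(), d.nz, v, zz);
      std::memcpy(col, g.data(), sizeof(double) * d.nz);
    }
  // along y
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = out[lin(d, z, y, x)];
      dt1d(f.data(), g.data(), d.ny, v, zz);
      for (int y = 0; y < d.ny; ++y) out[lin(d, z, y, x)] = g[y];
    }
  // along x
  for (int y = 0; y < d.ny; ++y)
    for (int z = 0; z < d.nz; ++z) {
      for (int x = 0; x < d.nx; ++x) f[x] = out[lin(d, z, y, x)];
      dt1d(f.data(), g.data(), d.nx, v, zz);
      for (int x = 0; x < d.nx; ++x) out[lin(d, z, y, x)] = g[x];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (Hildebrand-Ruegsegger) by exhaustive sphere painting
// ---------------------------------------------------------------------------

// For every foreground voxel q the inscribed sphere centred at q with
// radius r(q) = sqrt(edt_sq[q]) (centre-to-centre distance to the nearest
// background voxel) paints diameter 2*r(q) onto every voxel it covers;
// each voxel keeps the maximum.  Exact w.r.t.
// thickness(p) = 2 * max{ r(q) : |p-q| <= r(q) }.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, NumericVector edt_sq) {
  Dim3 d = get_dim(mask);
  NumericVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  // process in decreasing radius order so most writes are early
  std::vector<R_xlen_t> idx;
  for (R_xlen_t i = 0; i < d.n; ++i) if (mask[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return edt_sq[a] > edt_sq[b];
  });
  for (R_xlen_t t = 0; t < (R_xlen_t)idx.size(); ++t) {
    R_xlen_t i = idx[t];
    double r2 = edt_sq[i];
    if (r2 <= 0) continue;
    double rs = std::sqrt(r2);
    double rs2 = r2;
    double dia = 2.0 * rs;
    int z = (int)(i % d.nz);
    int y = (int)((i / d.nz) % d.ny);
    int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
    int ri = (int)std::floor(rs + 1e-9);
    for (int dx = -ri; dx <= ri; ++dx) {
      int x2 = x + dx;
      if (x2 < 0 || x2 >= d.nx) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= d.ny) continue;
        double rem = rs2 - dx * dx - dy * dy;
        if (rem < 0) continue;
        int rz = (int)std::floor(std::sqrt(rem) + 1e-9);
        int zlo = std::max(0, z - rz), zhi = std::min(d.nz - 1, z + rz);
        R_xlen_t base = lin(d, 0, y2, x2);
        for (int z2 = zlo; z2 <= zhi; ++z2) {
          if (out[base + z2] < dia) out[base + z2] = dia;
        }
      }
    }
    // rs may be < 1 yet the centre voxel itself is always covered
    if (out[i] < dia) out[i] = dia;
  }
  // spheres with centre-to-centre radii graze background voxel centres;
  // thickness is only defined on the foreground
  for (R_xlen_t i = 0; i < d.n; ++i) if (!mask[i]) out[i] = 0.0;
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning (sequential, 6 directional subiterations)
// ---------------------------------------------------------------------------

namespace {

// 3x3x3 neighbourhood occupancy around a voxel; nb[dz+1][dy+1][dx+1].
// Out-of-volume neighbours are foreground (FOV continuation).
inline void fetch_nbhd(const std::vector<char>& m, const Dim3& d,
                       int z, int y, int x, bool nb[3][3][3]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int z2 = z + dz, y2 = y + dy, x2 = x + dx;
        if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
          nb[dz + 1][dy + 1][dx + 1] = true;
        else
          nb[dz + 1][dy + 1][dx + 1] = m[lin(d, z2, y2, x2)] != 0;
      }
}

// number of foreground 26-neighbours
inline int count26(const bool nb[3][3][3]) {
  int c = 0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        if (!(i == 1 && j == 1 && k == 1) && nb[i][j][k]) ++c;
  return c;
}

// Bertrand-Malandain characterisation of a simple point:
//   T26 (fg 26-components in N26)  == 1   and
//   T6+ (bg 6-components of N18 6-adjacent to the centre) == 1
bool is_simple(const bool nb[3][3][3]) {
  // --- T26 over foreground in the 26-neighbourhood ---
  int labs[27]; int idx[27];
  int nfg = 0;
  for (int i = 0; i < 27; ++i) labs[i] = -1;
  for (int i = 0; i < 27; ++i) {
    if (i == 13) continue;
    if (nb[i / 9][(i / 3) % 3][i % 3]) idx[nfg++] = i;
  }
  if (nfg == 0) return false;
  int ncomp = 0;
  for (int s = 0; s < nfg; ++s) {
    int start = idx[s];
    if (labs[start] != -1) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int stack[27]; int sp = 0;
    stack[sp++] = start; labs[start] = ncomp;
    while (sp) {
      int cur = stack[--sp];
      int cz = cur / 9, cy = (cur / 3) % 3, cx = cur % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
            int j = z2 * 9 + y2 * 3 + x2;
            if (j == 13 || labs[j] != -1) continue;
            if (nb[z2][y2][x2]) { labs[j] = ncomp; stack[sp++] = j; }
          }
    }
  }
  // --- T6+ over background in N18, 6-connectivity, seeded at face voxels ---
  for (int i = 0; i < 27; ++i) labs[i] = -1;
  const int faces[6] = {4, 22, 10, 16, 12, 14};  // the six 6-neighbours
  int nbg = 0;
  for (int s = 0; s < 6; ++s) {
    int start = faces[s];
    if (nb[start / 9][(start / 3) % 3][start % 3]) continue;  // fg
    if (labs[start] != -1) continue;
    ++nbg;
    if (nbg > 1) return false;
    int stack[27]; int sp = 0;
    stack[sp++] = start; labs[start] = nbg;
    while (sp) {
      int cur = stack[--sp];
      int cz = cur / 9, cy = (cur / 3) % 3, cx = cur % 3;
      const int dzs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dxs[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int z2 = cz + dzs[k], y2 = cy + dys[k], x2 = cx + dxs[k];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        // restrict to N18: exclude the 8 corners and the centre
        int man = std::abs(z2 - 1) + std::abs(y2 - 1) + std::abs(x2 - 1);
        if (man == 0 || man == 3) continue;
        int j = z2 * 9 + y2 * 3 + x2;
        if (labs[j] != -1 || nb[z2][y2][x2]) continue;
        labs[j] = nbg; stack[sp++] = j;
      }
    }
  }
  return nbg == 1;
}

} // namespace

// Medial-axis thinning: iteratively delete simple, non-endpoint border
// voxels in six directional subiterations until stable.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  std::vector<char> m(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) m[i] = mask[i] ? 1 : 0;
  bool nb[3][3][3];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      const int bz = OFF6[dir][0], by = OFF6[dir][1], bx = OFF6[dir][2];
      cand.clear();
      for (int x = 0; x < d.nx; ++x)
        for (int y = 0; y < d.ny; ++y)
          for (int z = 0; z < d.nz; ++z) {
            R_xlen_t i = lin(d, z, y, x);
            if (!m[i]) continue;
            int z2 = z + bz, y2 = y + by, x2 = x + bx;
            if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
              continue;  // outside counts as foreground: not a border voxel
            if (m[lin(d, z2, y2, x2)]) continue;
            cand.push_back(i);
          }
      for (R_xlen_t t = 0; t < (R_xlen_t)cand.size(); ++t) {
        R_xlen_t i = cand[t];
        if (!m[i]) continue;
        int z = (int)(i % d.nz);
        int y = (int)((i / d.nz) % d.ny);
        int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
        fetch_nbhd(m, d, z, y, x, nb);
        if (count26(nb) <= 1) continue;          // endpoint (or isolated)
        if (!is_simple(nb)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < d.n; ++i) out[i] = m[i] != 0;
  return out;
}

// 26-neighbour counts of foreground voxels (out-of-volume = background here:
// used for skeleton graph degrees, where the graph must be self-contained).
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency26(LogicalVector mask) {
  Dim3 d = get_dim(mask);
  // positive-direction half of the 26 offsets to enumerate each edge once
  std::vector<std::pair<int, int>> edges;
  std::vector<int> vox_of(d.n, 0);  // 1-based voxel order among foreground
  int nv = 0;
  for (R_xlen_t i = 0; i < d.n; ++i) if (mask[i]) vox_of[i] = ++nv;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        if (!mask[i]) continue;
        for (int k = 0; k < 26; ++k) {
          const int dz = OFF26[k][0], dy = OFF26[k][1], dx = OFF26[k][2];
          // take only offsets that are lexicographically positive
          if (dx < 0 || (dx == 0 && dy < 0) || (dx == 0 && dy == 0 && dz <= 0))
            continue;
          int z2 = z + dz, y2 = y + dy, x2 = x + dx;
          if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
            continue;
          R_xlen_t j = lin(d, z2, y2, x2);
          if (mask[j]) edges.push_back(std::make_pair(vox_of[i], vox_of[j]));
        }
      }
  IntegerMatrix em(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    em(e, 0) = edges[e].first;
    em(e, 1) = edges[e].second;
  }
  return em;
}

// ---------------------------------------------------------------------------
// Tube rasterization for the phantom generator
// ---------------------------------------------------------------------------

// segs columns: z0,y0,x0,z1,y1,x1 (um), r0,r1 (um), arc0 (um), tube_id (1-based)
// Voxel (z,y,x) centre is at (z,y,x)*voxel_size_um.  A voxel is vessel iff its
// centre lies within the local radius of some centreline segment; ties across
// tubes resolved by smallest signed surface distance.
// [[Rcpp::export]]
List cpp_rasterize_tubes(IntegerVector dim, double voxel_size_um,
                         NumericMatrix segs) {
  Dim3 d;
  d.nz = dim[0]; d.ny = dim[1]; d.nx = dim[2];
  d.n = (R_xlen_t)d.nz * d.ny * d.nx;
  LogicalVector mask(d.n);
  mask.attr("dim") = dim;
  NumericVector arc(d.n);
  IntegerVector tube(d.n);
  arc.attr("dim") = dim;
  tube.attr("dim") = dim;
  std::vector<double> bestsd(d.n, 1e30);
  const double h = voxel_size_um;
  for (int s = 0; s < segs.nrow(); ++s) {
    const double az = segs(s, 0), ay = segs(s, 1), ax = segs(s, 2);
    const double bz = segs(s, 3), by = segs(s, 4), bx = segs(s, 5);
    const double r0 = segs(s, 6), r1 = segs(s, 7);
    const double arc0 = segs(s, 8);
    const int tid = (int)segs(s, 9);
    const double wz = bz - az, wy = by - ay, wx = bx - ax;
    const double ww = wz * wz + wy * wy + wx * wx;
    const double seglen = std::sqrt(ww);
    const double rmax = std::max(r0, r1);
    int zlo = std::max(0, (int)std::floor((std::min(az, bz) - rmax) / h) - 1);
    int zhi = std::min(d.nz - 1, (int)std::ceil((std::max(az, bz) + rmax) / h) + 1);
    int ylo = std::max(0, (int)std::floor((std::min(ay, by) - rmax) / h) - 1);
    int yhi = std::min(d.ny - 1, (int)std::ceil((std::max(ay, by) + rmax) / h) + 1);
    int xlo = std::max(0, (int)std::floor((std::min(ax, bx) - rmax) / h) - 1);
    int xhi = std::min(d.nx - 1, (int)std::ceil((std::max(ax, bx) + rmax) / h) + 1);
    for (int x = xlo; x <= xhi; ++x)
      for (int y = ylo; y <= yhi; ++y)
        for (int z = zlo; z <= zhi; ++z) {
          const double pz = z * h, py = y * h, px = x * h;
          double t = 0.0;
          if (ww > 0)
            t = ((pz - az) * wz + (py - ay) * wy + (px - ax) * wx) / ww;
          t = std::max(0.0, std::min(1.0, t));
          const double cz = az + t * wz, cy = ay + t * wy, cx = ax + t * wx;
          const double dist = std::sqrt((pz - cz) * (pz - cz) +
                                        (py - cy) * (py - cy) +
                                        (px - cx) * (px - cx));
          const double r = r0 + (r1 - r0) * t;
          const double sd = dist - r;
          R_xlen_t i = lin(d, z, y, x);
          if (sd < bestsd[i]) {
            bestsd[i] = sd;
            arc[i] = arc0 + t * seglen;
            tube[i] = tid;
          }
        }
  }
  for (R_xlen_t i = 0; i < d.n; ++i) {
    if (bestsd[i] <= 0.0) mask[i] = TRUE;
    else { arc[i] = 0.0; tube[i] = 0; }
  }
  return List::create(_["mask"] = mask, _["arc_um"] = arc, _["tube"] = tube);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur (truncated FIR, symmetric reflection)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, double sigma_vox) {
  Dim3 d = get_dim(vol);
  if (sigma_vox <= 0) return clone(vol);
  const int R = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> w(2 * R + 1);
  double sw = 0;
  for (int i = -R; i <= R; ++i) {
    w[i + R] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    sw += w[i + R];
  }
  for (size_t i = 0; i < w.size(); ++i) w[i] /= sw;
  NumericVector cur = clone(vol);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector nxt(cur.size());
    nxt.attr("dim") = vol.attr("dim");
    int nline = (axis == 0) ? d.nz : (axis == 1 ? d.ny : d.nx);
    std::vector<double> line(nline);
    auto at = [&](int a, int u, int v) -> R_xlen_t {
      if (axis == 0) return lin(d, a, u, v);
      if (axis == 1) return lin(d, u, a, v);
      return lin(d, u, v, a);
    };
    int nu = (axis == 0) ? d.ny : d.nz;
    int nv = (axis == 2) ? d.ny : d.nx;
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u) {
        for (int a = 0; a < nline; ++a) line[a] = cur[at(a, u, v)];
        for (int a = 0; a < nline; ++a) {
          double acc = 0;
          for (int i = -R; i <= R; ++i) acc += w[i + R] * line[reflect(a + i, nline)];
          nxt[at(a, u, v)] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}
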