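#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Label connected components of equal positive level in a 3D integer array.
// levels: flattened column-major array, 0 = background (outside mask).
// conn26 = true: 26-connectivity; false: 8-connectivity within each z-slice.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector levels, IntegerVector dims, bool conn26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next_label = 0;
  const int zlo = conn26 ? -1 : 0, zhi = conn26 ? 1 : 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (levels[s] == 0 || labels[s] != 0) continue;
    const int lev = levels[s];
    ++next_label;
    labels[s] = next_label;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur / ((R_xlen_t)nx * ny);
      int rem = cur - (R_xlen_t)z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (int dz = zlo; dz <= zhi; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (labels[idx] == 0 && levels[idx] == lev) {
              labels[idx] = next_label;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("n_zones") = next_label;
  return labels;
}

static inline double tet_vol6(const double a[3], const double b[3],
                              const double c[3], const double d[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {d[0] - a[0], d[1] - a[1], d[2] - a[2]};
  return u[0] * (v[1] * w[2] - v[2] * w[1]) -
         u[1] * (v[0] * w[2] - v[2] * w[0]) +
         u[2] * (v[0] * w[1] - v[1] * w[0]);
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void lerp_pt(const double p[3], const double q[3], double dp,
                           double dq, double out[3]) {
  double t = dp / (dp - dq); // dp, dq have opposite signs
  out[0] = p[0] + t * (q[0] - p[0]);
  out[1] = p[1] + t * (q[1] - p[1]);
  out[2] = p[2] + t * (q[2] - p[2]);
}

// Iso-surface area and enclosed volume of {field >= iso} by marching
// tetrahedra on a scalar field sampled at voxel centres (column-major).
// The caller pads the field so the surface closes inside the domain.
// [[Rcpp::export]]
NumericVector march_area_volume(NumericVector field, IntegerVector dims,
                                NumericVector spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // 6-tetrahedron decomposition of the unit cell sharing diagonal 000-111
  static const int tets[6][4] = {{0, 4, 6, 7}, {0, 6, 2, 7}, {0, 2, 3, 7},
                                 {0, 3, 1, 7}, {0, 1, 5, 7}, {0, 5, 4, 7}};
  // corner offsets, bit order (x, y, z): corner c has dx=c&1, dy=(c>>1)&1, dz=(c>>2)&1
  double area = 0.0, vol = 0.0;
  double P[8][3];
  double D[8];
  for (int z = 0; z + 1 < nz; ++z) {
    for (int y = 0; y + 1 < ny; ++y) {
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          R_xlen_t idx = (R_xlen_t)(z + dz) * nx * ny +
                         (R_xlen_t)(y + dy) * nx + (x + dx);
          D[c] = field[idx] - iso;
          P[c][0] = (x + dx) * sx;
          P[c][1] = (y + dy) * sy;
          P[c][2] = (z + dz) * sz;
          if (D[c] >= 0) any_above = true; else any_below = true;
        }
        if (!any_above) continue;
        if (!any_below) { // fully inside
          vol += sx * sy * sz;
          continue;
        }
        for (int t = 0; t < 6; ++t) {
          const int *v = tets[t];
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int k = 0; k < 4; ++k) {
            if (D[v[k]] >= 0) above[na++] = v[k]; else below[nb++] = v[k];
          }
          double tv = std::fabs(tet_vol6(P[v[0]], P[v[1]], P[v[2]], P[v[3]])) / 6.0;
          if (na == 0) continue;
          if (na == 4) { vol += tv; continue; }
          if (na == 1) {
            int a = above[0];
            double p1[3], p2[3], p3[3];
            lerp_pt(P[a], P[below[0]], D[a], D[below[0]], p1);
            lerp_pt(P[a], P[below[1]], D[a], D[below[1]], p2);
            lerp_pt(P[a], P[below[2]], D[a], D[below[2]], p3);
            area += tri_area(p1, p2, p3);
            vol += std::fabs(tet_vol6(P[a], p1, p2, p3)) / 6.0;
          } else if (na == 3) {
            int b = below[0];
            double p1[3], p2[3], p3[3];
            lerp_pt(P[b], P[above[0]], D[b], D[above[0]], p1);
            lerp_pt(P[b], P[above[1]], D[b], D[above[1]], p2);
            lerp_pt(P[b], P[above[2]], D[b], D[above[2]], p3);
            area += tri_area(p1, p2, p3);
            vol += tv - std::fabs(tet_vol6(P[b], p1, p2, p3)) / 6.0;
          } else { // na == 2: wedge above with vertices a1, a2, p13, p14, p23, p24
            int a1 = above[0], a2 = above[1], b1 = below[0], b2 = below[1];
            double p13[3], p14[3], p23[3], p24[3];
            lerp_pt(P[a1], P[b1], D[a1], D[b1], p13);
            lerp_pt(P[a1], P[b2], D[a1], D[b2], p14);
            lerp_pt(P[a2], P[b1], D[a2], D[b1], p23);
            lerp_pt(P[a2], P[b2], D[a2], D[b2], p24);
            area += tri_area(p13, p14, p24) + tri_area(p13, p24, p23);
            // prism triangulation: (a1,p13,p14) ~ (a2,p23,p24)
            vol += std::fabs(tet_vol6(P[a1], p13, p14, P[a2])) / 6.0;
            vol += std::fabs(tet_vol6(p13, p14, P[a2], p23)) / 6.0;
            vol += std::fabs(tet_vol6(p14, P[a2], p23, p24)) / 6.0;
          }
        }
      }
    }
  }
  return NumericVector::create(_["area"] = area, _["volume"] = vol);
}

// Maximum pairwise Euclidean distance among points (rows of coords, mm).
// [[Rcpp::export]]
double max_pairwise_dist(NumericMatrix coords) {
  const R_xlen_t n = coords.nrow();
  double best = 0.0;
  for (R_xlen_t i = 0; i + 1 < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Symmetric gray-level co-occurrence counts for each offset (rows of
// offsets), restricted to voxels with level > 0. Returns an ng x ng x
// n_offsets array of counts (each unordered pair counted in both orders).
// [[Rcpp::export]]
NumericVector glcm_counts(IntegerVector levels, IntegerVector dims,
                          IntegerMatrix offsets, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int noff = offsets.nrow();
  NumericVector out((R_xlen_t)ng * ng * noff);
  for (int o = 0; o < noff; ++o) {
    const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    double *mat = &out[(R_xlen_t)o * ng * ng];
    for (int z = 0; z < nz; ++z) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          int li = levels[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
          if (li == 0) continue;
          int lj = levels[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          if (lj == 0) continue;
          mat[(R_xlen_t)(lj - 1) * ng + (li - 1)] += 1.0;
          mat[(R_xlen_t)(li - 1) * ng + (lj - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, noff);
  return out;
}

// Separable convolution of a 3D array with a 1D kernel applied along all
// three axes, replicating edge values (used for Gaussian smoothing).
// [[Rcpp::export]]
NumericVector conv3d_sep(NumericVector field, IntegerVector dims,
                         NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kn = kernel.size();
  const int kh = kn / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  // axis strides and extents
  const int ext[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = ext[ax];
    const R_xlen_t st = strides[ax];
    const int e1 = ext[(ax + 1) % 3], e2 = ext[(ax + 2) % 3];
    const R_xlen_t s1 = strides[(ax + 1) % 3], s2 = strides[(ax + 2) % 3];
    for (int i2 = 0; i2 < e2; ++i2) {
      for (int i1 = 0; i1 < e1; ++i1) {
        R_xlen_t base = i1 * s1 + i2 * s2;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int k = 0; k < kn; ++k) {
            int src = i + k - kh;
            if (src < 0) src = 0;
            if (src >= len) src = len - 1;
            acc += kernel[k] * a[base + (R_xlen_t)src * st];
          }
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
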