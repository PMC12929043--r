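#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---- cell-list neighbour search -------------------------------------------
//
// Pairs (i, j), i < j, with center distance <= cutoff.  Linked-cell grid with
// cell edge = cutoff; equivalent to the O(n^2) scan and tested against it.

// [[Rcpp::export]]
DataFrame cpp_neighbor_pairs(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  std::vector<int> out_i, out_j;
  std::vector<double> out_d;
  if (n < 2 || cutoff <= 0) {
    return DataFrame::create(_["i"] = IntegerVector(0),
                             _["j"] = IntegerVector(0),
                             _["dist"] = NumericVector(0));
  }
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = pos(0, k); hi[k] = pos(0, k);
    for (int i = 1; i < n; ++i) {
      lo[k] = std::min(lo[k], pos(i, k));
      hi[k] = std::max(hi[k], pos(i, k));
    }
  }
  int nc[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / cutoff) + 1);
    nc[k] = std::min(nc[k], 512);  // cap grid; cells then exceed cutoff, still correct
  }
  double cs[3];
  for (int k = 0; k < 3; ++k)
    cs[k] = std::max((hi[k] - lo[k]) / nc[k], cutoff) + 1e-12;
  const long ncell = (long)nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > cells(ncell);
  std::vector<long> cell_of(n);
  for (int i = 0; i < n; ++i) {
    long cx = std::min((long)((pos(i, 0) - lo[0]) / cs[0]), (long)nc[0] - 1);
    long cy = std::min((long)((pos(i, 1) - lo[1]) / cs[1]), (long)nc[1] - 1);
    long cz = std::min((long)((pos(i, 2) - lo[2]) / cs[2]), (long)nc[2] - 1);
    long c = cx + nc[0] * (cy + (long)nc[1] * cz);
    cells[c].push_back(i);
    cell_of[i] = c;
  }
  const double c2 = cutoff * cutoff;
  for (long cx = 0; cx < nc[0]; ++cx)
    for (long cy = 0; cy < nc[1]; ++cy)
      for (long cz = 0; cz < nc[2]; ++cz) {
        long c = cx + nc[0] * (cy + (long)nc[1] * cz);
        if (cells[c].empty()) continue;
        for (long dx = -1; dx <= 1; ++dx)
          for (long dy = -1; dy <= 1; ++dy)
            for (long dz = -1; dz <= 1; ++dz) {
              long ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (ex < 0 || ey < 0 || ez < 0 ||
                  ex >= nc[0] || ey >= nc[1] || ez >= nc[2]) continue;
              long e = ex + nc[0] * (ey + (long)nc[1] * ez);
              if (e < c) continue;  // each cell pair once
              const std::vector<int> &A = cells[c], &B = cells[e];
              for (size_t a = 0; a < A.size(); ++a) {
                size_t b0 = (e == c) ? a + 1 : 0;
                for (size_t b = b0; b < B.size(); ++b) {
                  int i = A[a], j = B[b];
                  double ddx = pos(i, 0) - pos(j, 0);
                  double ddy = pos(i, 1) - pos(j, 1);
                  double ddz = pos(i, 2) - pos(j, 2);
                  double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                  if (d2 <= c2) {
                    if (i < j) { out_i.push_back(i + 1); out_j.push_back(j + 1); }
                    else       { out_i.push_back(j + 1); out_j.push_back(i + 1); }
                    out_d.push_back(std::sqrt(d2));
                  }
                }
              }
            }
      }
  return DataFrame::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                           _["dist"] = wrap(out_d));
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) -----

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxel units) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (long i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (long iz = 0; iz < nz; ++iz)
    for (long iy = 0; iy < ny; ++iy) {
      long base = nx * (iy + (long)ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[base + ix];
      dt1d(f, d, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) g[base + ix] = d[ix];
    }
  // along y
  for (long iz = 0; iz < nz; ++iz)
    for (long ix = 0; ix < nx; ++ix) {
      long base = ix + (long)nx * ny * iz;
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[base + (long)nx * iy];
      dt1d(f, d, v, z, ny);
      for (int iy = 0; iy < ny; ++iy) g[base + (long)nx * iy] = d[iy];
    }
  // along z
  const long nxy = (long)nx * ny;
  for (long iy = 0; iy < ny; ++iy)
    for (long ix = 0; ix < nx; ++ix) {
      long base = ix + (long)nx * iy;
      for (int iz = 0; iz < nz; ++iz) f[iz] = g[base + nxy * iz];
      dt1d(f, d, v, z, nz);
      for (int iz = 0; iz < nz; ++iz) g[base + nxy * iz] = d[iz];
    }
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- local thickness -------------------------------------------------------
//
// For each void voxel, the diameter (voxel units) of the largest inscribed
// ball that contains it.  dt must be the distance from void voxels to the
// nearest non-void voxel.  Centers whose maximal ball is contained in a
// neighbour's maximal ball are pruned (exact containment test), the rest are
// painted in descending radius order.

// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector dt, LogicalVector voidmask,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  NumericVector lt(n);
  std::vector<long> centers;
  centers.reserve(n / 8);
  const double sq2 = std::sqrt(2.0), sq3 = std::sqrt(3.0);
  for (long iz = 0; iz < nz; ++iz)
    for (long iy = 0; iy < ny; ++iy)
      for (long ix = 0; ix < nx; ++ix) {
        long i = ix + nx * (iy + (long)ny * iz);
        if (!voidmask[i] || dt[i] <= 0) continue;
        bool redundant = false;
        for (int dz = -1; dz <= 1 && !redundant; ++dz)
          for (int dy = -1; dy <= 1 && !redundant; ++dy)
            for (int dx = -1; dx <= 1 && !redundant; ++dx) {
              if (!dx && !dy && !dz) continue;
              long jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
                continue;
              long j = jx + nx * (jy + (long)ny * jz);
              if (!voidmask[j]) continue;
              int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
              double step = (ad == 1) ? 1.0 : (ad == 2 ? sq2 : sq3);
              if (dt[j] >= dt[i] + step - 1e-12) redundant = true;
            }
        if (!redundant) centers.push_back(i);
      }
  std::sort(centers.begin(), centers.end(),
            [&](long a, long b) { return dt[a] > dt[b]; });
  for (size_t ci = 0; ci < centers.size(); ++ci) {
    long c = centers[ci];
    double r = dt[c];
    long cz = c / nxy, cy = (c - cz * nxy) / nx, cx = c - cz * nxy - cy * (long)nx;
    // epsilon guards: voxels exactly at distance r must be covered
    int ir = (int)std::floor(r + 1e-9);
    double r2 = r * r + 1e-9, diam = 2.0 * r;
    for (int dz = -ir; dz <= ir; ++dz) {
      long jz = cz + dz;
      if (jz < 0 || jz >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        long jy = cy + dy;
        if (jy < 0 || jy >= ny) continue;
        double rho2 = r2 - dz * dz - dy * dy;
        if (rho2 < 0) continue;
        int rx = (int)std::floor(std::sqrt(rho2) + 1e-9);
        long x0 = std::max((long)0, cx - rx), x1 = std::min((long)nx - 1, cx + rx);
        long base = nx * (jy + (long)ny * jz);
        for (long jx = x0; jx <= x1; ++jx) {
          long j = base + jx;
          if (lt[j] < diam) lt[j] = diam;
        }
      }
    }
  }
  for (long i = 0; i < n; ++i) if (!voidmask[i]) lt[i] = 0.0;
  return lt;
}

// ---- cylinder rasterization ------------------------------------------------
//
// Marks voxels whose center lies inside any cylinder (radius r, height h,
// axis = row of normals, centered at row of centers).  Units: same as voxel.

// [[Rcpp::export]]
LogicalVector cpp_fill_cylinders(NumericMatrix centers, NumericMatrix normals,
                                 double r, double h, NumericVector origin,
                                 double voxel, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector occ(n);
  const double rb = std::sqrt(r * r + h * h / 4.0);  // bounding sphere
  const double half_h = h / 2.0, r2 = r * r;
  for (int p = 0; p < centers.nrow(); ++p) {
    double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    double ax = normals(p, 0), ay = normals(p, 1), az = normals(p, 2);
    int x0 = std::max(0, (int)std::floor((cx - rb - origin[0]) / voxel));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + rb - origin[0]) / voxel));
    int y0 = std::max(0, (int)std::floor((cy - rb - origin[1]) / voxel));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + rb - origin[1]) / voxel));
    int z0 = std::max(0, (int)std::floor((cz - rb - origin[2]) / voxel));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + rb - origin[2]) / voxel));
    for (int iz = z0; iz <= z1; ++iz) {
      double vz = origin[2] + (iz + 0.5) * voxel - cz;
      for (int iy = y0; iy <= y1; ++iy) {
        double vy = origin[1] + (iy + 0.5) * voxel - cy;
        for (int ix = x0; ix <= x1; ++ix) {
          double vx = origin[0] + (ix + 0.5) * voxel - cx;
          double axial = vx * ax + vy * ay + vz * az;
          if (std::fabs(axial) > half_h) continue;
          double rad2 = vx * vx + vy * vy + vz * vz - axial * axial;
          if (rad2 <= r2)
            occ[ix + nx * (iy + (long)ny * iz)] = true;
        }
      }
    }
  }
  return occ;
}

// ---- rigid push-apart relaxation ------------------------------------------
//
// Resolves inter-fiber overlaps by translating whole fibers.  Poses within a
// fiber move together; fibers are kept inside [lo, hi] on all axes.  A pose
// pair on different fibers closer than dmin contributes an equal-and-opposite
// push along the pair axis.  Returns sweeps used and the worst remaining
// inter-fiber center distance.

// [[Rcpp::export]]
List cpp_relax_fibers(NumericMatrix pos, IntegerVector fiber,
                      NumericVector lo, NumericVector hi,
                      double dmin, int max_sweeps,
                      Nullable<NumericMatrix> anchors = R_NilValue,
                      double anchor_gain = 0.0) {
  const int n = pos.nrow();
  int nf = 0;
  for (int i = 0; i < n; ++i) nf = std::max(nf, fiber[i] + 1);
  std::vector<double> shift(3 * nf);
  std::vector<int> npush(nf);
  NumericMatrix anc;
  bool use_anchor = anchors.isNotNull() && anchor_gain > 0;
  if (use_anchor) anc = NumericMatrix(anchors);
  int sweep = 0;
  double worst = std::numeric_limits<double>::infinity();
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    DataFrame prs = cpp_neighbor_pairs(pos, dmin);
    IntegerVector pi = prs["i"], pj = prs["j"];
    NumericVector pd = prs["dist"];
    std::fill(shift.begin(), shift.end(), 0.0);
    std::fill(npush.begin(), npush.end(), 0);
    int nover = 0;
    worst = std::numeric_limits<double>::infinity();
    for (int k = 0; k < pi.size(); ++k) {
      int i = pi[k] - 1, j = pj[k] - 1;
      if (fiber[i] == fiber[j]) continue;
      double d = pd[k];
      worst = std::min(worst, d);
      ++nover;
      double ux, uy, uz;
      if (d > 1e-9) {
        ux = (pos(j, 0) - pos(i, 0)) / d;
        uy = (pos(j, 1) - pos(i, 1)) / d;
        uz = (pos(j, 2) - pos(i, 2)) / d;
      } else {  // coincident: deterministic separation axis
        ux = 1.0; uy = 0.0; uz = 0.0; d = 0.0;
      }
      double push = 0.6 * (dmin - d);
      int fi = fiber[i], fj = fiber[j];
      shift[3 * fj] += push * ux; shift[3 * fj + 1] += push * uy;
      shift[3 * fj + 2] += push * uz;
      shift[3 * fi] -= push * ux; shift[3 * fi + 1] -= push * uy;
      shift[3 * fi + 2] -= push * uz;
      ++npush[fi]; ++npush[fj];
    }
    if (nover == 0) break;
    // apply mean shift per fiber (plus an optional restraint toward each
    // fiber's home slot, countering collective clumping), clamped to keep
    // every pose inside the box
    std::vector<double> fmin(3 * nf, 1e30), fmax(3 * nf, -1e30);
    std::vector<double> fcen(3 * nf, 0.0);
    std::vector<int> fcnt(nf, 0);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        fmin[3 * fiber[i] + k] = std::min(fmin[3 * fiber[i] + k], pos(i, k));
        fmax[3 * fiber[i] + k] = std::max(fmax[3 * fiber[i] + k], pos(i, k));
        fcen[3 * fiber[i] + k] += pos(i, k);
      }
      ++fcnt[fiber[i]];
    }
    for (int f = 0; f < nf; ++f) {
      for (int k = 0; k < 3; ++k) {
        // overlapping fibers follow the push field; conflict-free fibers
        // drift back toward their home slot, keeping the packing homogeneous
        double s = (npush[f] > 0) ? shift[3 * f + k] / npush[f]
          : (use_anchor ? anchor_gain * (anc(f, k) - fcen[3 * f + k] / fcnt[f])
                        : 0.0);
        s = std::max(s, lo[k] - fmin[3 * f + k]);
        s = std::min(s, hi[k] - fmax[3 * f + k]);
        shift[3 * f + k] = s;
      }
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        pos(i, k) += shift[3 * fiber[i] + k];
  }
  return List::create(_["sweeps"] = sweep, _["worst_dist"] = worst,
                      _["pos"] = pos);
}

// ---- cylinder-cylinder separation -----------------------------------------
//
// Distance between two solid cylinders by alternating Euclidean projections
// (convex bodies); overlapping pairs are resolved by bisecting a common
// shrink factor.  Facet codes: 0 = face (flat cap within face_frac of the
// cap radius), 1 = side.

static inline void proj_cyl(const double *q, const double *c, const double *a,
                            double r, double h, double *out) {
  double v[3] = {q[0] - c[0], q[1] - c[1], q[2] - c[2]};
  double ax = v[0] * a[0] + v[1] * a[1] + v[2] * a[2];
  double axc = std::max(-h / 2, std::min(h / 2, ax));
  double rad[3] = {v[0] - ax * a[0], v[1] - ax * a[1], v[2] - ax * a[2]};
  double rn = std::sqrt(rad[0] * rad[0] + rad[1] * rad[1] + rad[2] * rad[2]);
  double sc = (rn > r && rn > 0) ? r / rn : 1.0;
  for (int k = 0; k < 3; ++k) out[k] = c[k] + axc * a[k] + rad[k] * sc;
}

static inline int facet_code(const double *p, const double *c, const double *a,
                             double r, double h, double face_frac) {
  double v[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double ax = v[0] * a[0] + v[1] * a[1] + v[2] * a[2];
  double rad2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2] - ax * ax;
  if (std::fabs(std::fabs(ax) - h / 2) < 1e-6 &&
      rad2 <= face_frac * face_frac * r * r) return 0;
  return 1;
}

static double ap_dist(const double *c1, const double *n1, const double *c2,
                      const double *n2, double r1, double h1, double r2,
                      double h2, double *p, double *q) {
  for (int k = 0; k < 3; ++k) { p[k] = c1[k]; q[k] = c2[k]; }
  double d_prev = 1e300, d = 0;
  for (int it = 0; it < 200; ++it) {
    proj_cyl(q, c1, n1, r1, h1, p);
    proj_cyl(p, c2, n2, r2, h2, q);
    d = std::sqrt((p[0] - q[0]) * (p[0] - q[0]) +
                  (p[1] - q[1]) * (p[1] - q[1]) +
                  (p[2] - q[2]) * (p[2] - q[2]));
    if (d_prev - d < 1e-9) break;
    d_prev = d;
  }
  return d;
}

// [[Rcpp::export]]
List cpp_cyl_separation(NumericVector c1, NumericVector n1, NumericVector c2,
                        NumericVector n2, double r, double h,
                        double face_frac) {
  double p[3], q[3];
  double d = ap_dist(c1.begin(), n1.begin(), c2.begin(), n2.begin(),
                     r, h, r, h, p, q);
  bool overlap = d <= 1e-7;
  double sep = d;
  if (overlap) {
    double s_lo = 0, s_hi = 1;
    for (int it = 0; it < 30; ++it) {
      double s = (s_lo + s_hi) / 2;
      double ds = ap_dist(c1.begin(), n1.begin(), c2.begin(), n2.begin(),
                          r * s, h * s, r * s, h * s, p, q);
      if (ds > 1e-7) s_lo = s; else s_hi = s;
    }
    double s = s_lo;
    ap_dist(c1.begin(), n1.begin(), c2.begin(), n2.begin(),
            r * s, h * s, r * s, h * s, p, q);
    double da = std::sqrt((p[0] - c1[0]) * (p[0] - c1[0]) +
                          (p[1] - c1[1]) * (p[1] - c1[1]) +
                          (p[2] - c1[2]) * (p[2] - c1[2]));
    double db = std::sqrt((q[0] - c2[0]) * (q[0] - c2[0]) +
                          (q[1] - c2[1]) * (q[1] - c2[1]) +
                          (q[2] - c2[2]) * (q[2] - c2[2]));
    sep = -(1 - s) * (da + db);
    int fa = facet_code(p, c1.begin(), n1.begin(), r * s, h * s, face_frac);
    int fb = facet_code(q, c2.begin(), n2.begin(), r * s, h * s, face_frac);
    return List::create(_["separation"] = sep, _["fa"] = fa, _["fb"] = fb,
                        _["overlap"] = true,
                        _["points"] = NumericMatrix(2, 3,
                            NumericVector::create(p[0], q[0], p[1], q[1],
                                                  p[2], q[2]).begin()));
  }
  int fa = facet_code(p, c1.begin(), n1.begin(), r, h, face_frac);
  int fb = facet_code(q, c2.begin(), n2.begin(), r, h, face_frac);
  return List::create(_["separation"] = sep, _["fa"] = fa, _["fb"] = fb,
                      _["overlap"] = false,
                      _["points"] = NumericMatrix(2, 3,
                          NumericVector::create(p[0], q[0], p[1], q[1],
                                                p[2], q[2]).begin()));
}
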