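// Capsule (spherocylinder) geometry kernels: pairwise overlap relaxation and
// needle -> cell first-hit detection, both accelerated by a uniform grid.
// All coordinates are in micrometres. A cell is the set of points within
// radius R of the segment of length L centred on (x, y) with orientation
// `angle`. These loops dominate simulation cost, hence C++.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct Seg {
  double px, py;  // one endpoint
  double dx, dy;  // full segment vector (other endpoint = p + d)
};

static inline Seg cell_segment(double x, double y, double ang, double len) {
  Seg s;
  double c = std::cos(ang), sn = std::sin(ang);
  s.px = x - 0.5 * len * c;
  s.py = y - 0.5 * len * sn;
  s.dx = len * c;
  s.dy = len * sn;
  return s;
}

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

// Closest points between two segments (Ericson, Real-Time Collision
// Detection, 5.1.9). Returns squared distance; s,t in [0,1] are the
// parameters of the closest points on segments a and b. For near-parallel
// segments the closest pair is degenerate (a whole interval attains the
// minimum); the midpoint of that interval is returned so that side-by-side
// contacts produce a symmetric, torque-free correction.
static double seg_seg_closest(const Seg& a, const Seg& b,
                              double& s, double& t) {
  double rx = a.px - b.px, ry = a.py - b.py;
  double A = a.dx * a.dx + a.dy * a.dy;  // |d1|^2
  double E = b.dx * b.dx + b.dy * b.dy;  // |d2|^2
  double F = b.dx * rx + b.dy * ry;
  const double EPS = 1e-14;
  if (A <= EPS && E <= EPS) {
    s = t = 0.0;
  } else if (A <= EPS) {
    s = 0.0;
    t = clamp01(F / E);
  } else {
    double C = a.dx * rx + a.dy * ry;
    if (E <= EPS) {
      t = 0.0;
      s = clamp01(-C / A);
    } else {
      double B = a.dx * b.dx + a.dy * b.dy;
      double denom = A * E - B * B;
      if (denom > 1e-6 * A * E) {
        s = clamp01((B * F - C * E) / denom);
        t = (B * s + F) / E;
        if (t < 0.0) {
          t = 0.0;
          s = clamp01(-C / A);
        } else if (t > 1.0) {
          t = 1.0;
          s = clamp01((B - C) / A);
        }
      } else {
        // near-parallel: project b's endpoints onto a, take the midpoint of
        // the parameter interval closest to b
        double s0 = clamp01(-C / A);            // b start projected on a
        double s1 = clamp01((B - C) / A);       // b end projected on a
        s = 0.5 * (s0 + s1);
        t = clamp01((s * B + F) / E);
      }
    }
  }
  double cx = a.px + s * a.dx - (b.px + t * b.dx);
  double cy = a.py + s * a.dy - (b.py + t * b.dy);
  return cx * cx + cy * cy;
}

// Distance from point (px,py) to segment s.
static inline double point_seg_dist(double px, double py, const Seg& s) {
  double L2 = s.dx * s.dx + s.dy * s.dy;
  double t = 0.0;
  if (L2 > 1e-14)
    t = clamp01(((px - s.px) * s.dx + (py - s.py) * s.dy) / L2);
  double cx = s.px + t * s.dx - px;
  double cy = s.py + t * s.dy - py;
  return std::sqrt(cx * cx + cy * cy);
}

// ---- uniform grid over capsule AABBs -------------------------------------

typedef std::unordered_map<int64_t, std::vector<int> > Grid;

static inline int64_t bin_key(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^
         (static_cast<int64_t>(static_cast<uint32_t>(iy)));
}

// Register object i in every bin overlapped by the AABB
// [xmin,xmax] x [ymin,ymax].
static void grid_insert(Grid& g, int i, double xmin, double xmax,
                        double ymin, double ymax, double h) {
  int ix0 = (int)std::floor(xmin / h), ix1 = (int)std::floor(xmax / h);
  int iy0 = (int)std::floor(ymin / h), iy1 = (int)std::floor(ymax / h);
  for (int ix = ix0; ix <= ix1; ++ix)
    for (int iy = iy0; iy <= iy1; ++iy)
      g[bin_key(ix, iy)].push_back(i);
}

static void build_cell_grid(Grid& g, const std::vector<Seg>& segs,
                            int n, double R, double h) {
  g.clear();
  for (int i = 0; i < n; ++i) {
    const Seg& s = segs[i];
    double x0 = std::min(s.px, s.px + s.dx) - R;
    double x1 = std::max(s.px, s.px + s.dx) + R;
    double y0 = std::min(s.py, s.py + s.dy) - R;
    double y1 = std::max(s.py, s.py + s.dy) + R;
    grid_insert(g, i, x0, x1, y0, y1, h);
  }
}

// ---- overlap relaxation ---------------------------------------------------

// Collect candidate pairs (i < j) whose capsule surfaces are closer than
// `slack` via the grid. Pairs further apart cannot come into contact within
// a few damped sweeps, so the list is reused across several sweeps.
static void build_pair_list(const std::vector<double>& X,
                            const std::vector<double>& Y,
                            const std::vector<double>& A,
                            const NumericVector& len, int n, double R,
                            double grid_size, double slack,
                            std::vector<int>& pi, std::vector<int>& pj) {
  pi.clear(); pj.clear();
  std::vector<Seg> segs(n);
  for (int i = 0; i < n; ++i) segs[i] = cell_segment(X[i], Y[i], A[i], len[i]);
  Grid g;
  build_cell_grid(g, segs, n, R + 0.5 * slack, grid_size);
  std::vector<int> seen(n, -1);
  double reach = 2.0 * R + slack;
  for (int i = 0; i < n; ++i) {
    const Seg& si = segs[i];
    double x0 = std::min(si.px, si.px + si.dx) - R - 0.5 * slack;
    double x1 = std::max(si.px, si.px + si.dx) + R + 0.5 * slack;
    double y0 = std::min(si.py, si.py + si.dy) - R - 0.5 * slack;
    double y1 = std::max(si.py, si.py + si.dy) + R + 0.5 * slack;
    int ix0 = (int)std::floor(x0 / grid_size), ix1 = (int)std::floor(x1 / grid_size);
    int iy0 = (int)std::floor(y0 / grid_size), iy1 = (int)std::floor(y1 / grid_size);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        Grid::const_iterator it = g.find(bin_key(ix, iy));
        if (it == g.end()) continue;
        const std::vector<int>& members = it->second;
        for (size_t m = 0; m < members.size(); ++m) {
          int j = members[m];
          if (j <= i || seen[j] == i) continue;
          seen[j] = i;
          double s, t;
          if (seg_seg_closest(segs[i], segs[j], s, t) < reach * reach) {
            pi.push_back(i);
            pj.push_back(j);
          }
        }
      }
  }
}

// Position-based removal of pairwise capsule overlap. Each sweep visits the
// candidate pairs in a fixed order and, for any pair whose surfaces
// interpenetrate by more than `tol`, translates and rotates both cells
// apart along the contact normal (Gauss-Seidel with damping). The candidate
// list is refreshed periodically; convergence is only declared when a sweep
// over a freshly built list finds no overlap above `tol`. Lengths, volumes
// and life status are untouched.
// [[Rcpp::export]]
List cpp_relax(NumericVector x, NumericVector y, NumericVector angle,
               NumericVector len, double R, double tol, int max_iter,
               double grid_size, double damping) {
  int n = x.size();
  std::vector<double> X(x.begin(), x.end());
  std::vector<double> Y(y.begin(), y.end());
  std::vector<double> A(angle.begin(), angle.end());
  std::vector<int> pi, pj;
  const double slack = 0.8;       // um; candidate horizon beyond contact
  const int rebuild_every = 10;   // sweeps between candidate refreshes
  const double rot_gain = 0.3;    // keeps shallow-angle contacts from scissoring
  double two_r = 2.0 * R;
  double maxov = 0.0;
  int iter = 0, since_rebuild = 0;
  bool converged = (n < 2);

  if (!converged)
    build_pair_list(X, Y, A, len, n, R, grid_size, slack, pi, pj);

  while (iter < max_iter && !converged) {
    if (since_rebuild >= rebuild_every) {
      build_pair_list(X, Y, A, len, n, R, grid_size, slack, pi, pj);
      since_rebuild = 0;
    }
    ++iter;
    ++since_rebuild;
    maxov = 0.0;
    for (size_t k = 0; k < pi.size(); ++k) {
      int i = pi[k], j = pj[k];
      Seg sa = cell_segment(X[i], Y[i], A[i], len[i]);
      Seg sb = cell_segment(X[j], Y[j], A[j], len[j]);
      double s, t;
      double d2 = seg_seg_closest(sa, sb, s, t);
      double dist = std::sqrt(d2);
      double ov = two_r - dist;
      if (ov > maxov) maxov = ov;
      if (ov <= tol) continue;
      double nx, ny;
      if (dist > 1e-9) {
        double pax = sa.px + s * sa.dx, pay = sa.py + s * sa.dy;
        double pbx = sb.px + t * sb.dx, pby = sb.py + t * sb.dy;
        nx = (pax - pbx) / dist;
        ny = (pay - pby) / dist;
      } else {  // centres coincide: push perpendicular to i's axis
        nx = -std::sin(A[i]);
        ny = std::cos(A[i]);
      }
      double corr = 0.5 * damping * ov;
      double rix = sa.px + s * sa.dx - X[i];
      double riy = sa.py + s * sa.dy - Y[i];
      double rjx = sb.px + t * sb.dx - X[j];
      double rjy = sb.py + t * sb.dy - Y[j];
      X[i] += corr * nx;  Y[i] += corr * ny;
      X[j] -= corr * nx;  Y[j] -= corr * ny;
      double Ii = len[i] * len[i] / 12.0 + R * R;
      double Ij = len[j] * len[j] / 12.0 + R * R;
      A[i] += rot_gain * (rix * corr * ny - riy * corr * nx) / Ii;
      A[j] += -rot_gain * (rjx * corr * ny - rjy * corr * nx) / Ij;
    }
    if (maxov <= tol) {
      if (since_rebuild == 1) {
        converged = true;  // clean sweep over a fresh candidate list
      } else {
        since_rebuild = rebuild_every;  // verify against a fresh list
      }
    }
  }

  return List::create(_["x"] = NumericVector(X.begin(), X.end()),
                      _["y"] = NumericVector(Y.begin(), Y.end()),
                      _["angle"] = NumericVector(A.begin(), A.end()),
                      _["iterations"] = iter,
                      _["max_overlap"] = (n < 2 ? 0.0 : maxov),
                      _["converged"] = converged);
}

// Brute-force maximum pairwise surface overlap (test oracle; O(n^2)).
// [[Rcpp::export]]
double cpp_max_overlap(NumericVector x, NumericVector y, NumericVector angle,
                       NumericVector len, double R) {
  int n = x.size();
  std::vector<Seg> segs(n);
  for (int i = 0; i < n; ++i) segs[i] = cell_segment(x[i], y[i], angle[i], len[i]);
  double maxov = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s, t;
      double d = std::sqrt(seg_seg_closest(segs[i], segs[j], s, t));
      double ov = 2.0 * R - d;
      if (ov > maxov) maxov = ov;
    }
  return maxov;
}

// ---- needle hit detection -------------------------------------------------

// Entry distance of the needle ray b + t*u (t in [0, nlen]) into the capsule
// around `seg` with radius R, or -1 if it never enters. The distance from a
// point moving along a line to a convex set (the capsule) is convex in t, so
// the sub-level set {f <= 0} is an interval: locate the minimum by ternary
// search, then the first crossing by bisection.
static double needle_entry(double bx, double by, double ux, double uy,
                           double nlen, const Seg& seg, double R) {
  double f0 = point_seg_dist(bx, by, seg) - R;
  if (f0 <= 0.0) return 0.0;  // base already inside the target surface
  double lo = 0.0, hi = nlen;
  for (int k = 0; k < 60; ++k) {
    double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
    double f1 = point_seg_dist(bx + m1 * ux, by + m1 * uy, seg) - R;
    double f2 = point_seg_dist(bx + m2 * ux, by + m2 * uy, seg) - R;
    if (f1 <= f2) hi = m2; else lo = m1;
  }
  double tmin = 0.5 * (lo + hi);
  double fmin = point_seg_dist(bx + tmin * ux, by + tmin * uy, seg) - R;
  if (fmin > 0.0) return -1.0;
  // first crossing in [0, tmin]: f(0) > 0, f(tmin) <= 0
  lo = 0.0; hi = tmin;
  for (int k = 0; k < 60; ++k) {
    double mid = 0.5 * (lo + hi);
    double fm = point_seg_dist(bx + mid * ux, by + mid * uy, seg) - R;
    if (fm <= 0.0) hi = mid; else lo = mid;
  }
  return hi;
}

// For each needle, the 1-based index of the first cell whose capsule the
// needle segment enters (excluding the firer), and the entry distance along
// the needle; 0 / NA when nothing is reached. Cells are indexed by the grid.
// [[Rcpp::export]]
List cpp_resolve_hits(NumericVector bx, NumericVector by,
                      NumericVector ux, NumericVector uy,
                      double needle_len, IntegerVector firer,
                      NumericVector x, NumericVector y, NumericVector angle,
                      NumericVector len, double R, double grid_size) {
  int nn = bx.size(), nc = x.size();
  std::vector<Seg> segs(nc);
  for (int i = 0; i < nc; ++i) segs[i] = cell_segment(x[i], y[i], angle[i], len[i]);
  Grid g;
  build_cell_grid(g, segs, nc, R, grid_size);

  IntegerVector target(nn);
  NumericVector tdist(nn);
  std::vector<int> seen(nc, -1);

  for (int k = 0; k < nn; ++k) {
    double x0 = std::min(bx[k], bx[k] + needle_len * ux[k]);
    double x1 = std::max(bx[k], bx[k] + needle_len * ux[k]);
    double y0 = std::min(by[k], by[k] + needle_len * uy[k]);
    double y1 = std::max(by[k], by[k] + needle_len * uy[k]);
    int ix0 = (int)std::floor(x0 / grid_size), ix1 = (int)std::floor(x1 / grid_size);
    int iy0 = (int)std::floor(y0 / grid_size), iy1 = (int)std::floor(y1 / grid_size);
    int best = -1;
    double best_t = needle_len + 1.0;
    for (int ix = ix0; ix <= ix1; ++ix) {
      for (int iy = iy0; iy <= iy1; ++iy) {
        Grid::const_iterator it = g.find(bin_key(ix, iy));
        if (it == g.end()) continue;
        const std::vector<int>& members = it->second;
        Seg ns;  // needle as a segment, for the cheap reject below
        ns.px = bx[k]; ns.py = by[k];
        ns.dx = needle_len * ux[k]; ns.dy = needle_len * uy[k];
        for (size_t m = 0; m < members.size(); ++m) {
          int j = members[m];
          if (j == firer[k] - 1 || seen[j] == k) continue;
          seen[j] = k;
          // the needle can only enter the capsule if the segments approach
          // within R somewhere; skip the entry refinement otherwise
          double qs, qt;
          if (seg_seg_closest(ns, segs[j], qs, qt) > R * R) continue;
          double t = needle_entry(bx[k], by[k], ux[k], uy[k],
                                  needle_len, segs[j], R);
          if (t >= 0.0 && (t < best_t || (t == best_t && j < best))) {
            best_t = t;
            best = j;
          }
        }
      }
    }
    if (best >= 0) {
      target[k] = best + 1;
      tdist[k] = best_t;
    } else {
      target[k] = 0;
      tdist[k] = NA_REAL;
    }
  }
  return List::create(_["target"] = target, _["distance"] = tdist);
}
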