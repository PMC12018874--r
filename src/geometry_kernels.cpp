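#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3-d k-d tree for exact nearest-neighbour queries.
//
// Tie rule (fixed for the whole package): among equidistant candidates the
// smallest original point index wins.  Squared distances are accumulated in
// the fixed order x, y, z so the accelerated path is bit-identical to the
// O(N*M) brute force used as oracle in the tests.
// ---------------------------------------------------------------------------

class KDTree {
public:
  KDTree(const NumericMatrix& m) : pts(m), n(m.nrow()), idx(m.nrow()) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }

  // returns 0-based index of nearest point; d2out receives squared distance
  int nearest(double qx, double qy, double qz, double& d2out) const {
    double bd2 = R_PosInf;
    int bi = -1;
    double q[3] = {qx, qy, qz};
    search(0, n, 0, q, bd2, bi);
    d2out = bd2;
    return bi;
  }

  double dist2(int i, const double* q) const {
    double dx = q[0] - pts(i, 0);
    double dy = q[1] - pts(i, 1);
    double dz = q[2] - pts(i, 2);
    double s = dx * dx;
    s = s + dy * dy;
    s = s + dz * dz;
    return s;
  }

private:
  const NumericMatrix& pts;
  int n;
  std::vector<int> idx;

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    const NumericMatrix& p = pts;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&p, ax](int a, int b) { return p(a, ax) < p(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void search(int lo, int hi, int depth, const double* q,
              double& bd2, int& bi) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double d2 = dist2(i, q);
    if (d2 < bd2 || (d2 == bd2 && i < bi)) { bd2 = d2; bi = i; }
    if (hi - lo == 1) return;
    int ax = depth % 3;
    double diff = q[ax] - pts(i, ax);
    if (diff < 0) {
      search(lo, mid, depth + 1, q, bd2, bi);
      if (diff * diff <= bd2) search(mid + 1, hi, depth + 1, q, bd2, bi);
    } else {
      search(mid + 1, hi, depth + 1, q, bd2, bi);
      if (diff * diff <= bd2) search(lo, mid, depth + 1, q, bd2, bi);
    }
  }
};

// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix query, NumericMatrix ref) {
  KDTree tree(ref);
  int m = query.nrow();
  IntegerVector out(m);
  double d2;
  for (int j = 0; j < m; ++j) {
    out[j] = tree.nearest(query(j, 0), query(j, 1), query(j, 2), d2) + 1;
  }
  return out;
}

// Bidirectional local distance mapping.  For each baseline point b the
// candidate set is {forward NN of b on test} united with every test point
// whose nearest baseline point is b; the mapped point is the candidate at
// the largest distance (ties -> smallest test index).
// [[Rcpp::export]]
List cpp_bld_map(NumericMatrix base, NumericMatrix test) {
  int n = base.nrow(), m = test.nrow();
  KDTree ttree(test);
  KDTree btree(base);

  IntegerVector fwd(n);
  std::vector<double> fwd_d2(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    fwd[i] = ttree.nearest(base(i, 0), base(i, 1), base(i, 2), d2);
    fwd_d2[i] = d2;
  }

  // reverse assignment: owner of each test point among baseline points
  std::vector<int> owner(m);
  std::vector<int> head(n, -1), nxt(m, -1), tail(n, -1);
  for (int j = 0; j < m; ++j) {
    double d2;
    owner[j] = btree.nearest(test(j, 0), test(j, 1), test(j, 2), d2);
    int o = owner[j];
    if (head[o] < 0) head[o] = j; else nxt[tail[o]] = j;  // ascending j per owner
    tail[o] = j;
  }

  IntegerVector mapped(n);
  NumericVector bld(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {base(i, 0), base(i, 1), base(i, 2)};
    // walk candidates in ascending test index; strict > keeps smallest index
    int bi = -1;
    double bd2 = -1.0;
    int f = fwd[i];
    bool fdone = false;
    for (int j = head[i]; j != -1; j = nxt[j]) {
      if (!fdone && f < j) {  // interleave forward candidate at its rank
        double d2 = fwd_d2[i];
        if (d2 > bd2) { bd2 = d2; bi = f; }
        fdone = true;
      }
      if (j == f) fdone = true;
      double d2 = ttree.dist2(j, q);
      if (d2 > bd2) { bd2 = d2; bi = j; }
    }
    if (!fdone) {
      double d2 = fwd_d2[i];
      if (d2 > bd2) { bd2 = d2; bi = f; }
    }
    mapped[i] = bi + 1;
    bld[i] = std::sqrt(bd2);
  }
  return List::create(_["mapped_idx"] = mapped, _["bld_mm"] = bld,
                      _["reverse_owner"] = IntegerVector(owner.begin(), owner.end()) + 1);
}

// ---------------------------------------------------------------------------
// Planar polygon predicates (polygon given as open vertex list, implicitly
// closed).  Boundary points classify as outside.
// ---------------------------------------------------------------------------

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int n = vx.size(), m = px.size();
  LogicalVector out(m);
  const double eps = 1e-12;
  for (int k = 0; k < m; ++k) {
    double x = px[k], y = py[k];
    bool boundary = false, inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = vx[i], yi = vy[i], xj = vx[j], yj = vy[j];
      // on-segment test
      double cr = cross3(xj, yj, xi, yi, x, y);
      if (std::abs(cr) <= eps * (std::abs(xi - xj) + std::abs(yi - yj) + 1.0) &&
          x >= std::min(xi, xj) - eps && x <= std::max(xi, xj) + eps &&
          y >= std::min(yi, yj) - eps && y <= std::max(yi, yj) + eps) {
        boundary = true;
        break;
      }
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[k] = boundary ? false : inside;
  }
  return out;
}

static inline int orient_sign(double ox, double oy, double ax, double ay,
                              double bx, double by) {
  double c = cross3(ox, oy, ax, ay, bx, by);
  if (c > 0) return 1;
  if (c < 0) return -1;
  return 0;
}

static bool on_segment_collinear(double px, double py, double qx, double qy,
                                 double rx, double ry) {
  return qx <= std::max(px, rx) && qx >= std::min(px, rx) &&
         qy <= std::max(py, ry) && qy >= std::min(py, ry);
}

static bool segments_intersect(double p1x, double p1y, double p2x, double p2y,
                               double p3x, double p3y, double p4x, double p4y) {
  int o1 = orient_sign(p1x, p1y, p2x, p2y, p3x, p3y);
  int o2 = orient_sign(p1x, p1y, p2x, p2y, p4x, p4y);
  int o3 = orient_sign(p3x, p3y, p4x, p4y, p1x, p1y);
  int o4 = orient_sign(p3x, p3y, p4x, p4y, p2x, p2y);
  if (o1 != o2 && o3 != o4) return true;
  if (o1 == 0 && on_segment_collinear(p1x, p1y, p3x, p3y, p2x, p2y)) return true;
  if (o2 == 0 && on_segment_collinear(p1x, p1y, p4x, p4y, p2x, p2y)) return true;
  if (o3 == 0 && on_segment_collinear(p3x, p3y, p1x, p1y, p4x, p4y)) return true;
  if (o4 == 0 && on_segment_collinear(p3x, p3y, p2x, p2y, p4x, p4y)) return true;
  return false;
}

// A polygon is simple when no two non-adjacent edges intersect and adjacent
// edges meet only at their shared vertex.
// [[Rcpp::export]]
bool cpp_polygon_is_simple(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    if (vx[i] == vx[i2] && vy[i] == vy[i2]) return false;  // zero-length edge
  }
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      bool adjacent = (i2 == j) || (j2 == i);
      if (adjacent) {
        // shared vertex s; the other two endpoints must not straddle through s
        double sx, sy, ax, ay, bx, by;
        if (i2 == j) { sx = vx[j]; sy = vy[j]; ax = vx[i]; ay = vy[i]; bx = vx[j2]; by = vy[j2]; }
        else         { sx = vx[i]; sy = vy[i]; ax = vx[j]; ay = vy[j]; bx = vx[i2]; by = vy[i2]; }
        if (orient_sign(sx, sy, ax, ay, bx, by) == 0 &&
            ((ax - sx) * (bx - sx) + (ay - sy) * (by - sy)) > 0)
          return false;  // collinear spike folding back over itself
      } else {
        if (segments_intersect(vx[i], vy[i], vx[i2], vy[i2],
                               vx[j], vy[j], vx[j2], vy[j2]))
          return false;
      }
    }
  }
  return true;
}
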