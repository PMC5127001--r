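#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact neighbor searches on a uniform grid hash. All queries are exact
// (no approximation): candidate cells are enumerated in expanding shells
// and the search stops only once the shell lower bound exceeds the current
// k-th best distance.

namespace {

struct GridIndex3 {
  double x0, y0, z0, cs;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int> > cells;

  // exact (injective) cell key: indices are non-negative and far below
  // the packing base, so distinct cells never share a key
  long long key(int ix, int iy, int iz) const {
    const long long base = 1048583LL;
    return (static_cast<long long>(ix) * base +
            static_cast<long long>(iy)) * base +
           static_cast<long long>(iz);
  }

  void build(const NumericMatrix& pts, double cell_size) {
    cs = cell_size;
    int n = pts.nrow();
    x0 = y0 = z0 = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, pts(i, 0));
      y0 = std::min(y0, pts(i, 1));
      z0 = std::min(z0, pts(i, 2));
    }
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((pts(i, 0) - x0) / cs));
      int iy = static_cast<int>(std::floor((pts(i, 1) - y0) / cs));
      int iz = static_cast<int>(std::floor((pts(i, 2) - z0) / cs));
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
};

inline double sqdist3(const NumericMatrix& p, int i, int j) {
  double dx = p(i, 0) - p(j, 0);
  double dy = p(i, 1) - p(j, 1);
  double dz = p(i, 2) - p(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// Mean Euclidean distance from each point to its k nearest neighbors
// (excluding the point itself). Exact.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more than k points");

  // Cell size heuristic: aim for a handful of points per cell.
  double xr = 0, yr = 0, zr = 0;
  {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
           zmin = R_PosInf, zmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
      ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
      zmin = std::min(zmin, pts(i, 2)); zmax = std::max(zmax, pts(i, 2));
    }
    xr = xmax - xmin; yr = ymax - ymin; zr = zmax - zmin;
  }
  // dimension-aware cell size: degenerate extents (planar/linear clouds)
  // must not shrink the cells, or the ring search explodes
  double prod = 1.0;
  int ndim = 0;
  for (double e : {xr, yr, zr}) {
    if (e > 1e-9) { prod *= e; ++ndim; }
  }
  double cs = ndim > 0 ? std::pow(prod * (k + 1.0) / n, 1.0 / ndim) : 1.0;
  if (!(cs > 0) || !std::isfinite(cs)) cs = 1.0;

  GridIndex3 g;
  g.build(pts, cs);

  NumericVector out(n);
  std::priority_queue<double> best; // max-heap of k smallest squared dists

  for (int i = 0; i < n; ++i) {
    while (!best.empty()) best.pop();
    int cix = static_cast<int>(std::floor((pts(i, 0) - g.x0) / cs));
    int ciy = static_cast<int>(std::floor((pts(i, 1) - g.y0) / cs));
    int ciz = static_cast<int>(std::floor((pts(i, 2) - g.z0) / cs));

    for (int ring = 0;; ++ring) {
      // Lower bound on distance to any point in a cell of this ring.
      double lb = (ring - 1) * cs;
      if (static_cast<int>(best.size()) == k && ring > 0 &&
          lb * lb > best.top())
        break;
      bool any_cell = false;
      for (int dx = -ring; dx <= ring; ++dx) {
        for (int dy = -ring; dy <= ring; ++dy) {
          for (int dz = -ring; dz <= ring; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;
            auto it = g.cells.find(g.key(cix + dx, ciy + dy, ciz + dz));
            if (it == g.cells.end()) continue;
            any_cell = true;
            for (int j : it->second) {
              if (j == i) continue;
              double d2 = sqdist3(pts, i, j);
              if (static_cast<int>(best.size()) < k) {
                best.push(d2);
              } else if (d2 < best.top()) {
                best.pop();
                best.push(d2);
              }
            }
          }
        }
      }
      // Safety stop: expanded far beyond any possible occupied cell.
      if (!any_cell && ring > 1 &&
          ring * cs > std::sqrt(xr * xr + yr * yr + zr * zr) + 2 * cs &&
          static_cast<int>(best.size()) == k)
        break;
      if (ring > 100000) stop("grid search failed to terminate");
    }

    double s = 0;
    int m = static_cast<int>(best.size());
    std::priority_queue<double> tmp = best;
    while (!tmp.empty()) { s += std::sqrt(tmp.top()); tmp.pop(); }
    out[i] = s / m;
  }
  return out;
}

namespace {

struct GridIndex2 {
  double x0, y0, cs;
  std::unordered_map<long long, std::vector<int> > cells;

  long long key(int ix, int iy) const {
    return (static_cast<long long>(ix) << 32) ^
           (static_cast<long long>(iy) & 0xffffffffLL);
  }

  void build(const NumericVector& x, const NumericVector& y, double cell_size) {
    cs = cell_size;
    int n = x.size();
    x0 = y0 = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, x[i]);
      y0 = std::min(y0, y[i]);
    }
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((x[i] - x0) / cs));
      int iy = static_cast<int>(std::floor((y[i] - y0) / cs));
      cells[key(ix, iy)].push_back(i);
    }
  }

  template <typename F>
  void visit_disc(double px, double py, double radius, F f) const {
    int ix0 = static_cast<int>(std::floor((px - radius - x0) / cs));
    int ix1 = static_cast<int>(std::floor((px + radius - x0) / cs));
    int iy0 = static_cast<int>(std::floor((py - radius - y0) / cs));
    int iy1 = static_cast<int>(std::floor((py + radius - y0) / cs));
    for (int ix = ix0; ix <= ix1; ++ix) {
      for (int iy = iy0; iy <= iy1; ++iy) {
        auto it = cells.find(key(ix, iy));
        if (it == cells.end()) continue;
        for (int j : it->second) f(j);
      }
    }
  }
};

} // namespace

// Flags points that are the strictly highest within a horizontal disc of
// the given radius; exact ties are broken in favor of the lowest index.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector x, NumericVector y,
                               NumericVector z, double radius) {
  int n = x.size();
  GridIndex2 g;
  g.build(x, y, radius > 0 ? radius : 1.0);
  LogicalVector out(n);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    bool is_max = true;
    g.visit_disc(x[i], y[i], radius, [&](int j) {
      if (!is_max || j == i) return;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= r2) {
        if (z[j] > z[i] || (z[j] == z[i] && j < i)) is_max = false;
      }
    });
    out[i] = is_max;
  }
  return out;
}

// Per query position: max z, min z and point count over points within the
// horizontal disc of the given radius.
// [[Rcpp::export]]
NumericMatrix cpp_disc_minmax(NumericVector x, NumericVector y,
                              NumericVector z, NumericVector px,
                              NumericVector py, double radius) {
  int m = px.size();
  GridIndex2 g;
  g.build(x, y, radius > 0 ? radius : 1.0);
  NumericMatrix out(m, 3);
  double r2 = radius * radius;
  for (int q = 0; q < m; ++q) {
    double zmax = R_NegInf, zmin = R_PosInf;
    int cnt = 0;
    g.visit_disc(px[q], py[q], radius, [&](int j) {
      double dx = x[j] - px[q], dy = y[j] - py[q];
      if (dx * dx + dy * dy <= r2) {
        if (z[j] > zmax) zmax = z[j];
        if (z[j] < zmin) zmin = z[j];
        ++cnt;
      }
    });
    out(q, 0) = cnt > 0 ? zmax : NA_REAL;
    out(q, 1) = cnt > 0 ? zmin : NA_REAL;
    out(q, 2) = cnt;
  }
  return out;
}

// For each query (qx, qy): 1-based index of the nearest target point within
// the horizontal radius, or 0 if none.
// [[Rcpp::export]]
IntegerVector cpp_nearest_within(NumericVector qx, NumericVector qy,
                                 NumericVector tx, NumericVector ty,
                                 double radius) {
  int m = qx.size();
  IntegerVector out(m);
  if (tx.size() == 0) {
    std::fill(out.begin(), out.end(), 0);
    return out;
  }
  GridIndex2 g;
  g.build(tx, ty, radius > 0 ? radius : 1.0);
  double r2 = radius * radius;
  for (int q = 0; q < m; ++q) {
    double bd = r2;
    int bi = -1;
    g.visit_disc(qx[q], qy[q], radius, [&](int j) {
      double dx = tx[j] - qx[q], dy = ty[j] - qy[q];
      double d2 = dx * dx + dy * dy;
      if (d2 < bd || (d2 == bd && (bi < 0 || j < bi))) {
        bd = d2;
        bi = j;
      }
    });
    out[q] = bi >= 0 ? bi + 1 : 0;
  }
  return out;
}
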