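#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of open (non-barrier) subcells, 4-connectivity
// (rook moves only): a one-subcell-wide rasterized road fully severs patches.
// Returns integer labels (0 = barrier) and the subcell count of each patch.
// [[Rcpp::export]]
List label_patches_cpp(LogicalMatrix open) {
  const int nr = open.nrow(), nc = open.ncol();
  if (nr == 0 || nc == 0) stop("empty landscape");
  IntegerMatrix labels(nr, nc);
  std::vector<double> counts;
  std::vector<int> stack;
  int next_label = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!open(i, j) || labels(i, j) != 0) continue;
      ++next_label;
      double count = 0.0;
      labels(i, j) = next_label;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        count += 1.0;
        if (ci > 0 && open(ci - 1, cj) && labels(ci - 1, cj) == 0) {
          labels(ci - 1, cj) = next_label; stack.push_back(idx - 1);
        }
        if (ci < nr - 1 && open(ci + 1, cj) && labels(ci + 1, cj) == 0) {
          labels(ci + 1, cj) = next_label; stack.push_back(idx + 1);
        }
        if (cj > 0 && open(ci, cj - 1) && labels(ci, cj - 1) == 0) {
          labels(ci, cj - 1) = next_label; stack.push_back(idx - nr);
        }
        if (cj < nc - 1 && open(ci, cj + 1) && labels(ci, cj + 1) == 0) {
          labels(ci, cj + 1) = next_label; stack.push_back(idx + nr);
        }
      }
      counts.push_back(count);
    }
  }
  return List::create(_["labels"] = labels, _["counts"] = wrap(counts));
}

// Tabulate, for every reporting cell, the number of subcells belonging to
// each patch intersecting that cell (the A_ik bookkeeping, in subcell counts).
// Reporting cell id is (cell_row - 1) * n_cell_cols + cell_col, cell_row 1 at
// the matrix row-1 end (bottom of the grid).
// [[Rcpp::export]]
List cell_patch_counts_cpp(IntegerMatrix labels, int f) {
  const int nr = labels.nrow(), nc = labels.ncol();
  if (f < 1 || nr % f != 0 || nc % f != 0) stop("subcell factor inconsistent with matrix");
  const int NR = nr / f, NC = nc / f;
  std::vector<int> cell_ids, patch_ids;
  std::vector<double> cnts;
  cell_ids.reserve((size_t)NR * NC);
  patch_ids.reserve((size_t)NR * NC);
  cnts.reserve((size_t)NR * NC);
  std::map<int, double> tab;
  for (int cr = 0; cr < NR; ++cr) {
    for (int cc = 0; cc < NC; ++cc) {
      tab.clear();
      const int i0 = cr * f, j0 = cc * f;
      for (int j = j0; j < j0 + f; ++j) {
        for (int i = i0; i < i0 + f; ++i) {
          const int lab = labels(i, j);
          if (lab > 0) tab[lab] += 1.0;
        }
      }
      const int cell_id = cr * NC + cc + 1;
      for (std::map<int, double>::const_iterator it = tab.begin(); it != tab.end(); ++it) {
        cell_ids.push_back(cell_id);
        patch_ids.push_back(it->first);
        cnts.push_back(it->second);
      }
    }
  }
  return List::create(_["cell"] = wrap(cell_ids), _["patch"] = wrap(patch_ids),
                      _["count"] = wrap(cnts));
}

static inline bool on_segment(double px, double py, double x1, double y1,
                              double x2, double y2, double eps) {
  const double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  const double len = std::sqrt((x2 - x1) * (x2 - x1) + (y2 - y1) * (y2 - y1));
  if (std::fabs(cross) > eps * std::max(1.0, len)) return false;
  const double dot = (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1);
  return dot >= -eps && dot <= len * len + eps;
}

static bool point_in_ring(double px, double py, const NumericMatrix &ring, double eps) {
  const int n = ring.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double xi = ring(i, 0), yi = ring(i, 1);
    const double xj = ring(j, 0), yj = ring(j, 1);
    if (on_segment(px, py, xi, yi, xj, yj, eps)) return true; // closed rule
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// Closed-rule point-in-polygon over a union of rings (no holes): a point on
// the boundary counts as covered.
// [[Rcpp::export]]
LogicalVector points_in_rings_cpp(NumericVector px, NumericVector py, List rings) {
  const double eps = 1e-9;
  const int n = px.size(), nrings = rings.size();
  LogicalVector out(n);
  std::vector<NumericMatrix> rs;
  for (int r = 0; r < nrings; ++r) rs.push_back(as<NumericMatrix>(rings[r]));
  for (int k = 0; k < n; ++k) {
    bool in = false;
    for (int r = 0; r < nrings && !in; ++r)
      in = point_in_ring(px[k], py[k], rs[r], eps);
    out[k] = in;
  }
  return out;
}

static inline double dist_point_segment(double px, double py, double x1, double y1,
                                        double x2, double y2) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - x1) * dx + (py - y1) * dy) / l2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  const double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

// Euclidean distance from points to a polygon (union of rings); 0 inside.
// [[Rcpp::export]]
NumericVector dist_to_rings_cpp(NumericVector px, NumericVector py, List rings) {
  const double eps = 1e-9;
  const int n = px.size(), nrings = rings.size();
  NumericVector out(n);
  std::vector<NumericMatrix> rs;
  for (int r = 0; r < nrings; ++r) rs.push_back(as<NumericMatrix>(rings[r]));
  for (int k = 0; k < n; ++k) {
    bool in = false;
    for (int r = 0; r < nrings && !in; ++r)
      in = point_in_ring(px[k], py[k], rs[r], eps);
    if (in) { out[k] = 0.0; continue; }
    double d = R_PosInf;
    for (int r = 0; r < nrings; ++r) {
      const NumericMatrix &ring = rs[r];
      const int m = ring.nrow();
      for (int i = 0, j = m - 1; i < m; j = i++) {
        const double dd = dist_point_segment(px[k], py[k], ring(j, 0), ring(j, 1),
                                             ring(i, 0), ring(i, 1));
        if (dd < d) d = dd;
      }
    }
    out[k] = d;
  }
  return out;
}

// Supercover traversal (Amanatides & Woo): every grid cell a segment passes
// through, clipped to the grid extent. Returns 1-based column-major matrix
// indices for a matrix with n_rows rows (row 1 at y = origin_y).
// [[Rcpp::export]]
IntegerVector supercover_indices_cpp(double x0, double y0, double x1, double y1,
                                     double ox, double oy, double cs,
                                     int n_rows, int n_cols) {
  std::vector<int> out;
  const double xmax = ox + n_cols * cs, ymax = oy + n_rows * cs;
  // Liang-Barsky clip of the segment to the grid rectangle
  double t0 = 0.0, t1 = 1.0;
  const double dx = x1 - x0, dy = y1 - y0;
  const double p[4] = { -dx, dx, -dy, dy };
  const double q[4] = { x0 - ox, xmax - x0, y0 - oy, ymax - y0 };
  bool ok = true;
  for (int i = 0; i < 4 && ok; ++i) {
    if (p[i] == 0.0) { if (q[i] < 0.0) ok = false; }
    else {
      const double r = q[i] / p[i];
      if (p[i] < 0.0) { if (r > t1) ok = false; else if (r > t0) t0 = r; }
      else            { if (r < t0) ok = false; else if (r < t1) t1 = r; }
    }
  }
  if (!ok) return IntegerVector(0);
  const double sx = x0 + t0 * dx, sy = y0 + t0 * dy;
  const double ex = x0 + t1 * dx, ey = y0 + t1 * dy;
  int ci = (int)std::floor((sx - ox) / cs);
  int cj = (int)std::floor((sy - oy) / cs);
  int ei = (int)std::floor((ex - ox) / cs);
  int ej = (int)std::floor((ey - oy) / cs);
  if (ci < 0) ci = 0; if (ci >= n_cols) ci = n_cols - 1;
  if (cj < 0) cj = 0; if (cj >= n_rows) cj = n_rows - 1;
  if (ei < 0) ei = 0; if (ei >= n_cols) ei = n_cols - 1;
  if (ej < 0) ej = 0; if (ej >= n_rows) ej = n_rows - 1;
  const int stepi = (dx > 0) ? 1 : ((dx < 0) ? -1 : 0);
  const int stepj = (dy > 0) ? 1 : ((dy < 0) ? -1 : 0);
  double tMaxX, tMaxY, tDeltaX, tDeltaY;
  if (stepi != 0) {
    const double nextx = ox + (ci + (stepi > 0 ? 1 : 0)) * cs;
    tMaxX = (nextx - sx) / dx;
    tDeltaX = cs / std::fabs(dx);
  } else { tMaxX = R_PosInf; tDeltaX = R_PosInf; }
  if (stepj != 0) {
    const double nexty = oy + (cj + (stepj > 0 ? 1 : 0)) * cs;
    tMaxY = (nexty - sy) / dy;
    tDeltaY = cs / std::fabs(dy);
  } else { tMaxY = R_PosInf; tDeltaY = R_PosInf; }
  const int guard = 2 * (n_rows + n_cols) + 4;
  int steps = 0;
  while (true) {
    out.push_back(ci * n_rows + cj + 1); // column-major index, 1-based
    if ((ci == ei && cj == ej) || ++steps > guard) break;
    if (tMaxX < tMaxY) { ci += stepi; tMaxX += tDeltaX; }
    else               { cj += stepj; tMaxY += tDeltaY; }
    if (ci < 0 || ci >= n_cols || cj < 0 || cj >= n_rows) break;
  }
  return wrap(out);
}
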