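#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets; 4-connectivity uses the first four entries.
static const int DR[8] = { -1, 0, 0, 1, -1, -1, 1, 1 };
static const int DC[8] = { 0, -1, 1, 0, -1, 1, -1, 1 };

// Connected-component labelling with labels assigned in row-major
// first-encounter order (deterministic for a given mask).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        const int id = stack.back();
        stack.pop_back();
        const int rr = id / nc, cc = id % nc;
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

struct FloodEntry {
  double priority;     // distance-map value: larger floods first
  long long order;     // FIFO tie-break for determinism
  int r, c, label;
};
struct FloodCmp {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;
  }
};

// Marker-controlled flooding of the negated distance map: every masked
// pixel is assigned to exactly one marker, growing from high distance
// values downward (watershed without watershed lines).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_flood(const NumericMatrix &dist,
                                  const IntegerMatrix &markers,
                                  const LogicalMatrix &mask,
                                  int connectivity) {
  const int nr = dist.nrow(), nc = dist.ncol();
  const int nn = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long long order = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push(FloodEntry{ dist(r, c), order++, r, c, markers(r, c) });
      }
  while (!pq.empty()) {
    const FloodEntry e = pq.top();
    pq.pop();
    for (int k = 0; k < nn; ++k) {
      const int r2 = e.r + DR[k], c2 = e.c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = e.label;
      pq.push(FloodEntry{ dist(r2, c2), order++, r2, c2, e.label });
    }
  }
  return lab;
}

// Even-odd scanline fill of one or more rings against pixel centers.
// Pixel (r, c) has center (c + 0.5, r + 0.5); a center lying exactly on
// a crossing is counted as inside. Multiple rings give even-odd holes.
// [[Rcpp::export]]
LogicalMatrix cpp_polygon_fill(const List &rings, int nr, int nc) {
  LogicalMatrix out(nr, nc);
  const double eps = 1e-9;
  std::vector<double> xs;
  for (int r = 0; r < nr; ++r) {
    const double yc = r + 0.5;
    xs.clear();
    for (int g = 0; g < rings.size(); ++g) {
      NumericMatrix ring = rings[g];
      const int n = ring.nrow();
      for (int i = 0; i < n; ++i) {
        const int j = (i + 1) % n;
        const double y1 = ring(i, 1), y2 = ring(j, 1);
        if ((y1 <= yc) == (y2 <= yc)) continue;  // no crossing
        const double x1 = ring(i, 0), x2 = ring(j, 0);
        xs.push_back(x1 + (yc - y1) * (x2 - x1) / (y2 - y1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c1 = (int)std::ceil(xs[k] - 0.5 - eps);
      int c2 = (int)std::floor(xs[k + 1] - 0.5 + eps);
      if (c1 < 0) c1 = 0;
      if (c2 >= nc) c2 = nc - 1;
      for (int c = c1; c <= c2; ++c) out(r, c) = true;
    }
  }
  return out;
}

// Crack-following trace of the outer boundary of the 4-connected
// foreground component containing the first (row-major) true pixel.
// Returns polygon vertices on pixel corners, (x, y) with y downward,
// so that even-odd center fill reproduces the component exactly
// (holes, if any, are filled).
// [[Rcpp::export]]
NumericMatrix cpp_trace_outer(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  int r0 = -1, c0 = -1;
  for (int r = 0; r < nr && r0 < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) { r0 = r; c0 = c; break; }
  if (r0 < 0) return NumericMatrix(0, 2);

  auto fg = [&](int r, int c) -> bool {
    return r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c);
  };
  // directions: 0 = E(+x), 1 = S(+y), 2 = W(-x), 3 = N(-y); y downward.
  const int DX[4] = { 1, 0, -1, 0 };
  const int DY[4] = { 0, 1, 0, -1 };
  // pixels adjacent to the crack ahead of corner (x, y): {left, right}
  // relative to travel direction, foreground kept on the right.
  auto aheadLeft = [&](int x, int y, int d) -> bool {
    switch (d) {
      case 0: return fg(y - 1, x);
      case 1: return fg(y, x);
      case 2: return fg(y, x - 1);
      default: return fg(y - 1, x - 1);
    }
  };
  auto aheadRight = [&](int x, int y, int d) -> bool {
    switch (d) {
      case 0: return fg(y, x);
      case 1: return fg(y, x - 1);
      case 2: return fg(y - 1, x - 1);
      default: return fg(y - 1, x);
    }
  };
  std::vector<double> vx, vy;
  int x = c0, y = r0, d = 0;
  long long guard = 0;
  const long long maxSteps = 8LL * (nr + 2) * (nc + 2) + 16;
  // One step: turn if the crack ahead is not a boundary crack (recording
  // the corner), then advance one corner. The walk's state (corner,
  // direction) identifies the directed boundary crack about to be
  // traversed, so the state reached after the first step recurs exactly
  // when the boundary cycle closes.
  auto step = [&]() {
    if (aheadLeft(x, y, d)) {
      d = (d + 3) % 4;           // turn left
      vx.push_back(x); vy.push_back(y);
    } else if (!aheadRight(x, y, d)) {
      d = (d + 1) % 4;           // turn right
      vx.push_back(x); vy.push_back(y);
    }
    x += DX[d];
    y += DY[d];
  };
  step();
  const int sx = x, sy = y, sd = d;
  do {
    step();
    if (++guard > maxSteps) stop("boundary trace failed to close");
  } while (!(x == sx && y == sy && d == sd));
  // rotate so vertices are in visit order starting at the start corner
  NumericMatrix out(vx.size(), 2);
  for (size_t i = 0; i < vx.size(); ++i) {
    out(i, 0) = vx[i];
    out(i, 1) = vy[i];
  }
  return out;
}

// Pairwise overlap pixel counts between two label images of equal size.
// Returns a 3-column matrix (gt_label, pred_label, n_pixels) over pairs
// with at least one shared pixel, ordered by (gt, pred).
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_counts(const IntegerMatrix &gt,
                                 const IntegerMatrix &pred) {
  if (gt.nrow() != pred.nrow() || gt.ncol() != pred.ncol())
    stop("label images must have identical dimensions");
  std::map<std::pair<int, int>, int> cnt;
  const int n = gt.size();
  for (int i = 0; i < n; ++i) {
    const int g = gt[i], p = pred[i];
    if (g > 0 && p > 0) ++cnt[std::make_pair(g, p)];
  }
  IntegerMatrix out(cnt.size(), 3);
  int i = 0;
  for (auto &kv : cnt) {
    out(i, 0) = kv.first.first;
    out(i, 1) = kv.first.second;
    out(i, 2) = kv.second;
    ++i;
  }
  return out;
}
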