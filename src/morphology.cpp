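// Low-level morphological primitives backing the nucleolus detector:
// grayscale reconstruction by dilation (Vincent's hybrid algorithm),
// plateau-aware regional maxima, 8-connected labeling, and a
// marker-controlled watershed implemented as a priority flood.
// All operate on column-major R matrices; 8-connectivity throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// Grayscale reconstruction of `mask` from `marker` by dilation.
// Requires marker <= mask elementwise (enforced by clamping).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J(clone(marker));
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) J[i] = mask[i];

  // raster scan: neighbours already visited in raster order
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double v = J(y, x);
      for (int k = 0; k < 8; ++k) {
        int qx = x + DX[k], qy = y + DY[k];
        if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
        if (qx > x || (qx == x && qy >= y)) continue; // only N+
        if (J(qy, qx) > v) v = J(qy, qx);
      }
      if (v > mask(y, x)) v = mask(y, x);
      J(y, x) = v;
    }
  }

  // anti-raster scan + queue initialisation
  std::queue<int> fifo;
  for (int x = nc - 1; x >= 0; --x) {
    for (int y = nr - 1; y >= 0; --y) {
      double v = J(y, x);
      for (int k = 0; k < 8; ++k) {
        int qx = x + DX[k], qy = y + DY[k];
        if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
        if (qx < x || (qx == x && qy <= y)) continue; // only N-
        if (J(qy, qx) > v) v = J(qy, qx);
      }
      if (v > mask(y, x)) v = mask(y, x);
      J(y, x) = v;
      for (int k = 0; k < 8; ++k) {
        int qx = x + DX[k], qy = y + DY[k];
        if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
        if (qx < x || (qx == x && qy <= y)) continue;
        if (J(qy, qx) < J(y, x) && J(qy, qx) < mask(qy, qx)) {
          fifo.push(y + x * nr);
          break;
        }
      }
    }
  }

  // queue propagation
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int py = p % nr, px = p / nr;
    double vp = J(py, px);
    for (int k = 0; k < 8; ++k) {
      int qx = px + DX[k], qy = py + DY[k];
      if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
      if (J(qy, qx) < vp && mask(qy, qx) != J(qy, qx)) {
        double nv = vp < mask(qy, qx) ? vp : mask(qy, qx);
        if (nv > J(qy, qx)) {
          J(qy, qx) = nv;
          fifo.push(qy + qx * nr);
        }
      }
    }
  }
  return J;
}

// Regional maxima: plateaus of constant value with no strictly greater
// 8-neighbour. Exact (no epsilon), via plateau flood fill.
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> visited(nr * nc, 0);
  std::vector<int> plateau;
  std::queue<int> q;

  for (int start = 0; start < nr * nc; ++start) {
    if (visited[start]) continue;
    double v = img[start];
    bool isMax = true;
    plateau.clear();
    visited[start] = 1;
    q.push(start);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      plateau.push_back(p);
      int py = p % nr, px = p / nr;
      for (int k = 0; k < 8; ++k) {
        int qx = px + DX[k], qy = py + DY[k];
        if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
        int idx = qy + qx * nr;
        double w = img[idx];
        if (w > v) isMax = false;
        else if (w == v && !visited[idx]) {
          visited[idx] = 1;
          q.push(idx);
        }
      }
    }
    if (isMax)
      for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = true;
  }
  return out;
}

// 8-connected components of a logical mask, labelled 1..L in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < nr * nc; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int py = p % nr, px = p / nr;
      for (int k = 0; k < 8; ++k) {
        int qx = px + DX[k], qy = py + DY[k];
        if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
        int idx = qy + qx * nr;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return lab;
}

struct FloodNode {
  double value;
  long age;
  int index;
};
struct FloodCmp {
  bool operator()(const FloodNode& a, const FloodNode& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.age > b.age;                             // FIFO tie-break
  }
};

// Marker-controlled watershed: flood `priority` (lower floods first) from
// labelled markers, restricted to `mask`. Every reachable mask pixel gets
// the label of the marker that reaches it first; no explicit ridge lines.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_flood(NumericMatrix priority, IntegerMatrix markers,
                                  LogicalMatrix mask) {
  int nr = priority.nrow(), nc = priority.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("priority, markers and mask must have identical dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> heap;
  long age = 0;
  for (int i = 0; i < nr * nc; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      heap.push({priority[i], age++, i});
    }
  }
  while (!heap.empty()) {
    FloodNode nd = heap.top(); heap.pop();
    int p = nd.index;
    int py = p % nr, px = p / nr;
    for (int k = 0; k < 8; ++k) {
      int qx = px + DX[k], qy = py + DY[k];
      if (qx < 0 || qx >= nc || qy < 0 || qy >= nr) continue;
      int idx = qy + qx * nr;
      if (!mask[idx] || lab[idx] != 0) continue;
      lab[idx] = lab[p];
      heap.push({priority[idx], age++, idx});
    }
  }
  return lab;
}
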