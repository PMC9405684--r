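#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour bit layout for the 8-neighbourhood of p (x right, y down):
//   bit 0: E, 1: NE, 2: N, 3: NW, 4: W, 5: SW, 6: S, 7: SE
static const int NB_DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1 };
static const int NB_DC[8] = { 1,  1,  0, -1, -1, -1,  0,  1 };

// Number of 8-connected components of set bits within the 8-neighbourhood.
static int fg_components(int mask) {
  if (mask == 0) return 0;
  // adjacency among the 8 neighbour positions (ring coords)
  int comp = 0;
  int seen = 0;
  for (int s = 0; s < 8; ++s) {
    if (!((mask >> s) & 1) || ((seen >> s) & 1)) continue;
    ++comp;
    // BFS over neighbour positions that are 8-adjacent to each other
    std::vector<int> stack(1, s);
    seen |= (1 << s);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < 8; ++v) {
        if (!((mask >> v) & 1) || ((seen >> v) & 1)) continue;
        int dr = NB_DR[u] - NB_DR[v], dc = NB_DC[u] - NB_DC[v];
        if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
          seen |= (1 << v);
          stack.push_back(v);
        }
      }
    }
  }
  return comp;
}

// Number of 4-connected background components in the 8-neighbourhood that are
// 4-adjacent to the centre pixel.
static int bg_components(int mask) {
  int bg = (~mask) & 0xFF;
  if (bg == 0) return 0;
  int comp = 0;
  int seen = 0;
  for (int s = 0; s < 8; s += 2) { // only 4-neighbours (E,N,W,S) can seed
    if (!((bg >> s) & 1) || ((seen >> s) & 1)) continue;
    ++comp;
    std::vector<int> stack(1, s);
    seen |= (1 << s);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < 8; ++v) {
        if (!((bg >> v) & 1) || ((seen >> v) & 1)) continue;
        int dr = NB_DR[u] - NB_DR[v], dc = NB_DC[u] - NB_DC[v];
        if (std::abs(dr) + std::abs(dc) == 1) { // 4-adjacency in the ring
          seen |= (1 << v);
          stack.push_back(v);
        }
      }
    }
  }
  return comp;
}

struct SimpleTables {
  bool simple[256];
  int ncount[256];
  SimpleTables() {
    for (int m = 0; m < 256; ++m) {
      simple[m] = (fg_components(m) == 1) && (bg_components(m) == 1);
      int c = 0;
      for (int b = 0; b < 8; ++b) c += (m >> b) & 1;
      ncount[m] = c;
    }
  }
};
static SimpleTables TAB;

static inline int neighbour_mask(const std::vector<uint8_t>& img,
                                 int nr, int nc, int r, int c) {
  int mask = 0;
  for (int b = 0; b < 8; ++b) {
    int rr = r + NB_DR[b], cc = c + NB_DC[b];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img[(size_t)cc * nr + rr])
      mask |= (1 << b);
  }
  return mask;
}

// Topology-preserving thinning. Sequential deletion of simple, non-endpoint
// border pixels in four directional subiterations (N, S, W, E borders) until
// stable. Sequential update guarantees every deleted pixel is simple at the
// moment of deletion, so 8-connected components and holes are preserved.
// [[Rcpp::export]]
LogicalMatrix cpp_thin_mask(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<uint8_t> img((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img[(size_t)c * nr + r] = mask(r, c) ? 1 : 0;

  // border directions: bit index of the neighbour that must be background
  // N border -> N neighbour (bit 2) bg; S -> bit 6; W -> bit 4; E -> bit 0
  const int dirs[4] = { 2, 6, 4, 0 };
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      int bit = dirs[d];
      // phase 1: freeze the d-border pixels of the current image
      cand.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          size_t idx = (size_t)c * nr + r;
          if (!img[idx]) continue;
          int m = neighbour_mask(img, nr, nc, r, c);
          if ((m >> bit) & 1) continue;          // not a border pixel for d
          if (TAB.ncount[m] < 2) continue;       // keep endpoints
          if (!TAB.simple[m]) continue;
          cand.push_back((int)idx);
        }
      }
      // phase 2: delete sequentially, re-checking against the updated image
      for (size_t k = 0; k < cand.size(); ++k) {
        int idx = cand[k];
        int r = idx % nr, c = idx / nr;
        int m = neighbour_mask(img, nr, nc, r, c);
        if (TAB.ncount[m] < 2 || !TAB.simple[m]) continue;
        img[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img[(size_t)c * nr + r] != 0;
  return out;
}

// 8-neighbour foreground count per pixel of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_count(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int n = 0;
      for (int b = 0; b < 8; ++b) {
        int rr = r + NB_DR[b], cc = c + NB_DC[b];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc)) ++n;
      }
      out(r, c) = n;
    }
  }
  return out;
}

// Connected-component labelling (connectivity 4 or 8), BFS, labels in raster
// discovery order starting at 1; background = 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 4) ? 4 : 8;
  const int DR4[4] = { 0, -1, 0, 1 }, DC4[4] = { 1, 0, -1, 0 };
  int next = 0;
  std::vector<std::pair<int,int> > queue;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      queue.clear();
      queue.push_back(std::make_pair(r, c));
      while (!queue.empty()) {
        std::pair<int,int> p = queue.back(); queue.pop_back();
        for (int b = 0; b < nnb; ++b) {
          int rr = p.first  + (connectivity == 4 ? DR4[b] : NB_DR[b]);
          int cc = p.second + (connectivity == 4 ? DC4[b] : NB_DC[b]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!mask(rr, cc) || lab(rr, cc)) continue;
          lab(rr, cc) = next;
          queue.push_back(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}

// Dijkstra shortest path on the 8-connected pixel grid.
// Edge weight u-v = 0.5*(cost[u]+cost[v]) * steplen (1 orthogonal, sqrt2
// diagonal), a symmetric weighting so path cost is identical in both
// directions. Neighbours expanded in the fixed order E,NE,N,NW,W,SW,S,SE;
// priority-queue ties broken by linear pixel index for bit-reproducibility.
// r0,c0,r1,c1 are 0-based; rows/cols outside [rmin,rmax]x[cmin,cmax] are
// excluded (the search window). Returns list(path = k x 2 matrix of (row,col),
// cost = total path cost).
// [[Rcpp::export]]
List cpp_dijkstra(NumericMatrix cost, int r0, int c0, int r1, int c1,
                  int rmin, int rmax, int cmin, int cmax) {
  int nr = cost.nrow(), nc = cost.ncol();
  const double SQRT2 = std::sqrt(2.0);
  size_t n = (size_t)nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> prev(n, -1);
  std::vector<uint8_t> done(n, 0);
  typedef std::pair<double, int> QE; // (dist, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  int s = c0 * nr + r0, t = c1 * nr + r1;
  dist[s] = 0.0;
  pq.push(std::make_pair(0.0, s));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == t) break;
    int r = u % nr, c = u / nr;
    for (int b = 0; b < 8; ++b) {
      int rr = r + NB_DR[b], cc = c + NB_DC[b];
      if (rr < rmin || rr > rmax || cc < cmin || cc > cmax) continue;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = cc * nr + rr;
      if (done[v]) continue;
      double step = (NB_DR[b] != 0 && NB_DC[b] != 0) ? SQRT2 : 1.0;
      double w = 0.5 * (cost(r, c) + cost(rr, cc)) * step;
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        prev[v] = u;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  if (!R_FINITE(dist[t]))
    return List::create(_["path"] = R_NilValue, _["cost"] = R_PosInf);
  std::vector<int> chain;
  for (int u = t; u != -1; u = prev[u]) chain.push_back(u);
  int k = (int)chain.size();
  IntegerMatrix path(k, 2);
  for (int i = 0; i < k; ++i) {
    int u = chain[k - 1 - i];
    path(i, 0) = u % nr;
    path(i, 1) = u / nr;
  }
  return List::create(_["path"] = path, _["cost"] = dist[t]);
}
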