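#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary mask (union-find).
// Input: logical/integer matrix, non-zero = foreground.
// Output: integer matrix; background 0, components labelled 1..K in
// first-encounter (column-major) order.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_cc8")]]
IntegerMatrix label_cc8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background sentinel

  // first pass: provisional labels, merging over the 4 already-visited
  // 8-neighbours (N, W, NW, SW in column-major traversal)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        int l = (int)parent.size();
        parent.push_back(l);
        lab(r, c) = l;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // second pass: flatten and renumber 1..K in order of first appearance
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

// Zhang-Suen thinning: iteratively peels boundary pixels of a binary mask
// until only an 8-connected unit-width skeleton remains. Endpoints and
// curve interiors are deletion-stable, so a 1-px curve passes unchanged.

// [[Rcpp::export(name = ".thin_zhang_suen")]]
LogicalMatrix thin_zhang_suen(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<std::pair<int, int> > kill;
  bool changed = true;

  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours P2..P9 clockwise from north; off-image = 0
          int p[8];
          int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
          int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
          for (int k = 0; k < 8; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc)) ? 1 : 0;
          }
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue; // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue; // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue; // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue; // P2*P6*P8
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
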