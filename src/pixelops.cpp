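#include <Rcpp.h>
using namespace Rcpp;

// Pixel-level primitives used by the simulator and the segmenter.
// All matrices are row/col indexed (R storage, column-major); labels use
// 0 for background.

// Discrete Voronoi labelling: for every pixel, the index of the nearest
// seed (Euclidean). Seeds are hashed into a coarse bucket grid and searched
// in expanding Chebyshev rings; a ring at index k holds only seeds at least
// (k-1)*bucket pixels away, which bounds the search.
// [[Rcpp::export(name = ".nearest_seed_label")]]
IntegerMatrix nearest_seed_label(int H, int W,
                                 NumericVector seed_r, NumericVector seed_c) {
  int n = seed_r.size();
  IntegerMatrix lab(H, W);
  double bucket = std::max(4.0, std::sqrt((double)H * W / std::max(1, n)));
  int nbr = (int)std::ceil(H / bucket), nbc = (int)std::ceil(W / bucket);
  std::vector<std::vector<int> > cells(nbr * nbc);
  for (int k = 0; k < n; ++k) {
    int bi = std::min(nbr - 1, std::max(0, (int)((seed_r[k] - 1) / bucket)));
    int bj = std::min(nbc - 1, std::max(0, (int)((seed_c[k] - 1) / bucket)));
    cells[bi * nbc + bj].push_back(k);
  }
  int max_ring = std::max(nbr, nbc);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int bi = std::min(nbr - 1, (int)(r / bucket));
      int bj = std::min(nbc - 1, (int)(c / bucket));
      double best = R_PosInf;
      int who = 0;
      for (int ring = 0; ring <= max_ring; ++ring) {
        if (best < R_PosInf && (double)(ring - 1) * bucket > std::sqrt(best))
          break;
        for (int di = -ring; di <= ring; ++di) {
          int i = bi + di;
          if (i < 0 || i >= nbr) continue;
          for (int dj = -ring; dj <= ring; ++dj) {
            if (std::max(std::abs(di), std::abs(dj)) != ring) continue;
            int j = bj + dj;
            if (j < 0 || j >= nbc) continue;
            const std::vector<int> &cell = cells[i * nbc + j];
            for (size_t q = 0; q < cell.size(); ++q) {
              int k = cell[q];
              double dr = (r + 1) - seed_r[k];
              double dc = (c + 1) - seed_c[k];
              double d = dr * dr + dc * dc;
              if (d < best) { best = d; who = k + 1; }
            }
          }
        }
      }
      lab(r, c) = who;
    }
  }
  return lab;
}

// Two-pass connected component labelling (4-connectivity) with union-find.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  // find with path compression
  struct UF {
    std::vector<int> &p;
    UF(std::vector<int> &p_) : p(p_) {}
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) {
      a = find(a); b = find(b);
      if (a != b) p[std::max(a, b)] = std::min(a, b);
    }
  } uf(parent);
  int next = 1;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int lf = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      if (up == 0 && lf == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else if (up != 0 && lf != 0) {
        lab(r, c) = std::min(up, lf);
        uf.unite(up, lf);
      } else {
        lab(r, c) = std::max(up, lf);
      }
    }
  }
  // second pass: resolve and compact labels
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c)) {
        int root = uf.find(lab(r, c));
        if (!remap[root]) remap[root] = ++out;
        lab(r, c) = remap[root];
      }
  return lab;
}

// Constrained label growth: unlabelled pixels inside `allowed` adopt the
// smallest 4-neighbour label; synchronous sweeps so results are independent
// of scan order.
// [[Rcpp::export(name = ".grow_labels")]]
IntegerMatrix grow_labels(IntegerMatrix labels, LogicalMatrix allowed,
                          int iters) {
  int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix cur = clone(labels);
  for (int it = 0; it < iters; ++it) {
    IntegerMatrix nxt = clone(cur);
    bool changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (cur(r, c) != 0 || !allowed(r, c)) continue;
        int best = 0;
        if (r > 0     && cur(r - 1, c)) best = cur(r - 1, c);
        if (c > 0     && cur(r, c - 1) && (best == 0 || cur(r, c - 1) < best)) best = cur(r, c - 1);
        if (r < H - 1 && cur(r + 1, c) && (best == 0 || cur(r + 1, c) < best)) best = cur(r + 1, c);
        if (c < W - 1 && cur(r, c + 1) && (best == 0 || cur(r, c + 1) < best)) best = cur(r, c + 1);
        if (best) { nxt(r, c) = best; changed = true; }
      }
    }
    cur = nxt;
    if (!changed) break;
  }
  return cur;
}

// Morphological peeling: remove `iters` boundary layers from every labelled
// region. A pixel survives a pass when every neighbour (4- or 8-) is in
// bounds and carries the same label. Out-of-frame counts as background, so
// regions also erode away from the image border.
// [[Rcpp::export(name = ".peel_labels")]]
IntegerMatrix peel_labels(IntegerMatrix labels, int iters, bool conn8) {
  int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix cur = clone(labels);
  for (int it = 0; it < iters; ++it) {
    IntegerMatrix nxt = clone(cur);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int v = cur(r, c);
        if (!v) continue;
        bool keep =
          r > 0 && cur(r - 1, c) == v && r < H - 1 && cur(r + 1, c) == v &&
          c > 0 && cur(r, c - 1) == v && c < W - 1 && cur(r, c + 1) == v;
        if (keep && conn8) {
          keep = cur(r - 1, c - 1) == v && cur(r - 1, c + 1) == v &&
                 cur(r + 1, c - 1) == v && cur(r + 1, c + 1) == v;
        }
        if (!keep) nxt(r, c) = 0;
      }
    }
    cur = nxt;
  }
  return cur;
}
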