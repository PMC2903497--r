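#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path halving; roots are the smallest provisional label
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (a < b) parent[b] = a; else parent[a] = b;
}

// Two-pass connected-component labelling of a logical matrix.
// Labels are contiguous 1..K in order of first appearance (column-major scan).
// Returns the label matrix plus per-object area and bounding box
// (1-based, inclusive: row_min, row_max, col_min, col_max).
// [[Rcpp::export(name = ".cc_label")]]
List cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> parent(1, 0);
  int next_label = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = labels(r - 1, c);
      if (c > 0) {
        if (mask(r, c - 1)) neigh[nn++] = labels(r, c - 1);
        if (connectivity == 8) {
          if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = labels(r - 1, c - 1);
          if (r + 1 < nr && mask(r + 1, c - 1)) neigh[nn++] = labels(r + 1, c - 1);
        }
      }
      for (int i = 0; i < nn; ++i)
        if (best == 0 || neigh[i] < best) best = neigh[i];
      if (best == 0) {
        parent.push_back(next_label);
        labels(r, c) = next_label++;
      } else {
        labels(r, c) = best;
        for (int i = 0; i < nn; ++i) uf_union(parent, best, neigh[i]);
      }
    }
  }

  // resolve equivalences and renumber in order of first appearance
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lab = labels(r, c);
      if (lab == 0) continue;
      int root = uf_find(parent, lab);
      if (remap[root] == 0) remap[root] = ++k;
      labels(r, c) = remap[root];
    }
  }

  IntegerVector area(k);
  IntegerVector rmin(k), rmax(k), cmin(k), cmax(k);
  for (int i = 0; i < k; ++i) { rmin[i] = nr + 1; cmin[i] = nc + 1; rmax[i] = 0; cmax[i] = 0; }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lab = labels(r, c);
      if (lab == 0) continue;
      int i = lab - 1;
      area[i]++;
      if (r + 1 < rmin[i]) rmin[i] = r + 1;
      if (r + 1 > rmax[i]) rmax[i] = r + 1;
      if (c + 1 < cmin[i]) cmin[i] = c + 1;
      if (c + 1 > cmax[i]) cmax[i] = c + 1;
    }
  }

  return List::create(_["labels"] = labels, _["area"] = area,
                      _["row_min"] = rmin, _["row_max"] = rmax,
                      _["col_min"] = cmin, _["col_max"] = cmax);
}

// 2-d median filter with replicated borders; used on a coarse grid for
// robust illumination estimation, so brute force per pixel is fine
// [[Rcpp::export(name = ".median_filter")]]
NumericMatrix median_filter(NumericMatrix m, int window) {
  if (window < 1 || window % 2 == 0) stop("window must be odd and positive");
  const int nr = m.nrow(), nc = m.ncol(), r = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -r; dj <= r; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -r; di <= r; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(m(ci, cj));
        }
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
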