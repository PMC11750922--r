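#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// mask is an R logical matrix (column-major); labels are 1..K in
// first-encounter order (column-major scan), background = 0.
// eight = true uses 8-connectivity (diagonals connect).

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, bool eight) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != TRUE) continue;
      int lup = (r > 0) ? lab(r - 1, c) : 0;
      int llf = (c > 0) ? lab(r, c - 1) : 0;
      int lul = (eight && r > 0 && c > 0) ? lab(r - 1, c - 1) : 0;
      int ldl = (eight && r + 1 < nr && c > 0) ? lab(r + 1, c - 1) : 0;
      int lmin = 0;
      int nb[4] = {lup, llf, lul, ldl};
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (lmin == 0 || nb[k] < lmin)) lmin = nb[k];
      if (lmin == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0 && nb[k] != lmin) uf_union(parent, nb[k], lmin);
      }
    }
  }

  // flatten and relabel compactly in first-encounter order
  std::vector<int> remap(next, 0);
  int k2 = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++k2;
      lab(r, c) = remap[root];
    }
  }
  lab.attr("n_components") = k2;
  return lab;
}

// Per-component pixel count, centroid and bounding box (0-based pixel
// coordinates, row-major origin top-left), plus border-touch flags for a
// given rectangle of lateral columns [c0, c1) in 0-based coords.
// [[Rcpp::export]]
List cc_stats(IntegerMatrix lab, int ncomp, int c0, int c1) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector npix(ncomp), sr(ncomp), sc(ncomp);
  IntegerVector rmin(ncomp, nr), rmax(ncomp, -1), cmin(ncomp, nc), cmax(ncomp, -1);
  LogicalVector edge(ncomp, false);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int i = l - 1;
      npix[i] += 1;
      sr[i] += r;
      sc[i] += c;
      if (r < rmin[i]) rmin[i] = r;
      if (r > rmax[i]) rmax[i] = r;
      if (c < cmin[i]) cmin[i] = c;
      if (c > cmax[i]) cmax[i] = c;
      if (c == c0 || c == c1 - 1) edge[i] = true;
    }
  }
  for (int i = 0; i < ncomp; ++i) {
    if (npix[i] > 0) {
      sr[i] /= npix[i];
      sc[i] /= npix[i];
    }
  }
  return List::create(
    _["n_pixels"] = npix, _["centroid_row"] = sr, _["centroid_col"] = sc,
    _["row_min"] = rmin, _["row_max"] = rmax,
    _["col_min"] = cmin, _["col_max"] = cmax,
    _["touches_edge"] = edge);
}
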