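// Low-level raster primitives for the segmentation / spot-detection stages.
// Images are R numeric matrices (column-major); label 0 = background.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 boundary: ... 2 1 0 1 2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable convolution with reflect padding. kernel must have odd length.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol(), k = kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int j = -h; j <= h; ++j)
        s += kernel[j + h] * img(reflect_idx(r + j, nr), c);
      tmp(r, c) = s;
    }
  // along columns (horizontal pass)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int j = -h; j <= h; ++j)
        s += kernel[j + h] * tmp(r, reflect_idx(c + j, nc));
      out(r, c) = s;
    }
  return out;
}

// Connected-component labelling of a logical mask (4- or 8-connectivity).
// Labels are assigned in raster (column-major) order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int,int> > nb;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if (connectivity == 4 && std::abs(dr) + std::abs(dc) != 1) continue;
      nb.push_back(std::make_pair(dr, dc));
    }
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(c0 * nr + r0);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int r = idx % nr, c = idx / nr;
        for (size_t j = 0; j < nb.size(); ++j) {
          int rr = r + nb[j].first, cc = c + nb[j].second;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(cc * nr + rr);
          }
        }
      }
    }
  return lab;
}

// For every background pixel, the label of the nearest nonzero pixel within
// Euclidean distance max_dist (ties: smaller distance first, then lower label).
// Nonzero pixels keep their own label. Used for the seeded cytoplasm partition
// and for mask dilation.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_site(const IntegerMatrix& labels, double max_dist) {
  const int nr = labels.nrow(), nc = labels.ncol();
  if (max_dist <= 0) stop("max_dist must be > 0");
  const int R = (int)std::ceil(max_dist);
  const double md2 = max_dist * max_dist;
  // offsets sorted by squared distance; equal-distance runs are scanned fully
  struct Off { int dr, dc; double d2; };
  std::vector<Off> offs;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc) {
      double d2 = (double)dr * dr + (double)dc * dc;
      if (d2 <= md2 && d2 > 0) {
        Off o; o.dr = dr; o.dc = dc; o.d2 = d2;
        offs.push_back(o);
      }
    }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.d2 < b.d2; });
  IntegerMatrix out(nr, nc);
  const size_t no = offs.size();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int self = labels(r, c);
      if (self != 0) { out(r, c) = self; continue; }
      int best = 0; double bestd2 = -1.0;
      for (size_t j = 0; j < no; ++j) {
        if (best != 0 && offs[j].d2 > bestd2) break;  // past the tie run
        int rr = r + offs[j].dr, cc = c + offs[j].dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = labels(rr, cc);
        if (l != 0) {
          if (best == 0) { best = l; bestd2 = offs[j].d2; }
          else if (l < best) best = l;  // same distance, lower label wins
        }
      }
      out(r, c) = best;
    }
  return out;
}

// Local maxima of img within a disk of the given radius, restricted to mask
// pixels and values strictly above threshold. A pixel qualifies when no
// neighbour in the disk exceeds it. Returns candidate rows/cols (1-based).
// [[Rcpp::export]]
List cpp_local_maxima(const NumericMatrix& img, const LogicalMatrix& mask,
                      int radius, double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) stop("radius must be >= 1");
  const int R2 = radius * radius;
  std::vector<int> rows, cols;
  std::vector<double> vals;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double v = img(r, c);
      if (!(v > threshold)) continue;
      bool is_max = true;
      for (int dr = -radius; dr <= radius && is_max; ++dr)
        for (int dc = -radius; dc <= radius; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (dr * dr + dc * dc > R2) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (img(rr, cc) > v) { is_max = false; break; }
        }
      if (is_max) {
        rows.push_back(r + 1);
        cols.push_back(c + 1);
        vals.push_back(v);
      }
    }
  return List::create(_["row"] = wrap(rows), _["col"] = wrap(cols),
                      _["value"] = wrap(vals));
}
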