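#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Bernsen local threshold over a circular neighborhood (disk of the given
// radius, center included, offsets with dr^2 + dc^2 <= r^2). Neighborhoods
// are clipped at image borders: only in-image pixels contribute to min/max.
//
// Per pixel: lo = min, hi = max over the neighborhood, mid = (lo + hi) / 2,
// local contrast = hi - lo.
//   contrast >= c : foreground iff intensity > mid      (strict)
//   contrast <  c : foreground iff mid >= half_scale    (low-contrast rule)
// [[Rcpp::export]]
LogicalMatrix cpp_bernsen(IntegerMatrix img, int radius, double contrast,
                          double half_scale) {
  const int nr = img.nrow(), nc = img.ncol();
  // precompute disk offsets
  std::vector<int> dro, dco;
  const double r2 = (double)radius * radius;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if ((double)dr * dr + (double)dc * dc <= r2) {
        dro.push_back(dr);
        dco.push_back(dc);
      }
  const int nk = (int)dro.size();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lo = img(r, c), hi = lo;
      for (int k = 0; k < nk; ++k) {
        const int rr = r + dro[k];
        const int cc = c + dco[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int v = img(rr, cc);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      const double mid = (lo + hi) / 2.0;
      if ((double)(hi - lo) >= contrast)
        out(r, c) = (double)img(r, c) > mid;
      else
        out(r, c) = mid >= half_scale;
    }
  }
  return out;
}

// Connected-component labeling by breadth-first search. Components are
// numbered 1, 2, ... in raster-scan order (top-to-bottom, left-to-right)
// of their first-encountered pixel; background stays 0.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialized
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::deque<std::pair<int, int> > queue;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      queue.push_back(std::make_pair(r, c));
      while (!queue.empty()) {
        const std::pair<int, int> p = queue.front();
        queue.pop_front();
        for (int k = 0; k < nn; ++k) {
          const int rr = p.first + dr[k];
          const int cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            queue.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
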