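#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// 8-connected component labeling of a logical mask. Labels are 1..k in
// raster-scan discovery order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second;
        q.pop_front();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Background region 4-connected to the image border (the "outside");
// interior holes are background NOT in this region. Foreground pixels are
// never part of it.
// [[Rcpp::export]]
LogicalMatrix cpp_outside_background(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::deque<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) {
        if (!mask(i, j) && !out(i, j)) {
          out(i, j) = true;
          q.push_back(std::make_pair(i, j));
        }
      }
    }
  }
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int r = q.front().first, c = q.front().second;
    q.pop_front();
    for (int d = 0; d < 4; ++d) {
      int rr = r + DR4[d], cc = c + DC4[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) && !out(rr, cc)) {
        out(rr, cc) = true;
        q.push_back(std::make_pair(rr, cc));
      }
    }
  }
  return out;
}

// Standard persistence boundary-matrix reduction over Z/2. `cols` holds, for
// each simplex in filtration order, the 1-based positions of its boundary
// facets (sorted ascending); vertices have empty boundaries. Returns a two
// column matrix of (birth position, death position) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_reduce_boundary(List cols) {
  int m = cols.size();
  std::vector<std::vector<int> > B(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector v = cols[j];
    B[j] = std::vector<int>(v.begin(), v.end());
  }
  std::vector<int> owner(m + 1, -1); // owner[low] = column with that pivot
  std::vector<std::pair<int, int> > pairs;
  std::vector<int> tmp;
  for (int j = 0; j < m; ++j) {
    std::vector<int>& col = B[j];
    while (!col.empty()) {
      int low = col.back();
      int k = owner[low];
      if (k < 0) break;
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    B[k].begin(), B[k].end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      owner[col.back()] = j;
      pairs.push_back(std::make_pair(col.back(), j + 1));
    }
  }
  IntegerMatrix out((int) pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = pairs[i].first;
    out(i, 1) = pairs[i].second;
  }
  return out;
}
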