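#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scanline rasterization of a set of closed vertex loops onto an
// nrow x ncol pixel grid. Coordinates are 0-based continuous (row, col);
// a pixel (r, c) is filled when its centre (r + 0.5, c + 0.5) lies inside
// the loop arrangement. Two fill rules:
//   winding = TRUE  -> nonzero winding number (consistently oriented
//                      overlapping loops union; opposite-oriented loops
//                      cut holes)
//   winding = FALSE -> even-odd parity across the joint loop set
// Pixel centres sit at half-integers while loop vertices produced by mask
// tracing sit on integers, so the crossing tests below are tie-free for
// traced geometry.
// [[Rcpp::export]]
LogicalMatrix rasterize_loops_cpp(int nrow, int ncol, List loops, bool winding) {
  LogicalMatrix out(nrow, ncol);
  int np = loops.size();
  if (np == 0) return out;

  for (int i = 0; i < nrow; ++i) {
    double y = i + 0.5;
    std::vector<std::pair<double, int> > cross; // (col of crossing, direction)
    for (int p = 0; p < np; ++p) {
      NumericMatrix v = loops[p];
      int n = v.nrow();
      if (n < 3) continue;
      for (int a = 0; a < n; ++a) {
        int b = (a + 1) % n;
        double y1 = v(a, 0), x1 = v(a, 1);
        double y2 = v(b, 0), x2 = v(b, 1);
        if (y1 <= y && y2 > y) {
          double t = (y - y1) / (y2 - y1);
          cross.push_back(std::make_pair(x1 + t * (x2 - x1), 1));
        } else if (y2 <= y && y1 > y) {
          double t = (y - y1) / (y2 - y1);
          cross.push_back(std::make_pair(x1 + t * (x2 - x1), -1));
        }
      }
    }
    if (cross.empty()) continue;
    std::sort(cross.begin(), cross.end());
    size_t k = 0;
    int wind = 0, parity = 0;
    for (int j = 0; j < ncol; ++j) {
      double x = j + 0.5;
      while (k < cross.size() && cross[k].first <= x) {
        wind += cross[k].second;
        parity ^= 1;
        ++k;
      }
      out(i, j) = winding ? (wind != 0) : (parity == 1);
    }
  }
  return out;
}
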