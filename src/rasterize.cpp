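#include <Rcpp.h>
using namespace Rcpp;

// Fill the union of parametric ellipses into a logical raster.
//
// The raster maps pixel (row r, col c), 1-based, to world coordinates
// u = ox + (c - 1) / res, v = oy + (r - 1) / res. Each row of `ellipses`
// holds (cx, cy, ux, uy, vx, vy): the region is
// { (cx, cy) + a * (ux, uy) + b * (vx, vy) : a^2 + b^2 <= 1 }.
// Degenerate (near-singular) ellipses must be regularized by the caller.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_ellipses(int nrow, int ncol, double ox, double oy,
                                double res, NumericMatrix ellipses) {
  LogicalMatrix mask(nrow, ncol);
  for (int e = 0; e < ellipses.nrow(); ++e) {
    double cx = ellipses(e, 0), cy = ellipses(e, 1);
    double ux = ellipses(e, 2), uy = ellipses(e, 3);
    double vx = ellipses(e, 4), vy = ellipses(e, 5);
    double det = ux * vy - vx * uy;
    if (det == 0.0) continue;
    double ex = std::sqrt(ux * ux + vx * vx);
    double ey = std::sqrt(uy * uy + vy * vy);
    int c0 = (int)std::floor((cx - ex - ox) * res) + 1;
    int c1 = (int)std::ceil((cx + ex - ox) * res) + 1;
    int r0 = (int)std::floor((cy - ey - oy) * res) + 1;
    int r1 = (int)std::ceil((cy + ey - oy) * res) + 1;
    if (c0 < 1) c0 = 1;
    if (r0 < 1) r0 = 1;
    if (c1 > ncol) c1 = ncol;
    if (r1 > nrow) r1 = nrow;
    for (int c = c0; c <= c1; ++c) {
      double pu = ox + (c - 1) / res - cx;
      for (int r = r0; r <= r1; ++r) {
        if (mask(r - 1, c - 1)) continue;
        double pv = oy + (r - 1) / res - cy;
        double a = (vy * pu - vx * pv) / det;
        double b = (-uy * pu + ux * pv) / det;
        if (a * a + b * b <= 1.0) mask(r - 1, c - 1) = true;
      }
    }
  }
  return mask;
}
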