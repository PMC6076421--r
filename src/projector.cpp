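#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Arc-quadrature rows of the circular-mean projector for one detector.
//
// For each radius r[k] the circle centred on the detector is sampled at
// equal angles (>= samples_per_pixel samples per crossed pixel length) and
// each sample deposits its arc-length element (mm) onto the four
// surrounding pixel centres by bilinear interpolation. Samples falling
// outside the grid are dropped, which clips the arc to the image support.
//
// Grid convention: column-major pixel vector, index = col * ny + row
// (0-based); row 0 is the top of the image (largest y).
// [[Rcpp::export]]
List arc_row_triplets(int nx, int ny, double pixel,
                      double x0, double y0,
                      double det_x, double det_y,
                      NumericVector radii, double samples_per_pixel) {
  const int npix = nx * ny;
  std::vector<double> acc(npix, 0.0);
  std::vector<int> touched;
  touched.reserve(4096);
  std::vector<int> out_i, out_j;
  std::vector<double> out_x;

  for (int k = 0; k < radii.size(); ++k) {
    const double r = radii[k];
    if (!(r > 0)) continue;
    const double circ = 2.0 * M_PI * r;
    int n = (int)std::ceil(samples_per_pixel * circ / pixel);
    if (n < 16) n = 16;
    const double ds = circ / n;        // arc-length element, mm
    const double dth = 2.0 * M_PI / n;
    touched.clear();
    for (int s = 0; s < n; ++s) {
      const double th = (s + 0.5) * dth;
      const double px = det_x + r * std::cos(th);
      const double py = det_y + r * std::sin(th);
      // fractional pixel coordinates (col cx, row ry)
      const double cx = (px - x0) / pixel;
      const double ry = (y0 - py) / pixel;
      const int c0 = (int)std::floor(cx);
      const int r0 = (int)std::floor(ry);
      const double fx = cx - c0;
      const double fy = ry - r0;
      const double w[4] = {(1 - fx) * (1 - fy), (1 - fx) * fy,
                           fx * (1 - fy), fx * fy};
      const int cc[4] = {c0, c0, c0 + 1, c0 + 1};
      const int rr[4] = {r0, r0 + 1, r0, r0 + 1};
      for (int q = 0; q < 4; ++q) {
        if (cc[q] < 0 || cc[q] >= nx || rr[q] < 0 || rr[q] >= ny) continue;
        const int idx = cc[q] * ny + rr[q];
        if (acc[idx] == 0.0) touched.push_back(idx);
        acc[idx] += w[q] * ds;
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      const int idx = touched[t];
      if (acc[idx] != 0.0) {
        out_i.push_back(k);
        out_j.push_back(idx);
        out_x.push_back(acc[idx]);
        acc[idx] = 0.0;
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}
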