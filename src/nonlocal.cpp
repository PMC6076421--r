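#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Steering-kernel weight search over the whole image.
//
// For every pixel i the candidate set is the full image subsampled at
// `stride` plus an exhaustive local window of radius `window_radius`.
// Each candidate j is scored with the direction-adaptive weight
//   w = sqrt(det S_j) / (2 pi h^2 mu_j^2)
//       * exp( -d' S_j d / (2 h^2 mu_j^2) - ssd_ij / (2 patch_h^2) ),
// d the (col,row) pixel displacement and ssd_ij a Gaussian-windowed mean
// squared difference between the patches at i and j (dropped when
// use_patch is false); patch_h is an intensity-scale bandwidth, separate
// from the spatial one. Rows are max-normalised, screened at threshold T,
// capped at max_neighbors (self always kept) and renormalised to sum 1,
// giving a row-stochastic sparse operator.
//
// S is passed as per-pixel components (unit determinant by construction in
// the R caller); matrices are ny x nx, pixel index = col * ny + row.
// [[Rcpp::export]]
List nonlocal_triplets(NumericMatrix A,
                       NumericMatrix Sxx, NumericMatrix Sxy,
                       NumericMatrix Syy, NumericMatrix mu,
                       double h, double patch_h, double T,
                       int patch_radius, int stride, int window_radius,
                       int max_neighbors, bool use_patch,
                       NumericVector patch_kernel) {
  const int ny = A.nrow(), nx = A.ncol();
  const int npix = nx * ny;
  const double cut = 40.0;   // exp(-40) can never survive T >= 1e-17
  const int pr = patch_radius;
  const int pw = 2 * pr + 1;

  std::vector<int> out_i, out_j;
  std::vector<double> out_x;
  out_i.reserve((size_t)npix * 8);
  out_j.reserve((size_t)npix * 8);
  out_x.reserve((size_t)npix * 8);

  std::vector<int> cand_idx;
  std::vector<double> cand_w;
  cand_idx.reserve(8192);
  cand_w.reserve(8192);

  for (int ci = 0; ci < nx; ++ci) {
    for (int ri = 0; ri < ny; ++ri) {
      const int i = ci * ny + ri;
      cand_idx.clear();
      cand_w.clear();
      double wmax = 0.0;
      int self_pos = -1;

      // iterate the union of stride grid and local window without duplicates
      for (int pass = 0; pass < 2; ++pass) {
        int cl0, cl1, rl0, rl1, step;
        if (pass == 0) {              // local window, exhaustive
          cl0 = std::max(0, ci - window_radius);
          cl1 = std::min(nx - 1, ci + window_radius);
          rl0 = std::max(0, ri - window_radius);
          rl1 = std::min(ny - 1, ri + window_radius);
          step = 1;
        } else {                      // whole-image stride grid
          cl0 = 0; cl1 = nx - 1; rl0 = 0; rl1 = ny - 1; step = stride;
        }
        for (int cj = cl0; cj <= cl1; cj += step) {
          for (int rj = rl0; rj <= rl1; rj += step) {
            if (pass == 1 &&
                std::abs(cj - ci) <= window_radius &&
                std::abs(rj - ri) <= window_radius) continue;  // already done
            const double m = mu(rj, cj);
            if (!(m > 0)) continue;
            const double denom = 2.0 * h * h * m * m;
            const double dc = (double)(cj - ci);
            const double dr = (double)(rj - ri);
            double e = (Sxx(rj, cj) * dc * dc +
                        2.0 * Sxy(rj, cj) * dc * dr +
                        Syy(rj, cj) * dr * dr) / denom;
            if (e > cut) continue;
            if (use_patch) {
              double ssd = 0.0;
              int t = 0;
              for (int oc = -pr; oc <= pr; ++oc) {
                for (int orr = -pr; orr <= pr; ++orr, ++t) {
                  int c1 = ci + oc, r1 = ri + orr;
                  int c2 = cj + oc, r2 = rj + orr;
                  if (c1 < 0) c1 = 0; else if (c1 >= nx) c1 = nx - 1;
                  if (c2 < 0) c2 = 0; else if (c2 >= nx) c2 = nx - 1;
                  if (r1 < 0) r1 = 0; else if (r1 >= ny) r1 = ny - 1;
                  if (r2 < 0) r2 = 0; else if (r2 >= ny) r2 = ny - 1;
                  const double dv = A(r1, c1) - A(r2, c2);
                  ssd += patch_kernel[t] * dv * dv;
                }
              }
              e += ssd / (2.0 * patch_h * patch_h);
              if (e > cut) continue;
            }
            const double w = std::exp(-e) / (2.0 * M_PI * h * h * m * m);
            if (cj == ci && rj == ri) self_pos = (int)cand_idx.size();
            cand_idx.push_back(cj * ny + rj);
            cand_w.push_back(w);
            if (w > wmax) wmax = w;
          }
        }
      }
      (void)pw;

      if (self_pos < 0 || wmax <= 0.0) {   // degenerate: identity row
        out_i.push_back(i); out_j.push_back(i); out_x.push_back(1.0);
        continue;
      }

      // screen at T after max-normalisation; self always kept
      std::vector<std::pair<double, int> > kept;
      kept.reserve(cand_idx.size());
      for (size_t t = 0; t < cand_idx.size(); ++t) {
        const double wn = cand_w[t] / wmax;
        if (wn > T || (int)t == self_pos)
          kept.push_back(std::make_pair(wn, cand_idx[t]));
      }
      if ((int)kept.size() > max_neighbors) {
        const int self_idx = i;
        std::sort(kept.begin(), kept.end(),
                  [self_idx](const std::pair<double, int>& a,
                             const std::pair<double, int>& b) {
                    if (a.second == self_idx) return true;   // self first
                    if (b.second == self_idx) return false;
                    return a.first > b.first;
                  });
        kept.resize(max_neighbors);
      }
      double wsum = 0.0;
      for (size_t t = 0; t < kept.size(); ++t) wsum += kept[t].first;
      for (size_t t = 0; t < kept.size(); ++t) {
        out_i.push_back(i);
        out_j.push_back(kept[t].second);
        out_x.push_back(kept[t].first / wsum);
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}
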