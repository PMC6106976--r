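#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Seeded region growing with an adaptive gray-level homogeneity criterion.
// A FIFO queue of candidate pixels is processed; a candidate joins the
// region when |value - running region mean| < W (strict), and the mean is
// updated incrementally after each accepted pixel. Each seed grows its own
// region; the returned mask is the union. 4-connectivity; neighbors are
// enqueued in N, S, W, E order.
// [[Rcpp::export(name = ".regionGrowCpp")]]
NumericMatrix regionGrowCpp(NumericMatrix img, IntegerMatrix seeds, double W) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int s = 0; s < seeds.nrow(); ++s) {
    int sr = seeds(s, 0) - 1, sc = seeds(s, 1) - 1;  // 1-based from R
    if (sr < 0 || sr >= nr || sc < 0 || sc >= nc)
      stop("seed out of image bounds");
    std::vector<char> inRegion(static_cast<size_t>(nr) * nc, 0);
    std::queue<int> q;
    double total = img(sr, sc);
    long count = 1;
    inRegion[sr + static_cast<size_t>(sc) * nr] = 1;
    for (int k = 0; k < 4; ++k) {
      int r = sr + dr[k], c = sc + dc[k];
      if (r >= 0 && r < nr && c >= 0 && c < nc) q.push(r + c * nr);
    }
    while (!q.empty()) {
      int idx = q.front(); q.pop();
      if (inRegion[idx]) continue;
      int r = idx % nr, c = idx / nr;
      double mean = total / count;
      if (std::abs(img(r, c) - mean) < W) {
        inRegion[idx] = 1;
        total += img(r, c);
        ++count;
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
            int idx2 = r2 + c2 * nr;
            if (!inRegion[idx2]) q.push(idx2);
          }
        }
      }
    }
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (inRegion[r + static_cast<size_t>(c) * nr]) out(r, c) = 1.0;
  }
  return out;
}

// Iterated conditional modes for the two-class Gaussian + Potts posterior
// energy. Sequential sweeps in R's native column-major raster order; each
// pixel takes the label minimizing
//   (x - mu_l)^2 / (2 sigma2_l) + log(sigma_l) + beta * #{8-neighbors != l}
// using the labels current at visit time. Stops after nSweeps sweeps or as
// soon as a sweep changes nothing.
// [[Rcpp::export(name = ".icmSweepsCpp")]]
NumericMatrix icmSweepsCpp(NumericMatrix img, NumericMatrix labels0,
                           NumericVector mu, NumericVector sigma2,
                           double beta, int nSweeps) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix lab = clone(labels0);
  double logs[2] = {0.5 * std::log(sigma2[0]), 0.5 * std::log(sigma2[1])};
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int sweep = 0; sweep < nSweeps; ++sweep) {
    long changed = 0;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double x = img(r, c);
        double e[2];
        for (int l = 0; l < 2; ++l) {
          double d = x - mu[l];
          e[l] = d * d / (2.0 * sigma2[l]) + logs[l];
        }
        int disagree[2] = {0, 0};
        for (int k = 0; k < 8; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
            int ln = static_cast<int>(lab(r2, c2));
            ++disagree[1 - ln];
          }
        }
        e[0] += beta * disagree[0];
        e[1] += beta * disagree[1];
        double newLab = (e[1] < e[0]) ? 1.0 : 0.0;
        if (newLab != lab(r, c)) { lab(r, c) = newLab; ++changed; }
      }
    }
    if (changed == 0) break;
  }
  return lab;
}

// Nearest-distance from every point of set A to set B, physical units.
// Plain O(|A||B|) scan; boundary sets here are a few hundred points.
// [[Rcpp::export(name = ".nearestDistCpp")]]
NumericVector nearestDistCpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ar = A(i, 0), ac = A(i, 1);
    for (int j = 0; j < nb; ++j) {
      double d0 = ar - B(j, 0), d1 = ac - B(j, 1);
      double d = d0 * d0 + d1 * d1;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
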