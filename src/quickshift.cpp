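#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Quickshift mode seeking on the joint (ratio*L, ratio*a, ratio*b, x, y)
// feature space.  Each pixel's Parzen density is a Gaussian sum over a
// square spatial window of half-width ceil(3 * kernel_size); each pixel
// links to the spatially nearest pixel of strictly higher density within
// Euclidean spatial distance max_dist (ties: smallest row-major index).

// [[Rcpp::export(name = ".quickshift_cpp")]]
IntegerMatrix quickshift_cpp(NumericVector lab, double ratio,
                             double kernel_size, double max_dist) {
  IntegerVector dim = lab.attr("dim");
  int H = dim[0], W = dim[1];
  int N = H * W;
  const double* L = lab.begin();

  auto feat = [&](int r, int c, int ch) -> double {
    if (ch < 3) return ratio * L[r + H * c + H * W * ch];
    return ch == 3 ? (double)c : (double)r;
  };
  auto fdist2 = [&](int r1, int c1, int r2, int c2) -> double {
    double s = 0.0;
    for (int ch = 0; ch < 5; ++ch) {
      double d = feat(r1, c1, ch) - feat(r2, c2, ch);
      s += d * d;
    }
    return s;
  };

  int wdens = (int)std::ceil(3.0 * kernel_size);
  double inv2h2 = 1.0 / (2.0 * kernel_size * kernel_size);
  std::vector<double> density(N, 0.0);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double d = 0.0;
      for (int rr = std::max(0, r - wdens); rr <= std::min(H - 1, r + wdens); ++rr)
        for (int cc = std::max(0, c - wdens); cc <= std::min(W - 1, c + wdens); ++cc)
          d += std::exp(-fdist2(r, c, rr, cc) * inv2h2);
      density[r * W + c] = d;
    }

  int wlink = (int)std::ceil(max_dist);
  double md2 = max_dist * max_dist;
  std::vector<int> parent(N);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int p = r * W + c;
      int bestq = p;
      double bestd2 = R_PosInf;
      for (int rr = std::max(0, r - wlink); rr <= std::min(H - 1, r + wlink); ++rr)
        for (int cc = std::max(0, c - wlink); cc <= std::min(W - 1, c + wlink); ++cc) {
          int q = rr * W + cc;
          if (density[q] <= density[p]) continue;
          double sd2 = (double)(rr - r) * (rr - r) + (double)(cc - c) * (cc - c);
          if (sd2 > md2) continue;
          if (sd2 < bestd2 || (sd2 == bestd2 && q < bestq)) {
            bestd2 = sd2;
            bestq = q;
          }
        }
      parent[p] = bestq;  // self if root
    }

  // resolve each pixel to its tree root
  std::vector<int> root(N, -1);
  std::vector<int> path;
  for (int p = 0; p < N; ++p) {
    if (root[p] >= 0) continue;
    path.clear();
    int q = p;
    while (root[q] < 0 && parent[q] != q) {
      path.push_back(q);
      q = parent[q];
    }
    int r = root[q] >= 0 ? root[q] : q;
    root[q] = r;
    for (int v : path) root[v] = r;
  }

  std::vector<int> remap(N, -1);
  int next_id = 0;
  IntegerMatrix out(H, W);
  for (int p = 0; p < N; ++p) {
    if (remap[root[p]] < 0) remap[root[p]] = next_id++;
    out(p / W, p % W) = remap[root[p]];
  }
  out.attr("parent") = IntegerVector(parent.begin(), parent.end());
  out.attr("density") = NumericVector(density.begin(), density.end());
  return out;
}
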