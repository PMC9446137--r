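#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <vector>
using namespace Rcpp;

// 4-connected flood fill admitting pixels whose RGB Euclidean distance to
// the SEED pixel (not a running mean) is at most `tolerance`.

// [[Rcpp::export(name = ".floodfill_cpp")]]
LogicalMatrix floodfill_cpp(NumericVector img, int seed_r, int seed_c,
                            double tolerance) {
  IntegerVector dim = img.attr("dim");
  int H = dim[0], W = dim[1];
  auto at = [&](int r, int c, int ch) { return img[r + H * c + H * W * ch]; };
  double s0 = at(seed_r, seed_c, 0), s1 = at(seed_r, seed_c, 1),
         s2 = at(seed_r, seed_c, 2);
  auto ok = [&](int r, int c) {
    double d0 = at(r, c, 0) - s0, d1 = at(r, c, 1) - s1, d2 = at(r, c, 2) - s2;
    return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2) <= tolerance;
  };

  LogicalMatrix sel(H, W);
  std::deque<std::pair<int, int>> q;
  sel(seed_r, seed_c) = true;
  q.emplace_back(seed_r, seed_c);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    auto [r, c] = q.front();
    q.pop_front();
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (sel(rr, cc)) continue;
      if (ok(rr, cc)) {
        sel(rr, cc) = true;
        q.emplace_back(rr, cc);
      }
    }
  }
  return sel;
}
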