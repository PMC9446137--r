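#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <vector>
using namespace Rcpp;

// SLIC superpixels: local k-means in (L, a, b, x, y) with distance
// D^2 = d_lab^2 + (m/S)^2 d_xy^2, search windows of 2S x 2S around each
// center.  A pixel may always keep its current center, so the traced
// objective (sum of D^2 after each assignment sweep) never increases.

namespace {

struct Center {
  double L, a, b, x, y;  // x = column, y = row
};

inline double lab_at(const double* lab, int H, int W, int r, int c, int ch) {
  return lab[r + H * c + H * W * ch];
}

inline double d2(const double* lab, int H, int W, int r, int c,
                 const Center& ct, double mS2) {
  double dl = lab_at(lab, H, W, r, c, 0) - ct.L;
  double da = lab_at(lab, H, W, r, c, 1) - ct.a;
  double db = lab_at(lab, H, W, r, c, 2) - ct.b;
  double dx = c - ct.x, dy = r - ct.y;
  return dl * dl + da * da + db * db + mS2 * (dx * dx + dy * dy);
}

double gradient(const double* lab, int H, int W, int r, int c) {
  int rm = std::max(r - 1, 0), rp = std::min(r + 1, H - 1);
  int cm = std::max(c - 1, 0), cp = std::min(c + 1, W - 1);
  double g = 0.0;
  for (int ch = 0; ch < 3; ++ch) {
    double dh = lab_at(lab, H, W, r, cp, ch) - lab_at(lab, H, W, r, cm, ch);
    double dv = lab_at(lab, H, W, rp, c, ch) - lab_at(lab, H, W, rm, c, ch);
    g += dh * dh + dv * dv;
  }
  return g;
}

}  // namespace

// [[Rcpp::export(name = ".slic_cpp")]]
List slic_cpp(NumericVector lab, int n_segments, double compactness,
              int max_iter, bool enforce_connectivity) {
  IntegerVector dim = lab.attr("dim");
  int H = dim[0], W = dim[1];
  int N = H * W;
  const double* L = lab.begin();

  double S = std::sqrt((double)N / n_segments);
  double mS2 = (compactness / S) * (compactness / S);

  // regular grid of approximately n_segments seeds (row-major, first n kept)
  int ny = std::max(1, std::min(n_segments,
              (int)std::lround(std::sqrt((double)n_segments * H / W))));
  int nx = (n_segments + ny - 1) / ny;
  std::vector<Center> centers;
  centers.reserve(n_segments);
  for (int i = 0; i < ny && (int)centers.size() < n_segments; ++i) {
    for (int j = 0; j < nx && (int)centers.size() < n_segments; ++j) {
      int r0 = std::min(H - 1, (int)((i + 0.5) * H / ny));
      int c0 = std::min(W - 1, (int)((j + 0.5) * W / nx));
      // move to the lowest-gradient pixel in the 3x3 neighborhood
      int br = r0, bc = c0;
      double bg = gradient(L, H, W, r0, c0);
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int r = r0 + dr, c = c0 + dc;
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          double g = gradient(L, H, W, r, c);
          if (g < bg) { bg = g; br = r; bc = c; }
        }
      centers.push_back({lab_at(L, H, W, br, bc, 0),
                         lab_at(L, H, W, br, bc, 1),
                         lab_at(L, H, W, br, bc, 2),
                         (double)bc, (double)br});
    }
  }
  int K = centers.size();

  std::vector<int> label(N, -1);
  std::vector<double> best(N);
  std::vector<double> objective;
  int win = (int)std::ceil(S);

  for (int iter = 0; iter < max_iter; ++iter) {
    // keep-current-center option guarantees a monotone objective
    for (int p = 0; p < N; ++p) {
      if (label[p] >= 0)
        best[p] = d2(L, H, W, p / W, p % W, centers[label[p]], mS2);
      else
        best[p] = R_PosInf;
    }
    for (int k = 0; k < K; ++k) {
      int cy = (int)std::lround(centers[k].y);
      int cx = (int)std::lround(centers[k].x);
      int r1 = std::max(0, cy - win), r2 = std::min(H - 1, cy + win);
      int c1 = std::max(0, cx - win), c2 = std::min(W - 1, cx + win);
      for (int r = r1; r <= r2; ++r)
        for (int c = c1; c <= c2; ++c) {
          int p = r * W + c;
          double d = d2(L, H, W, r, c, centers[k], mS2);
          if (d < best[p]) { best[p] = d; label[p] = k; }
        }
    }
    // safety net: any pixel missed by every window joins its global nearest
    for (int p = 0; p < N; ++p) {
      if (label[p] >= 0) continue;
      for (int k = 0; k < K; ++k) {
        double d = d2(L, H, W, p / W, p % W, centers[k], mS2);
        if (d < best[p]) { best[p] = d; label[p] = k; }
      }
    }
    double obj = 0.0;
    for (int p = 0; p < N; ++p) obj += best[p];
    bool changed = objective.empty() || obj < objective.back() - 1e-12;
    objective.push_back(obj);

    // center update: mean labxy of members
    std::vector<double> acc(K * 5, 0.0);
    std::vector<int> cnt(K, 0);
    for (int p = 0; p < N; ++p) {
      int k = label[p], r = p / W, c = p % W;
      acc[k * 5 + 0] += lab_at(L, H, W, r, c, 0);
      acc[k * 5 + 1] += lab_at(L, H, W, r, c, 1);
      acc[k * 5 + 2] += lab_at(L, H, W, r, c, 2);
      acc[k * 5 + 3] += c;
      acc[k * 5 + 4] += r;
      cnt[k]++;
    }
    bool moved = false;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) continue;  // empty cluster keeps its center
      Center nc = {acc[k * 5] / cnt[k], acc[k * 5 + 1] / cnt[k],
                   acc[k * 5 + 2] / cnt[k], acc[k * 5 + 3] / cnt[k],
                   acc[k * 5 + 4] / cnt[k]};
      if (std::fabs(nc.x - centers[k].x) > 1e-9 ||
          std::fabs(nc.y - centers[k].y) > 1e-9 ||
          std::fabs(nc.L - centers[k].L) > 1e-9 ||
          std::fabs(nc.a - centers[k].a) > 1e-9 ||
          std::fabs(nc.b - centers[k].b) > 1e-9) moved = true;
      centers[k] = nc;
    }
    if (!moved && !changed && iter > 0) break;
  }

  if (enforce_connectivity) {
    // reassign 4-connected fragments smaller than S^2/4 to the adjacent
    // segment discovered before them in the row-major scan
    int min_frag = std::max(1, (int)(S * S / 4.0));
    std::vector<int> newlab(N, -1);
    std::vector<int> comp;
    for (int p0 = 0; p0 < N; ++p0) {
      if (newlab[p0] >= 0) continue;
      int adj = -1;  // label of a previously finished adjacent fragment
      comp.clear();
      comp.push_back(p0);
      newlab[p0] = label[p0];
      std::deque<int> q(1, p0);
      while (!q.empty()) {
        int p = q.front(); q.pop_front();
        int r = p / W, c = p % W;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          int pq = rr * W + cc;
          if (newlab[pq] < 0 && label[pq] == label[p0]) {
            newlab[pq] = label[p0];
            comp.push_back(pq);
            q.push_back(pq);
          } else if (newlab[pq] >= 0 && newlab[pq] != label[p0]) {
            adj = newlab[pq];
          }
        }
      }
      if ((int)comp.size() < min_frag && adj >= 0)
        for (int p : comp) newlab[p] = adj;
    }
    label.swap(newlab);
  }

  // contiguous ids, row-major first occurrence
  std::vector<int> remap(K + 1, -1);
  int next_id = 0;
  IntegerMatrix out(H, W);
  for (int p = 0; p < N; ++p) {
    int k = label[p];
    if (remap[k] < 0) remap[k] = next_id++;
    out(p / W, p % W) = remap[k];
  }
  return List::create(_["labels"] = out,
                      _["objective"] = NumericVector(objective.begin(),
                                                     objective.end()));
}
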