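#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Efficient graph-based segmentation on a 4-connected pixel grid.
// Edge weights are Euclidean distances in (smoothed) RGB; edges are
// processed in nondecreasing (weight, first endpoint, second endpoint)
// order, endpoints indexed row-major.  Components merge when the edge
// weight does not exceed min(Int(C) + k/|C|) over the two components,
// Int(C) being the largest edge weight already merged inside C.

namespace {

struct Edge {
  double w;
  int a, b;  // row-major linear pixel indices, a < b
};

struct DSU {
  std::vector<int> parent, size;
  std::vector<double> internal;  // Int(C), valid at roots
  explicit DSU(int n) : parent(n), size(n, 1), internal(n, 0.0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void join(int ra, int rb, double w) {
    // attach the larger root index under the smaller: deterministic
    if (rb < ra) std::swap(ra, rb);
    parent[rb] = ra;
    size[ra] += size[rb];
    internal[ra] = std::max(std::max(internal[ra], internal[rb]), w);
  }
};

inline double color_dist(const double* img, int H, int W, int p, int q) {
  // p, q row-major; array layout is column-major H x W x 3
  int pr = p / W, pc = p % W, qr = q / W, qc = q % W;
  double s = 0.0;
  for (int ch = 0; ch < 3; ++ch) {
    double d = img[pr + H * pc + H * W * ch] - img[qr + H * qc + H * W * ch];
    s += d * d;
  }
  return std::sqrt(s);
}

std::vector<Edge> grid_edges(const double* img, int H, int W) {
  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)H * W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int p = r * W + c;
      if (c + 1 < W) edges.push_back({color_dist(img, H, W, p, p + 1), p, p + 1});
      if (r + 1 < H) edges.push_back({color_dist(img, H, W, p, p + W), p, p + W});
    }
  }
  std::sort(edges.begin(), edges.end(), [](const Edge& x, const Edge& y) {
    if (x.w != y.w) return x.w < y.w;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });
  return edges;
}

}  // namespace

// [[Rcpp::export(name = ".felzenszwalb_cpp")]]
IntegerMatrix felzenszwalb_cpp(NumericVector img, double scale_k, int min_size) {
  IntegerVector dim = img.attr("dim");
  int H = dim[0], W = dim[1];
  int N = H * W;
  const double* px = img.begin();

  std::vector<Edge> edges = grid_edges(px, H, W);
  DSU dsu(N);

  for (const Edge& e : edges) {
    int ra = dsu.find(e.a), rb = dsu.find(e.b);
    if (ra == rb) continue;
    double ta = dsu.internal[ra] + scale_k / dsu.size[ra];
    double tb = dsu.internal[rb] + scale_k / dsu.size[rb];
    if (e.w <= std::min(ta, tb)) dsu.join(ra, rb, e.w);
  }

  // Post-merge: while a component is smaller than min_size, take the
  // smallest one (ties: smallest member pixel index) and merge it into
  // the neighbor reached by its lightest connecting edge.
  if (min_size > 1 && N >= min_size) {
    for (;;) {
      std::vector<int> minpix(N, N);
      for (int p = 0; p < N; ++p) {
        int r = dsu.find(p);
        if (p < minpix[r]) minpix[r] = p;
      }
      int target = -1;
      for (int p = 0; p < N; ++p) {
        int r = dsu.find(p);
        if (p != minpix[r]) continue;  // visit each root once
        if (dsu.size[r] >= min_size) continue;
        if (target == -1 ||
            dsu.size[r] < dsu.size[target] ||
            (dsu.size[r] == dsu.size[target] && minpix[r] < minpix[target]))
          target = r;
      }
      if (target == -1) break;
      // lightest edge out of `target` (edges already weight-sorted)
      bool merged = false;
      for (const Edge& e : edges) {
        int ra = dsu.find(e.a), rb = dsu.find(e.b);
        if (ra == rb) continue;
        if (ra == target || rb == target) {
          dsu.join(ra, rb, e.w);
          merged = true;
          break;
        }
      }
      if (!merged) break;  // single component left
    }
  }

  // contiguous ids in row-major first-occurrence order
  std::vector<int> remap(N, -1);
  int next_id = 0;
  IntegerMatrix out(H, W);
  for (int p = 0; p < N; ++p) {
    int r = dsu.find(p);
    if (remap[r] < 0) remap[r] = next_id++;
    out(p / W, p % W) = remap[r];
  }
  return out;
}
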