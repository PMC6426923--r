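// 3D connected components and threshold-free cluster enhancement (TFCE).
//
// TFCE uses a single descending sweep over threshold steps with an
// incremental weighted union-find: voxels activate as the threshold drops,
// components merge, and per-component increments extent^E * h^H * dh are
// accumulated lazily (each voxel's enhancement is recovered from potential
// offsets stored at merge time), giving near-linear cost per call.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

struct WUF {
  std::vector<int> parent;
  std::vector<double> shift;  // potential offset relative to parent
  std::vector<int> size;
  std::vector<double> acc;    // per-member accumulated value at roots

  void init(int n) {
    parent.assign(n, -1);
    shift.assign(n, 0.0);
    size.assign(n, 0);
    acc.assign(n, 0.0);
  }
  void make(int v) { parent[v] = v; size[v] = 1; }
  // find with path compression, folding shifts
  int find(int v, double& s) {
    double total = 0.0;
    int root = v;
    while (parent[root] != root) { total += shift[root]; root = parent[root]; }
    // compress
    int cur = v;
    double run = total;
    while (parent[cur] != root) {
      int nxt = parent[cur];
      double sh = shift[cur];
      shift[cur] = run;
      parent[cur] = root;
      run -= sh;
      cur = nxt;
    }
    s = total;
    return root;
  }
  // union roots; returns surviving root
  int link(int ra, int rb) {
    if (size[ra] < size[rb]) std::swap(ra, rb);
    // rb becomes child of ra
    parent[rb] = ra;
    shift[rb] = acc[rb] - acc[ra];
    size[ra] += size[rb];
    return ra;
  }
};

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  std::vector<std::array<int,3>> offs;
  neighbor_offsets(connectivity, offs);
  IntegerVector labels(V, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (int v = 0; v < V; ++v) {
    if (!mask[v] || labels[v]) continue;
    ++next_label;
    stack.clear();
    stack.push_back(v);
    labels[v] = next_label;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && !labels[w]) { labels[w] = next_label; stack.push_back(w); }
      }
    }
  }
  labels.attr("n_clusters") = next_label;
  return labels;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  NumericVector out(V, 0.0);
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) if (values[v] > hmax) hmax = values[v];
  if (hmax <= 0.0 || dh <= 0.0) return out;
  int nsteps = (int)std::floor(hmax / dh + 1e-12);
  if (nsteps < 1) return out;

  std::vector<std::array<int,3>> offs;
  neighbor_offsets(connectivity, offs);

  // voxels sorted by value descending
  std::vector<int> order(V);
  for (int v = 0; v < V; ++v) order[v] = v;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  WUF uf;
  uf.init(V);
  std::vector<int> roots;
  roots.reserve(1024);
  size_t ptr = 0;
  int n_dead = 0;

  for (int s = nsteps; s >= 1; --s) {
    double h = s * dh;
    // activate voxels with value >= h
    while (ptr < (size_t)V && values[order[ptr]] >= h) {
      int v = order[ptr++];
      uf.make(v);
      roots.push_back(v);
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (uf.parent[w] < 0) continue;   // neighbor not active yet
        double s1, s2;
        int rv = uf.find(v, s1);
        int rw = uf.find(w, s2);
        if (rv != rw) { uf.link(rv, rw); ++n_dead; }
      }
    }
    // accumulate increments on live roots
    double hH = std::pow(h, H) * dh;
    if (n_dead > (int)roots.size() / 2) {
      std::vector<int> live;
      live.reserve(roots.size() - n_dead);
      for (int r : roots) if (uf.parent[r] == r) live.push_back(r);
      roots.swap(live);
      n_dead = 0;
    }
    for (int r : roots) {
      if (uf.parent[r] != r) continue;
      uf.acc[r] += std::pow((double)uf.size[r], E) * hH;
    }
  }
  for (int v = 0; v < V; ++v) {
    if (uf.parent[v] < 0) continue;  // never activated
    double s;
    int r = uf.find(v, s);
    out[v] = uf.acc[r] + s;
  }
  return out;
}
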