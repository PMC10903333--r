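// Low-level 3D image kernels. All volumes are R arrays with dim = (nz, ny, nx),
// i.e. the z index varies fastest (column-major), matching the package's
// (z, y, x) axis convention. Linear index: z + nz*(y + ny*x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflect boundary; sigmas in voxel units.
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

static inline int reflect(int i, int n) {
  // reflect-101 style boundary; degenerates safely for n == 1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Convolve along one axis (0 = z, 1 = y, 2 = x) in place.
static void conv_axis(std::vector<double>& a, int nz, int ny, int nx,
                      int axis, const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  int n = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < n; ++z) line[z] = a[lin(z, y, x, nz, ny)];
        for (int z = 0; z < n; ++z) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(z + j, n)];
          a[lin(z, y, x, nz, ny)] = s;
        }
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < n; ++y) line[y] = a[lin(z, y, x, nz, ny)];
        for (int y = 0; y < n; ++y) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(y + j, n)];
          a[lin(z, y, x, nz, ny)] = s;
        }
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < n; ++x) line[x] = a[lin(z, y, x, nz, ny)];
        for (int x = 0; x < n; ++x) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(x + j, n)];
          a[lin(z, y, x, nz, ny)] = s;
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector arr, IntegerVector dim,
                                  double sigma_z, double sigma_y, double sigma_x) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  conv_axis(a, nz, ny, nx, 0, gauss_kernel(sigma_z));
  conv_axis(a, nz, ny, nx, 1, gauss_kernel(sigma_y));
  conv_axis(a, nz, ny, nx, 2, gauss_kernel(sigma_x));
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm, separable). Returns the distance
// from every voxel to the nearest background (FALSE) voxel, in physical units.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double h) {
  // squared-distance transform of sampled function f on grid spacing h;
  // the lower envelope is built over finite parabolas only
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> fin;
  fin.reserve(n);
  for (int i = 0; i < n; ++i)
    if (f[i] < INF) fin.push_back(i);
  if (fin.empty()) return; // stays all-infinite
  int m = (int)fin.size();
  std::vector<int> v(m);
  std::vector<double> zb(m + 1), d(n);
  int k = 0;
  v[0] = fin[0];
  zb[0] = -INF;
  zb[1] = INF;
  for (int qi = 1; qi < m; ++qi) {
    int q = fin[qi];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q * h * h) - (f[p] + (double)p * p * h * h)) /
          (2.0 * h * h * (q - p));
      if (k > 0 && s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = ((double)q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
  f = d;
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> a((size_t)nz * ny * nx);
  for (R_xlen_t i = 0; i < fg.size(); ++i) a[i] = fg[i] ? INF : 0.0;
  std::vector<double> line;
  // z axis
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) line[z] = a[lin(z, y, x, nz, ny)];
      dt1d(line, dz);
      for (int z = 0; z < nz; ++z) a[lin(z, y, x, nz, ny)] = line[z];
    }
  // y axis
  line.assign(ny, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) line[y] = a[lin(z, y, x, nz, ny)];
      dt1d(line, dy);
      for (int y = 0; y < ny; ++y) a[lin(z, y, x, nz, ny)] = line[y];
    }
  // x axis
  line.assign(nx, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) line[x] = a[lin(z, y, x, nz, ny)];
      dt1d(line, dx);
      for (int x = 0; x < nx; ++x) a[lin(z, y, x, nz, ny)] = line[x];
    }
  NumericVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) out[i] = std::sqrt(a[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (BFS), connectivity 6 or 26.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector fg, IntegerVector dim, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab((R_xlen_t)nz * ny * nx);
  std::vector<int> dzs, dys, dxs;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        dzs.push_back(a); dys.push_back(b); dxs.push_back(c);
      }
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!fg[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cx = cur / (nz * ny), rem = cur % (nz * ny);
          int cy = rem / nz, cz = rem % nz;
          for (size_t k = 0; k < dzs.size(); ++k) {
            int zz = cz + dzs[k], yy = cy + dys[k], xx = cx + dxs[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (fg[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding (Meyer), 6-connectivity, restricted to
// a mask. Ties broken by insertion order -> fully deterministic.
// ---------------------------------------------------------------------------

struct QItem {
  double prio;
  double dist;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding. Primary key: highest relief along
// the path (classic flooding); secondary key: physical geodesic distance
// traveled, so plateaus (flat cell interiors) are divided at equal metric
// distance even on anisotropic grids; final tie-break: insertion order.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector relief, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({relief[i], 0.0, order++, (int)i});
    }
  }
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};
  const double step[6] = {spacing[0], spacing[0], spacing[1], spacing[1],
                          spacing[2], spacing[2]};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int cur = it.idx;
    int cx = cur / (nz * ny), rem = cur % (nz * ny);
    int cy = rem / nz, cz = rem % nz;
    for (int k = 0; k < 6; ++k) {
      int zz = cz + dz6[k], yy = cy + dy6[k], xx = cx + dx6[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[cur];
        double p = relief[j] > it.prio ? relief[j] : it.prio;
        pq.push({p, it.dist + step[k], order++, j});
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// 26-neighborhood local maxima above a threshold.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_local_maxima3d(NumericVector arr, IntegerVector dim, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        double v = arr[i];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int a = -1; a <= 1 && ismax; ++a)
          for (int b = -1; b <= 1 && ismax; ++b)
            for (int c = -1; c <= 1 && ismax; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int zz = z + a, yy = y + b, xx = x + c;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              if (arr[lin(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        if (ismax) out.push_back(i + 1); // 1-based
      }
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// Sparse gated assignment: minimum-cost maximum-cardinality bipartite
// matching by successive shortest augmenting paths (Dijkstra with Johnson
// potentials). Edges are the candidate pairs within the gate; because every
// admissible pair is cheaper than leaving both endpoints unmatched, the
// min-cost maximum matching is exactly the gated optimal assignment with
// link-count priority. Returns, for each left node, the matched right node
// (1-based; 0 = unmatched).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_sparse_match(IntegerVector ei, IntegerVector ej,
                               NumericVector cost, int n_left, int n_right) {
  // Node ids: 0 = source, 1..n_left = left, n_left+1..n_left+n_right = right,
  // n_left+n_right+1 = sink. Successive shortest augmenting paths with
  // Johnson potentials; every Dijkstra runs to completion and potentials are
  // updated by min(dist, dist_T), keeping all reduced costs non-negative.
  int nE = ei.size();
  int S = 0, T = n_left + n_right + 1, NV = T + 1;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<std::vector<int>> adj_l(n_left);
  for (int k = 0; k < nE; ++k) adj_l[ei[k] - 1].push_back(k);
  std::vector<int> match_l(n_left, -1), match_r(n_right, -1);
  std::vector<int> match_edge_r(n_right, -1); // edge id of the matched pair
  std::vector<double> pi(NV, 0.0);

  struct Item { double d; int v; };
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const { return a.d > b.d; }
  };

  while (true) {
    std::vector<double> dist(NV, INF);
    std::vector<int> pred(NV, -1);      // predecessor edge id, or -2 for S/T arcs
    std::vector<int> pred_node(NV, -1);
    std::vector<bool> done(NV, false);
    std::priority_queue<Item, std::vector<Item>, Cmp> pq;
    dist[S] = 0.0;
    pq.push({0.0, S});
    while (!pq.empty()) {
      Item it = pq.top(); pq.pop();
      int u = it.v;
      if (done[u]) continue;
      done[u] = true;
      if (u == S) {
        for (int i = 0; i < n_left; ++i) {
          if (match_l[i] >= 0) continue;
          int vn = 1 + i;
          double nd = dist[u] + pi[S] - pi[vn];
          if (nd < dist[vn]) {
            dist[vn] = nd; pred[vn] = -2; pred_node[vn] = S;
            pq.push({nd, vn});
          }
        }
      } else if (u >= 1 && u <= n_left) {
        int i = u - 1;
        for (int k : adj_l[i]) {
          int j = ej[k] - 1;
          if (match_l[i] == j) continue;
          int vn = 1 + n_left + j;
          double nd = dist[u] + cost[k] + pi[u] - pi[vn];
          if (nd < dist[vn]) {
            dist[vn] = nd; pred[vn] = k; pred_node[vn] = u;
            pq.push({nd, vn});
          }
        }
      } else if (u < T) { // right node
        int j = u - 1 - n_left;
        if (match_r[j] < 0) {
          double nd = dist[u] + pi[u] - pi[T];
          if (nd < dist[T]) {
            dist[T] = nd; pred[T] = -2; pred_node[T] = u;
            pq.push({nd, T});
          }
        } else {
          int k = match_edge_r[j];
          int vn = 1 + match_r[j];
          double nd = dist[u] - cost[k] + pi[u] - pi[vn];
          if (nd < dist[vn]) {
            dist[vn] = nd; pred[vn] = k; pred_node[vn] = u;
            pq.push({nd, vn});
          }
        }
      }
    }
    if (dist[T] == INF) break;
    double dT = dist[T];
    for (int v = 0; v < NV; ++v)
      pi[v] += (dist[v] < dT) ? dist[v] : dT;
    // augment along predecessor chain T <- right <- left <- ... <- S
    int u = pred_node[T];
    while (u != S) {
      // u is a right node reached via forward edge pred[u]
      int k = pred[u];
      int j = ej[k] - 1;
      int i = ei[k] - 1;
      match_r[j] = i;
      match_edge_r[j] = k;
      int old_j = match_l[i];
      match_l[i] = j;
      int left_node = 1 + i;
      if (pred[left_node] == -2) { u = S; }
      else {
        // left node was reached via the reversed matched edge from old_j
        (void)old_j;
        u = pred_node[left_node];
      }
    }
  }
  IntegerVector out(n_left);
  for (int i = 0; i < n_left; ++i) out[i] = match_l[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Hungarian algorithm (Kuhn-Munkres with potentials, O(n^3)) for square cost
// matrices. Returns, for each row, the assigned column (1-based).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
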