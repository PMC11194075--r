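#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Disjoint-set over pixel indices with path compression.
static int dsu_find(std::vector<int> &parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

// Topographic-prominence maxima by descending flood (persistence pairing).
// Pixels are processed in decreasing intensity; each component is born at a
// local maximum and dies when it merges into a component with a higher (or
// tie-broken smaller-(y,x)) peak. A peak is reported iff
//   peak height - merge level >= prominence,
// the surviving global component measured against the image minimum.
// Returns 1-based (y, x) peak pixel coordinates, unsorted.
// [[Rcpp::export]]
IntegerMatrix find_maxima_cpp(NumericMatrix img, double prominence) {
  const int ny = img.nrow(), nx = img.ncol(), n = ny * nx;
  if (n == 0) return IntegerMatrix(0, 2);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  // decreasing value; ties in raster (y, x) order for determinism
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    int ra = a % ny, ca = a / ny, rb = b % ny, cb = b / ny;
    if (ra != rb) return ra < rb;
    return ca < cb;
  });

  std::vector<int> parent(n), peak_of(n, -1);
  std::vector<double> peak_val(n, 0.0);
  std::vector<char> seen(n, 0);
  std::vector<int> accepted;

  // (y,x)-lexicographic comparison of two pixel indices
  auto yx_less = [&](int a, int b) {
    int ra = a % ny, ca = a / ny, rb = b % ny, cb = b / ny;
    if (ra != rb) return ra < rb;
    return ca < cb;
  };

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int oi = 0; oi < n; ++oi) {
    int u = order[oi];
    double v = img[u];
    int r = u % ny, c = u / ny;
    parent[u] = u;
    peak_of[u] = u;
    peak_val[u] = v;
    seen[u] = 1;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
      int w = rr + cc * ny;
      if (!seen[w]) continue;
      int ru = dsu_find(parent, u), rw = dsu_find(parent, w);
      if (ru == rw) continue;
      // winner keeps its peak; loser's peak dies at the current level v
      bool w_wins = peak_val[rw] > peak_val[ru] ||
        (peak_val[rw] == peak_val[ru] && yx_less(peak_of[rw], peak_of[ru]));
      int win = w_wins ? rw : ru, lose = w_wins ? ru : rw;
      double pers = peak_val[lose] - v;
      if (pers >= prominence) accepted.push_back(peak_of[lose]);
      parent[lose] = win;
    }
  }

  // sole surviving component: prominence relative to the image minimum
  int root = dsu_find(parent, order[0]);
  double vmin = img[order[n - 1]];
  if (peak_val[root] - vmin >= prominence) accepted.push_back(peak_of[root]);

  IntegerMatrix out(accepted.size(), 2);
  for (size_t i = 0; i < accepted.size(); ++i) {
    out(i, 0) = accepted[i] % ny + 1;
    out(i, 1) = accepted[i] / ny + 1;
  }
  return out;
}

// Collapse a peak pixel to the centroid of its equal-intensity plateau:
// flood the 8-connected region of pixels with the same value, then return
// the plateau pixel nearest the centroid (ties to the smaller (y, x)).
// [[Rcpp::export]]
IntegerVector plateau_centroid_cpp(NumericMatrix img, int y, int x) {
  const int ny = img.nrow(), nx = img.ncol();
  double v = img(y - 1, x - 1);
  std::vector<char> vis(ny * nx, 0);
  std::vector<int> stack, members;
  int start = (y - 1) + (x - 1) * ny;
  stack.push_back(start);
  vis[start] = 1;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    members.push_back(u);
    int r = u % ny, c = u / ny;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
      int w = rr + cc * ny;
      if (!vis[w] && img[w] == v) { vis[w] = 1; stack.push_back(w); }
    }
  }
  double my = 0, mx = 0;
  for (int u : members) { my += u % ny; mx += u / ny; }
  my /= members.size(); mx /= members.size();
  int best = -1; double bestd = 0;
  for (int u : members) {
    double dy = u % ny - my, dx = u / ny - mx, d = dy * dy + dx * dx;
    if (best < 0 || d < bestd - 1e-12 ||
        (std::abs(d - bestd) <= 1e-12 &&
         (u % ny < best % ny || (u % ny == best % ny && u / ny < best / ny)))) {
      best = u; bestd = d;
    }
  }
  return IntegerVector::create(best % ny + 1, best / ny + 1);
}

// Marker-based watershed by descending priority flood: regions grow downhill
// from their markers simultaneously; each unlabeled masked pixel joins the
// region that reaches it at the highest intensity (FIFO tie-break). Returns
// a label image; pixels outside the mask stay 0.
// [[Rcpp::export]]
IntegerMatrix marker_watershed_cpp(NumericMatrix img, IntegerMatrix markers,
                                   LogicalMatrix mask) {
  const int ny = img.nrow(), nx = img.ncol();
  IntegerMatrix lab(ny, nx);
  struct Node { double v; long long seq; int idx; int label; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.v != b.v) return a.v < b.v;   // max-heap on value
      return a.seq > b.seq;               // FIFO among equals
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long seq = 0;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({img(r, c), seq++, r + c * ny, markers(r, c)});
      }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int r = nd.idx % ny, c = nd.idx / ny;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
      if (!mask(rr, cc) || lab(rr, cc) > 0) continue;
      lab(rr, cc) = nd.label;
      pq.push({img(rr, cc), seq++, rr + cc * ny, nd.label});
    }
  }
  return lab;
}

// Hungarian algorithm (shortest augmenting paths with potentials), n <= m.
// Returns, for each row, the 1-based assigned column.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// Render Gaussian spots into a fresh (z, y, x) signal array (column-major,
// index = z + nz*y + nz*ny*x) initialized to `background`. `spots` columns:
// y, x, z_center, sigma_xy, amplitude (1-based y/x, fractional).
// [[Rcpp::export]]
NumericVector render_spots_cpp(int nz, int ny, int nx, double background,
                               NumericMatrix spots, double z_sigma) {
  NumericVector sig(static_cast<R_xlen_t>(nz) * ny * nx, background);
  for (int s = 0; s < spots.nrow(); ++s) {
    double yc = spots(s, 0), xc = spots(s, 1), zc = spots(s, 2);
    double sxy = spots(s, 3), amp = spots(s, 4);
    int wy = (int)std::ceil(3.5 * sxy);
    int y0 = std::max(1, (int)std::floor(yc) - wy);
    int y1 = std::min(ny, (int)std::ceil(yc) + wy);
    int x0 = std::max(1, (int)std::floor(xc) - wy);
    int x1 = std::min(nx, (int)std::ceil(xc) + wy);
    int wz = (int)std::ceil(3.0 * z_sigma);
    int z0 = std::max(1, (int)std::floor(zc) - wz);
    int z1 = std::min(nz, (int)std::ceil(zc) + wz);
    std::vector<double> gz(z1 - z0 + 1), gy(y1 - y0 + 1), gx(x1 - x0 + 1);
    for (int z = z0; z <= z1; ++z)
      gz[z - z0] = std::exp(-0.5 * (z - zc) * (z - zc) /
                            (z_sigma * z_sigma));
    for (int y = y0; y <= y1; ++y)
      gy[y - y0] = std::exp(-0.5 * (y - yc) * (y - yc) / (sxy * sxy));
    for (int x = x0; x <= x1; ++x)
      gx[x - x0] = std::exp(-0.5 * (x - xc) * (x - xc) / (sxy * sxy));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y) {
        double a = amp * gx[x - x0] * gy[y - y0];
        R_xlen_t base = (R_xlen_t)(x - 1) * nz * ny + (R_xlen_t)(y - 1) * nz;
        for (int z = z0; z <= z1; ++z)
          sig[base + z - 1] += a * gz[z - z0];
      }
  }
  return sig;
}

// Camera model in one pass: Poisson shot noise on the expected signal,
// additive Gaussian read noise, rounding, clipping to [0, top]. Shot noise
// is drawn exactly for small expectations and by the standard Gaussian
// approximation N(lambda, lambda) above `exact_below` (default 30 counts,
// where the approximation error is negligible next to read noise). Uses
// R's RNG stream (deterministic under set.seed).
// Marsaglia polar standard normal on R's uniform stream (seed-deterministic,
// much cheaper than inversion at this volume).
struct PolarNormal {
  double spare = 0; bool has_spare = false;
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// [[Rcpp::export]]
NumericVector apply_camera_cpp(NumericVector sig, double read_sd,
                               double top, double exact_below = 30.0) {
  R_xlen_t n = sig.size();
  NumericVector out(n);
  double rv2 = read_sd * read_sd;
  PolarNormal norm;
  for (R_xlen_t i = 0; i < n; ++i) {
    double lam = sig[i], v;
    if (lam <= exact_below) {
      v = R::rpois(lam);
      if (read_sd > 0) v += norm() * read_sd;
    } else {
      // shot + read noise folded into one Gaussian draw
      v = lam + norm() * std::sqrt(lam + rv2);
    }
    v = std::nearbyint(v);
    if (v < 0) v = 0;
    if (v > top) v = top;
    out[i] = v;
  }
  return out;
}

// Maximum-intensity projection of a (z, y, x) column-major array.
// [[Rcpp::export]]
NumericMatrix mip_cpp(NumericVector arr, int nz, int ny, int nx) {
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz;
      double m = arr[base];
      for (int z = 1; z < nz; ++z)
        if (arr[base + z] > m) m = arr[base + z];
      out(y, x) = m;
    }
  return out;
}


// DAPI stack: background + zprof (x) plane, (z, y, x) column-major.
// [[Rcpp::export]]
NumericVector dapi_signal_cpp(NumericMatrix plane, NumericVector zprof,
                              double background) {
  int ny = plane.nrow(), nx = plane.ncol(), nz = zprof.size();
  NumericVector sig(static_cast<R_xlen_t>(nz) * ny * nx);
  R_xlen_t k = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double p = plane(y, x);
      for (int z = 0; z < nz; ++z)
        sig[k++] = background + zprof[z] * p;
    }
  return sig;
}

// Write one channel of a (channel, z, y, x) voxel array in place.
// [[Rcpp::export]]
void set_channel_cpp(NumericVector vox, int channel, int n_channels,
                     NumericVector values) {
  R_xlen_t n = values.size();
  R_xlen_t off = channel - 1;
  for (R_xlen_t i = 0; i < n; ++i)
    vox[off + i * n_channels] = values[i];
}


// 8-connected component labelling of a binary mask, labels in raster
// discovery order.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      if (!mask(r, c) || lab(r, c) > 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * ny);
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int ur = u % ny, uc = u / ny;
        for (int k = 0; k < 8; ++k) {
          int rr = ur + dr[k], cc = uc + dc[k];
          if (rr < 0 || rr >= ny || cc < 0 || cc >= nx) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * ny);
          }
        }
      }
    }
  return lab;
}
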